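test_that("per-site WC terms: no-differentiation and fixed-difference limits", {
  # equal frequencies, equal sizes, equal het -> numerator ~ 0
  g <- rbind(a1 = 1L, a2 = 1L, a3 = 0L, b1 = 1L, b2 = 1L, b3 = 0L)
  p <- dosage_panel(g)
  # the unbiased estimator is slightly negative at a single balanced site;
  # "no differentiation" means small magnitude, not exact zero
  t1 <- fst_site_terms(p, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_lt(abs(t1$a), 0.05)

  g2 <- rbind(a1 = 2L, a2 = 2L, b1 = 0L, b2 = 0L)
  p2 <- dosage_panel(g2)
  t2 <- fst_site_terms(p2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(t2$a / t2$abc, 1)
})

test_that("WC terms match an independent symbol-by-symbol transcription", {
  set.seed(12)
  for (rep in 1:20) {
    ga <- sample(c(0:2, NA), 6, replace = TRUE, prob = c(.3, .3, .3, .1))
    gb <- sample(c(0:2, NA), 6, replace = TRUE, prob = c(.3, .3, .3, .1))
    if (sum(!is.na(ga)) < 2 || sum(!is.na(gb)) < 2) next
    p <- dosage_panel(matrix(c(ga, gb), ncol = 1))
    terms <- fst_site_terms(p, p$samples[1:6], p$samples[7:12])
    oracle <- wc_terms_oracle(ga, gb)
    if (terms$monomorphic) {
      expect_equal(c(terms$a, terms$abc), c(0, 0))
    } else {
      expect_equal(terms$a, unname(oracle["a"]), tolerance = 1e-12)
      expect_equal(terms$abc, unname(oracle["abc"]), tolerance = 1e-12)
    }
  }
})

test_that("windowed Fst is the ratio of summed components (brute force)", {
  sim <- simulate_panel(sim_config(n_breeds = 2, samples_per_breed = 8,
                                   chrom_length = 1e5, snp_density = 1 / 1000,
                                   drift_F = 0.1, seed = 61))
  p <- sim$panel
  sa <- sim$popmap$sample[sim$popmap$breed == "A"]
  sb <- sim$popmap$sample[sim$popmap$breed == "B"]
  w <- windowed_fst(p, sa, sb, window_bp = 40000, step_bp = 20000)
  terms <- fst_site_terms(p, sa, sb)
  for (k in seq_len(nrow(w))) {
    sel <- terms$pos - 1 >= w$start[k] & terms$pos - 1 < w$end[k] &
      !is.na(terms$a)
    if (!any(sel)) {
      expect_true(is.na(w$value[k]))
    } else {
      expect_equal(w$value[k], sum(terms$a[sel]) / sum(terms$abc[sel]),
                   tolerance = 1e-12)
    }
  }
  # window ratio-of-sums never exceeds the max per-site ratio inside
  ratio <- terms$a / terms$abc
  for (k in which(!is.na(w$value))) {
    sel <- terms$pos - 1 >= w$start[k] & terms$pos - 1 < w$end[k] &
      is.finite(ratio)
    if (any(sel)) expect_lte(w$value[k], max(ratio[sel]) + 1e-12)
  }
})

test_that("windows over identical populations sit at zero differentiation", {
  sim <- simulate_panel(sim_config(n_breeds = 1, samples_per_breed = 16,
                                   chrom_length = 2e5, snp_density = 1 / 500,
                                   seed = 67))
  ids <- sim$panel$samples
  w <- windowed_fst(sim$panel, ids[1:8], ids[9:16])
  expect_lt(max(abs(w$value), na.rm = TRUE), 0.15)
  expect_lt(abs(mean(w$value, na.rm = TRUE)), 0.05)
})

test_that("EHH closed forms, brute-force equivalence, monotone decay", {
  # all haplotypes identical -> EHH 1 everywhere
  hap <- matrix(0L, nrow = 6, ncol = 5)
  e <- ehh(hap, pos = 1:5 * 100, core = 3, "right", cutoff = 0)
  expect_equal(e$ehh, rep(1, 3))

  # 4 haplotypes splitting 2/2 at the first flanking site -> 1/3
  hap2 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  e2 <- ehh(hap2, pos = c(100, 200), core = 1, "right", cutoff = 0)
  expect_equal(e2$ehh[2], 1 / 3)

  set.seed(3)
  hap3 <- matrix(rbinom(20 * 15, 1, 0.5), nrow = 20)
  e3 <- ehh(hap3, pos = 1:15 * 50, core = 8, "right", cutoff = 0)
  for (i in seq_len(nrow(e3))) {
    expect_equal(e3$ehh[i], ehh_oracle(hap3, 8, 8 + (i - 1)))
  }
  e3l <- ehh(hap3, pos = 1:15 * 50, core = 8, "left", cutoff = 0)
  for (i in seq_len(nrow(e3l))) {
    expect_equal(e3l$ehh[i], ehh_oracle(hap3, 8, 8 - (i - 1)))
  }
  expect_true(all(diff(e3$ehh) <= 1e-12))
  expect_equal(e3$ehh[1], 1)
})

test_that("XP-EHH direction, symmetry, antisymmetry and trapezoid oracle", {
  set.seed(8)
  # pop A: one fixed haplotype; pop B: maximally diverse
  h_a <- matrix(0L, nrow = 8, ncol = 10)
  h_b <- matrix(rbinom(80, 1, 0.5), nrow = 8)
  h1 <- rbind(h_a[1:4, ], h_b[1:4, ])
  h2 <- rbind(h_a[5:8, ], h_b[5:8, ])
  # make the core polymorphic in the combined panel
  p <- phased_panel(h1, h2, pos = 1:10 * 1000L)
  a_ids <- p$samples[1:4]; b_ids <- p$samples[5:8]
  s <- xpehh(p, a_ids, b_ids, core = 5, cutoff = 0)
  expect_gt(s, 0)
  expect_equal(xpehh(p, b_ids, a_ids, core = 5, cutoff = 0), -s)

  # same haplotype multiset in both pops -> score 0
  pp <- phased_panel(rbind(h_b[1:4, ], h_b[1:4, ]),
                     rbind(h_b[5:8, ], h_b[5:8, ]), pos = 1:10 * 1000L)
  expect_equal(xpehh(pp, pp$samples[1:4], pp$samples[5:8], core = 5,
                     cutoff = 0), 0)

  # trapezoid recompute oracle on a toy 8+8 set
  ihh_oracle <- function(hap, pos, core) {
    total <- 0
    for (dir in c("left", "right")) {
      targets <- if (dir == "right") core:ncol(hap) else core:1
      curve <- vapply(targets, function(t) ehh_oracle(hap, core, t), numeric(1))
      cpos <- pos[targets]
      if (length(targets) > 1) {
        total <- total +
          sum((curve[-1] + curve[-length(curve)]) / 2 * abs(diff(cpos)))
      }
    }
    total
  }
  ha_full <- rbind(h1[1:4, ], h2[1:4, ])
  hb_full <- rbind(h1[5:8, ], h2[5:8, ])
  expected <- log(ihh_oracle(ha_full, 1:10 * 1000, 5) /
                    ihh_oracle(hb_full, 1:10 * 1000, 5))
  expect_equal(s, expected, tolerance = 1e-12)
})

test_that("xpehh_scan is exactly antisymmetric in the two populations", {
  sim <- simulate_panel(sim_config(n_breeds = 2, samples_per_breed = 6,
                                   chrom_length = 1e5, snp_density = 1 / 1000,
                                   seed = 71))
  sa <- sim$popmap$sample[sim$popmap$breed == "A"]
  sb <- sim$popmap$sample[sim$popmap$breed == "B"]
  f <- xpehh_scan(sim$panel, sa, sb)
  r <- xpehh_scan(sim$panel, sb, sa)
  expect_equal(f$score, -r$score, tolerance = 1e-9)
})

test_that("standardised XP-EHH has mean 0 / sd 1 and windows average scores", {
  sim <- demo_sim(seed = 81)
  p <- filter_variants(sim$panel)
  sa <- sim$popmap$sample[sim$popmap$group == "TEB"]
  sd_ <- sim$popmap$sample[sim$popmap$group == "wild"]
  sc <- xpehh_scan(p, sa, sd_)
  win <- make_windows(p)
  tr <- standardize_and_window_xpehh(sc, win)
  fin <- is.finite(sc$score)
  z <- (sc$score[fin] - mean(sc$score[fin])) / sd(sc$score[fin])
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)

  # single-SNP windows reproduce their SNP's standardised score
  one <- which(tr$n_snps == 1 & !is.na(tr$value))
  zfull <- (sc$score - mean(sc$score[fin])) / sd(sc$score[fin])
  for (k in utils::head(one, 5)) {
    sel <- sc$chrom == tr$chrom[k] & sc$pos - 1 >= tr$start[k] &
      sc$pos - 1 < tr$end[k] & is.finite(zfull)
    expect_equal(tr$value[k], zfull[sel][1], tolerance = 1e-9)
  }

  # the swept region carries the top window
  top <- tr[which.max(tr$value), ]
  expect_true(top$start < 1e6 && top$end > 9e5)
})

test_that("LSBL arithmetic, star symmetry and branch additivity", {
  grid <- tibble::tibble(chrom = "chr1", start = c(0, 20000),
                         end = c(40000, 60000), n_snps = c(5L, 5L))
  tr <- function(v) dplyr::mutate(grid, value = v)
  expect_equal(lsbl(tr(c(0.3, 0.1)), tr(c(0.2, 0.1)), tr(c(0.1, 0.1)))$value,
               c(0.2, 0.05))
  f <- 0.12
  expect_equal(lsbl(tr(f), tr(f), tr(f))$value[1], f / 2)
  # additivity: lsbl_A + lsbl_B = Fst_AB per window
  ab <- tr(c(0.25, 0.4)); ac <- tr(c(0.15, 0.2)); bc <- tr(c(0.1, 0.3))
  la <- lsbl(ab, ac, bc)$value
  lb <- lsbl(ab, bc, ac)$value
  expect_equal(la + lb, ab$value)
  # mismatched grids error
  expect_error(lsbl(tr(1:2 / 10), tr(1:2 / 10)[1, ], tr(1:2 / 10)), "grids")
})

test_that("a sweep private to A maximises the A branch but not B or C", {
  sim <- demo_sim(seed = 91)
  p <- filter_variants(sim$panel)
  pm <- sim$popmap
  pops <- list(a = "TEB", b = "black", c = "white")
  win <- make_windows(p)
  wf <- function(x, y) windowed_fst(p, resolve_pop(pm, x), resolve_pop(pm, y),
                                    windows = win)
  ab <- wf("TEB", "black"); ac <- wf("TEB", "white"); bc <- wf("black", "white")
  la <- lsbl(ab, ac, bc)
  lb <- lsbl(ab, bc, ac)   # B branch
  lc <- lsbl(ac, bc, ab)   # C branch
  top_a <- la[which.max(la$value), ]
  expect_true(top_a$start < 1e6 && top_a$end > 9e5)
  sweep_w <- which(la$start < 1e6 & la$end > 9e5)
  expect_gt(max(la$value[sweep_w]),
            max(c(lb$value[sweep_w], lc$value[sweep_w])))
})

test_that("right-tail candidate calling follows the higher-quantile rule", {
  set.seed(42)
  v <- rnorm(10000)
  win <- tibble::tibble(chrom = "chr1", start = seq_along(v) * 20000 - 20000,
                        end = seq_along(v) * 20000 + 20000,
                        n_snps = 10L, value = v)
  cc <- call_candidates(win, tail = 0.03)
  expect_equal(sum(cc$candidate), 300)
  expect_equal(attr(cc, "n_flagged"), 300)
  expect_true(all(cc$value[cc$candidate] >= attr(cc, "threshold")))

  tied <- dplyr::mutate(win[1:10, ], value = 1)
  expect_warning(ct <- call_candidates(tied, 0.3), "equal")
  expect_true(all(ct$candidate))
  expect_error(call_candidates(win, 0.7), "tail")
})

test_that("intersection and merging of candidate windows", {
  grid <- tibble::tibble(chrom = "chr1",
                         start = c(0, 20000, 40000, 100000),
                         end = c(40000, 60000, 80000, 140000),
                         n_snps = 5L)
  a <- dplyr::mutate(grid, candidate = c(TRUE, TRUE, TRUE, TRUE))
  b <- dplyr::mutate(grid, candidate = c(TRUE, TRUE, TRUE, FALSE))
  r <- intersect_and_merge(a, b)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$end, 80000)
  expect_equal(r$length_bp, 80000)
  expect_equal(attr(r, "total_length_bp"), 80000)

  none <- dplyr::mutate(grid, candidate = FALSE)
  expect_equal(nrow(intersect_and_merge(a, none)), 0)
  expect_error(intersect_and_merge(a, b[1:2, ]), "grids")
})
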