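# small phased fixture: 2 breeds x 3 samples over 6 sites; breed X fixed for
# one haplotype over all sites, breed Y diverse
fixed_vs_diverse <- function(seed = 2) {
  set.seed(seed)
  fixed <- rep(0L, 6)
  hx <- matrix(fixed, nrow = 3, ncol = 6, byrow = TRUE)
  hy1 <- matrix(rbinom(18, 1, 0.5), nrow = 3)
  hy2 <- matrix(rbinom(18, 1, 0.5), nrow = 3)
  p <- phased_panel(rbind(hx, hy1), rbind(hx, hy2))
  pm <- popmap_for(p, rep(c("X", "Y"), each = 3), c("TEB", "wild"))
  list(panel = p, popmap = pm)
}

test_that("extract_haplotypes counts chromosomes and keys by allele string", {
  h <- matrix(c(0L, 1L, 0L), nrow = 2, ncol = 3, byrow = TRUE)
  p <- phased_panel(h, h)  # both samples identical and homozygous
  pm <- popmap_for(p, c("X", "X"))
  hs <- extract_haplotypes(p, "chr1", 0, 1000, pm)
  tab <- table(hs$chromosomes$haplotype)
  expect_equal(length(tab), 1)
  expect_equal(unname(as.integer(tab)), 4)  # 2 samples x 2 chromosomes
  expect_equal(nrow(hs$chromosomes), 2 * 2)
})

test_that("samples with missing calls in the region are excluded", {
  h1 <- matrix(0L, nrow = 3, ncol = 4)
  h2 <- matrix(0L, nrow = 3, ncol = 4)
  h1[2, 3] <- NA_integer_
  p <- phased_panel(h1, h2)
  pm <- popmap_for(p, rep("X", 3))
  expect_message(hs <- extract_haplotypes(p, "chr1", 0, 1000, pm), "excluded 1")
  expect_equal(hs$n_excluded, 1)
  expect_equal(nrow(hs$chromosomes), 4)  # 2 remaining samples x 2
})

test_that("swept breeds contribute exactly one distinct haplotype", {
  sim <- demo_sim(seed = 14)
  hs <- extract_haplotypes(sim$panel, "chr1", 9e5, 1e6, sim$popmap)
  swept <- hs$chromosomes[hs$chromosomes$breed == "A", ]
  expect_equal(length(unique(swept$haplotype)), 1)
  expect_equal(unique(swept$haplotype),
               paste(sim$sweep_truth$haplotype, collapse = ""))
  # conservation: counts sum to 2 x included samples
  expect_equal(nrow(hs$chromosomes),
               2 * length(unique(hs$chromosomes$sample)))
})

test_that("LD closed forms and contingency-table oracle", {
  # perfectly co-inherited pair
  al <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  p <- phased_panel(al[1:2, ], al[3:4, ])
  pm <- popmap_for(p, c("X", "X"))
  hs <- extract_haplotypes(p, "chr1", 0, 1000, pm)
  ld <- ld_pair(hs, 1, 2)
  expect_equal(ld$r2, 1)
  expect_equal(ld$dprime, 1)

  # monomorphic site -> NA
  al2 <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 0L), c(0L, 1L))
  p2 <- phased_panel(al2[1:2, ], al2[3:4, ])
  hs2 <- extract_haplotypes(p2, "chr1", 0, 1000, popmap_for(p2, c("X", "X")))
  expect_true(is.na(ld_pair(hs2, 1, 2)$r2))

  # independent loci at large n -> r2 near 0
  set.seed(4)
  n <- 400
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  h1 <- cbind(a[1:(n / 2)], b[1:(n / 2)])
  h2 <- cbind(a[(n / 2 + 1):n], b[(n / 2 + 1):n])
  p3 <- phased_panel(h1, h2)
  hs3 <- extract_haplotypes(p3, "chr1", 0, 1000,
                            popmap_for(p3, rep("X", n / 2)))
  expect_lt(ld_pair(hs3, 1, 2)$r2, 0.05)

  # 8-haplotype toy vs hand-computed 2x2 table
  ha <- c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L)
  hb <- c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L)
  p4 <- phased_panel(cbind(ha[1:4], hb[1:4]), cbind(ha[5:8], hb[5:8]))
  hs4 <- extract_haplotypes(p4, "chr1", 0, 1000, popmap_for(p4, rep("X", 4)))
  pa <- mean(ha); pb <- mean(hb)
  pab <- mean(ha == 1 & hb == 1)
  d <- pab - pa * pb
  expect_equal(ld_pair(hs4, 1, 2)$r2,
               d^2 / (pa * (1 - pa) * pb * (1 - pb)))
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  expect_equal(ld_pair(hs4, 1, 2)$dprime, abs(d) / dmax)
})

test_that("LD is invariant to allele-label swap at either locus", {
  set.seed(6)
  a <- rbinom(30, 1, 0.4); b <- as.integer(a == 1 | rbinom(30, 1, 0.2) == 1)
  mk <- function(x, y) {
    p <- phased_panel(cbind(x[1:15], y[1:15]), cbind(x[16:30], y[16:30]))
    extract_haplotypes(p, "chr1", 0, 1000, popmap_for(p, rep("X", 15)))
  }
  base <- ld_pair(mk(a, b), 1, 2)
  swap_a <- ld_pair(mk(1L - a, b), 1, 2)
  swap_b <- ld_pair(mk(a, 1L - b), 1, 2)
  expect_equal(swap_a$r2, base$r2, tolerance = 1e-12)
  expect_equal(swap_a$dprime, base$dprime, tolerance = 1e-12)
  expect_equal(swap_b$r2, base$r2, tolerance = 1e-12)
  expect_equal(swap_b$dprime, base$dprime, tolerance = 1e-12)
})

test_that("all-D'=1 data give one block over all sites", {
  # two haplotype classes over 5 sites, complete LD, plenty of copies
  set.seed(10)
  strings <- rbind(rep(0L, 5), rep(1L, 5))
  pick <- sample(1:2, 40, replace = TRUE)
  al <- strings[pick, ]
  p <- phased_panel(al[1:20, ], al[21:40, ])
  hs <- extract_haplotypes(p, "chr1", 0, 1000, popmap_for(p, rep("X", 20)))
  bl <- find_blocks(hs)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$first, 1L)
  expect_equal(bl$last, 5L)
})

test_that("no block bridges two unlinked halves", {
  set.seed(11)
  left <- rbind(rep(0L, 4), rep(1L, 4))
  right <- rbind(rep(0L, 4), rep(1L, 4))
  al <- cbind(left[sample(1:2, 60, TRUE), ], right[sample(1:2, 60, TRUE), ])
  p <- phased_panel(al[1:30, ], al[31:60, ])
  hs <- extract_haplotypes(p, "chr1", 0, 1000, popmap_for(p, rep("X", 30)))
  bl <- find_blocks(hs)
  expect_true(nrow(bl) >= 1)
  expect_true(all(bl$last <= 4 | bl$first >= 5))
})

test_that("haplotype_table applies the strict frequency > 2 rule", {
  # counts 5, 3, 2, 1 by construction (11 chromosomes -> pad to 12 with NA-free design)
  strings <- c(rep("000", 5), rep("011", 3), rep("101", 2), "110", "110")
  # 12 chromosomes = 6 samples; last string duplicated to keep counts even
  al <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  p <- phased_panel(al[1:6, ], al[7:12, ])
  pm <- popmap_for(p, rep("X", 6))
  hs <- extract_haplotypes(p, "chr1", 0, 1000, pm)
  tab <- haplotype_table(hs, min_count = 2)
  # counts now 5,3,2,2: strict > 2 retains the 5 and 3 only
  expect_setequal(unique(tab$hap_id), c("hap_1", "hap_2"))
  expect_equal(unique(tab$n_total[tab$hap_id == "hap_1"]), 5L)
  expect_lte(sum(dplyr::distinct(tab, .data$hap_id, .data$n_total)$n_total),
             nrow(hs$chromosomes))
})

test_that("sweep fixture: hap_1 is the swept haplotype, swept breed homozygous", {
  sim <- demo_sim(seed = 15)
  hs <- extract_haplotypes(sim$panel, "chr1", 9e5, 1e6, sim$popmap)
  tab <- haplotype_table(hs, min_count = 2)
  swept_string <- paste(sim$sweep_truth$haplotype, collapse = "")
  expect_equal(unique(tab$haplotype[tab$hap_id == "hap_1"]), swept_string)
  a_rows <- tab[tab$hap_id == "hap_1" & tab$breed == "A", ]
  expect_equal(a_rows$n_hom, sum(sim$popmap$breed == "A"))
  expect_equal(a_rows$n_chrom, 2L * sum(sim$popmap$breed == "A"))
})

test_that("haplotype network edges follow Hamming MST with tie-equal edges", {
  two <- tibble::tibble(hap_id = c("h1", "h2"),
                        haplotype = c("000", "111"), n_total = c(3L, 2L))
  net <- haplotype_network(two)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3L)

  three <- tibble::tibble(hap_id = c("h1", "h2", "h3"),
                          haplotype = c("00", "01", "10"),
                          n_total = c(2L, 2L, 2L))
  net3 <- haplotype_network(three)
  expect_equal(sort(net3$edges$weight), c(1L, 1L))
  expect_false(any(net3$edges$weight == 2))

  expect_error(haplotype_network(
    tibble::tibble(hap_id = c("a", "b"), haplotype = c("00", "00"),
                   n_total = c(1L, 1L))), "duplicate")
})

test_that("network spans all haplotypes with MST-minimal total weight", {
  set.seed(13)
  haps <- unique(apply(matrix(rbinom(9 * 12, 1, 0.5), 9), 1, paste,
                       collapse = ""))
  tb <- tibble::tibble(hap_id = paste0("h", seq_along(haps)),
                       haplotype = haps,
                       n_total = rep(2L, length(haps)))
  net <- haplotype_network(tb)
  # connectivity
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = tb$hap_id)
  expect_true(igraph::is_connected(g))
  # Kruskal cross-check: MST total weight from igraph equals the sum over a
  # spanning tree inside the network
  k <- length(haps)
  al <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  dm <- as.matrix(stats::dist(al, method = "manhattan"))
  full <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                              weighted = TRUE)
  mst_w <- sum(igraph::E(igraph::mst(full))$weight)
  net_mst <- igraph::mst(g, weights = net$edges$weight)
  expect_equal(sum(igraph::E(net_mst)$weight), mst_w)
  # every network edge weight equals the Hamming distance of its endpoints
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[r], tb$hap_id)
    j <- match(net$edges$to[r], tb$hap_id)
    expect_equal(net$edges$weight[r], sum(al[i, ] != al[j, ]))
  }
})

test_that("sharing matrix closed forms, recount, and sweep submatrix of ones", {
  al <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L), c(0L, 1L, 0L))
  p <- phased_panel(al[1:2, ], al[3:4, ])
  hs <- extract_haplotypes(p, "chr1", 0, 1000, popmap_for(p, c("X", "X")))
  s <- sharing_matrix(hs)
  expect_true(isSymmetric(s))
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_equal(s["s01_h1", "s02_h1"], 1)       # identical strings
  expect_equal(s["s01_h1", "s01_h2"], 0)       # complementary strings
  # per-site recount
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(s[i, j], mean(hs$alleles[i, ] == hs$alleles[j, ]))
  }

  sim <- demo_sim(seed = 16)
  hsw <- extract_haplotypes(sim$panel, "chr1", 9e5, 1e6, sim$popmap)
  sw <- sharing_matrix(hsw)
  a_chroms <- which(hsw$chromosomes$breed == "A")
  expect_true(all(sw[a_chroms, a_chroms] == 1))
})
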