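#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes, for every site, the Weir & Cockerham (1984) among-population
#' variance component `a` and the total `a + b + c`, from per-population
#' called sample sizes, allele frequencies and observed heterozygote
#' fractions. The per-site Fst estimate is a/(a+b+c); windowed Fst uses the
#' ratio of sums of these terms (the vcftools "weighted" convention). Sites
#' where either population has no called genotype, or where the mean sample
#' size is <= 1, get NA terms; sites monomorphic across both populations get
#' terms (0, 0) and are flagged.
#'
#' @param panel a `genotype_panel`.
#' @param samples_a,samples_b disjoint sample-id vectors.
#' @return tibble with columns `chrom`, `pos`, `a`, `abc`, `monomorphic`.
#' @export
fst_site_terms <- function(panel, samples_a, samples_b) {
  if (length(intersect(samples_a, samples_b)) > 0) {
    stop("populations overlap: ", paste(intersect(samples_a, samples_b), collapse = ", "))
  }
  ga <- panel$geno[samples_a, , drop = FALSE]
  gb <- panel$geno[samples_b, , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- colSums(gb, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- colSums(ga == 1, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(gb == 1, na.rm = TRUE) / pmax(n2, 1)
  nbar <- (n1 + n2) / 2
  nc <- 2 * n1 * n2 / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  abc <- a + b + cc
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  a[mono] <- 0; abc[mono] <- 0
  bad <- n1 < 1 | n2 < 1 | nbar <= 1
  a[bad] <- NA_real_; abc[bad] <- NA_real_
  dplyr::mutate(panel$sites[, c("chrom", "pos")],
                a = a, abc = abc, monomorphic = mono & !bad)
}

#' Sliding-window grid over a panel
#'
#' Windows of `window_bp` at `step_bp` step, anchored at position 0 on each
#' chromosome (0-based half-open intervals); every window whose interval
#' starts before the last SNP is emitted, the final partial window included
#' when it contains at least one SNP.
#'
#' @param panel a `genotype_panel`.
#' @param window_bp,step_bp window length and step in bp.
#' @param autosomes_only drop X/Y/MT.
#' @return tibble with `chrom`, `start`, `end`, `n_snps`.
#' @export
make_windows <- function(panel, window_bp = 40000, step_bp = 20000,
                         autosomes_only = TRUE) {
  sites <- panel$sites
  if (autosomes_only) sites <- sites[!is_sex_chrom(sites$chrom), ]
  purrr::map_dfr(split(sites$pos, sites$chrom)[unique(sites$chrom)], function(pos) {
    last0 <- max(pos) - 1
    starts <- seq(0, last0, by = step_bp)
    p0 <- pos - 1
    n_snps <- vapply(starts, function(s) {
      sum(p0 >= s & p0 < s + window_bp)
    }, integer(1))
    keep <- starts + window_bp <= last0 + 1 | n_snps > 0
    tibble::tibble(start = starts, end = starts + window_bp,
                   n_snps = n_snps)[keep, ]
  }, .id = "chrom")
}

#' Windowed Weir-Cockerham Fst between two populations
#'
#' Per window, Fst is the ratio of summed variance components
#' (sum a / sum (a+b+c)) over the window's sites; windows with no usable
#' site get NA.
#'
#' @param panel a filtered `genotype_panel`.
#' @param samples_a,samples_b disjoint sample-id vectors.
#' @param window_bp,step_bp window geometry (40 kb windows, 20 kb step by
#'   default).
#' @param windows optional precomputed grid from [make_windows()].
#' @return tibble `chrom`, `start`, `end`, `n_snps`, `value` — a window
#'   track usable by [call_candidates()].
#' @export
windowed_fst <- function(panel, samples_a, samples_b,
                         window_bp = 40000, step_bp = 20000, windows = NULL) {
  terms <- fst_site_terms(panel, samples_a, samples_b)
  if (is.null(windows)) windows <- make_windows(panel, window_bp, step_bp)
  value <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ti <- which(terms$chrom == ch & !is.na(terms$a))
    if (length(ti) == 0) next
    p0 <- terms$pos[ti] - 1
    a <- terms$a[ti]; abc <- terms$abc[ti]
    for (k in wi) {
      sel <- p0 >= windows$start[k] & p0 < windows$end[k]
      denom <- sum(abc[sel])
      value[k] <- if (any(sel) && denom != 0) sum(a[sel]) / denom else NA_real_
    }
  }
  dplyr::mutate(windows, value = value)
}

# haplotype matrix (2n x sites) for a set of samples on one chromosome;
# missing alleles coded 2 so they form their own extension class
hap_matrix <- function(panel, samples, site_idx) {
  if (!is_phased(panel)) stop("panel is unphased; phased input required")
  h <- rbind(panel$h1[samples, site_idx, drop = FALSE],
             panel$h2[samples, site_idx, drop = FALSE])
  h[is.na(h)] <- 2L
  h
}

#' Extended haplotype homozygosity from a core site
#'
#' EHH at a flanking site x is the probability that two randomly drawn
#' chromosomes are identical over all sites from the core (exclusive) out to
#' x (inclusive): sum over extended-haplotype classes g of C(n_g, 2) /
#' C(n, 2). EHH at the core itself is 1 and the curve is non-increasing with
#' distance; it is truncated when it falls below `cutoff` or at the
#' chromosome end.
#'
#' @param hap integer haplotype matrix (chromosomes x sites, alleles 0/1,
#'   missing coded 2).
#' @param pos site positions (bp), same length as `ncol(hap)`.
#' @param core core site index (column of `hap`).
#' @param direction "right" (increasing position) or "left".
#' @param cutoff truncation threshold (0 keeps every site).
#' @return tibble with `pos` and `ehh`, first row the core with EHH 1.
#' @export
ehh <- function(hap, pos, core, direction = c("right", "left"), cutoff = 0.05) {
  direction <- match.arg(direction)
  n <- nrow(hap)
  if (n < 2) stop("need >= 2 haplotypes")
  idx <- if (direction == "right") {
    if (core < ncol(hap)) (core + 1):ncol(hap) else integer(0)
  } else {
    if (core > 1) (core - 1):1 else integer(0)
  }
  out_pos <- pos[core]; out_ehh <- 1
  g <- rep(1L, n)
  denom <- n * (n - 1) / 2
  for (j in idx) {
    key <- g * 3L + hap[, j]
    g <- match(key, unique(key))
    sizes <- tabulate(g)
    e <- sum(sizes * (sizes - 1) / 2) / denom
    if (e < cutoff) break
    out_pos <- c(out_pos, pos[j]); out_ehh <- c(out_ehh, e)
  }
  tibble::tibble(pos = out_pos, ehh = out_ehh)
}

# integrated EHH: trapezoidal area of the (left + right) EHH decay curves
# over physical distance, extension capped at max_extend_bp from the core;
# inlined group refinement (same recurrence as ehh()) to keep the genome
# scan free of per-core matrix copies
ihh_one <- function(hap, pos, core, cutoff, max_extend_bp) {
  n <- nrow(hap)
  denom <- n * (n - 1) / 2
  total <- 0
  for (dirstep in c(-1L, 1L)) {
    g <- rep(1L, n)
    last_pos <- pos[core]
    last_e <- 1
    j <- core + dirstep
    while (j >= 1L && j <= ncol(hap) &&
           abs(pos[j] - pos[core]) <= max_extend_bp) {
      key <- g * 3L + hap[, j]
      g <- match(key, unique(key))
      sizes <- tabulate(g)
      e <- sum(sizes * (sizes - 1) / 2) / denom
      if (e < cutoff) break
      total <- total + (last_e + e) / 2 * abs(pos[j] - last_pos)
      last_pos <- pos[j]
      last_e <- e
      if (e == 0) break
      j <- j + dirstep
    }
  }
  total
}

#' Cross-population EHH score at one core site
#'
#' XP-EHH = ln(iHH_A / iHH_B), where iHH is the trapezoidal integral of the
#' population's EHH decay curve over physical distance on both sides of the
#' core, each population truncated independently at `cutoff` or
#' `max_extend_bp`. Strongly positive scores indicate extended haplotype
#' homozygosity (a sweep) in population A. Exactly antisymmetric in A and B.
#'
#' @param panel a phased `genotype_panel`.
#' @param samples_a,samples_b disjoint sample-id vectors.
#' @param core site index into the panel site table.
#' @param cutoff EHH truncation threshold.
#' @param max_extend_bp maximum extension from the core (1 Mb default).
#' @return unstandardised score, or NA when either integral is zero
#'   (degenerate haplotype set).
#' @export
xpehh <- function(panel, samples_a, samples_b, core,
                  cutoff = 0.05, max_extend_bp = 1e6) {
  ch <- panel$sites$chrom[core]
  idx <- which(panel$sites$chrom == ch)
  pos <- panel$sites$pos[idx]
  core_local <- match(core, idx)
  ha <- hap_matrix(panel, samples_a, idx)
  hb <- hap_matrix(panel, samples_b, idx)
  ia <- ihh_one(ha, pos, core_local, cutoff, max_extend_bp)
  ib <- ihh_one(hb, pos, core_local, cutoff, max_extend_bp)
  if (ia == 0 || ib == 0) return(NA_real_)
  log(ia / ib)
}

#' Genome-wide per-SNP XP-EHH scan
#'
#' Computes the unstandardised XP-EHH score at every autosomal site that is
#' polymorphic in the combined populations. Monomorphic cores and degenerate
#' integrals give NA.
#'
#' @inheritParams xpehh
#' @param autosomes_only drop X/Y/MT.
#' @return tibble `chrom`, `pos`, `score`.
#' @export
xpehh_scan <- function(panel, samples_a, samples_b,
                       cutoff = 0.05, max_extend_bp = 1e6,
                       autosomes_only = TRUE) {
  if (length(intersect(samples_a, samples_b)) > 0) stop("populations overlap")
  sites <- panel$sites
  chroms <- unique(sites$chrom)
  if (autosomes_only) chroms <- chroms[!is_sex_chrom(chroms)]
  out <- vector("list", length(chroms))
  comb <- panel$geno[c(samples_a, samples_b), , drop = FALSE]
  n_called <- colSums(!is.na(comb))
  pc <- colSums(comb, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & pc > 0 & pc < 1
  for (ci in seq_along(chroms)) {
    idx <- which(sites$chrom == chroms[ci])
    pos <- sites$pos[idx]
    ha <- hap_matrix(panel, samples_a, idx)
    hb <- hap_matrix(panel, samples_b, idx)
    score <- rep(NA_real_, length(idx))
    for (j in seq_along(idx)) {
      if (!poly[idx[j]]) next
      ia <- ihh_one(ha, pos, j, cutoff, max_extend_bp)
      ib <- ihh_one(hb, pos, j, cutoff, max_extend_bp)
      if (ia > 0 && ib > 0) score[j] <- log(ia / ib)
    }
    out[[ci]] <- tibble::tibble(chrom = chroms[ci], pos = pos, score = score)
  }
  dplyr::bind_rows(out)
}

#' Standardise per-SNP XP-EHH scores and average them into windows
#'
#' Scores are z-normalised genome-wide (mean 0, sd 1 over all finite per-SNP
#' scores), then each window's value is the mean of its member SNPs'
#' standardised scores (signed mean; set `absolute = TRUE` for |scores|).
#'
#' @param scores tibble from [xpehh_scan()] (`chrom`, `pos`, `score`).
#' @param windows window grid from [make_windows()].
#' @param absolute average absolute standardised scores instead of signed.
#' @return window track tibble `chrom`, `start`, `end`, `n_snps`, `value`.
#' @export
standardize_and_window_xpehh <- function(scores, windows, absolute = FALSE) {
  finite <- is.finite(scores$score)
  if (sum(finite) < 2) stop("need >= 2 finite scores")
  mu <- mean(scores$score[finite])
  sdv <- stats::sd(scores$score[finite])
  if (sdv == 0) stop("zero variance among XP-EHH scores")
  z <- (scores$score - mu) / sdv
  if (absolute) z <- abs(z)
  value <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(scores$chrom == ch & is.finite(z))
    if (length(si) == 0) next
    p0 <- scores$pos[si] - 1
    for (k in wi) {
      sel <- p0 >= windows$start[k] & p0 < windows$end[k]
      if (any(sel)) value[k] <- mean(z[si][sel])
    }
  }
  dplyr::mutate(windows, value = value)
}

#' Locus-specific branch length from three window-matched Fst tracks
#'
#' LSBL for focal population A against B and C:
#' (Fst_AB + Fst_AC - Fst_BC) / 2, elementwise per window; NA propagates.
#' Isolates differentiation specific to the A branch of the three-population
#' star.
#'
#' @param fst_ab,fst_ac,fst_bc window tracks from [windowed_fst()] on the
#'   same grid.
#' @return window track with `value` = the A-branch length.
#' @export
lsbl <- function(fst_ab, fst_ac, fst_bc) {
  same_grid <- function(x, y) {
    nrow(x) == nrow(y) && all(x$chrom == y$chrom) && all(x$start == y$start)
  }
  if (!same_grid(fst_ab, fst_ac) || !same_grid(fst_ab, fst_bc)) {
    stop("window grids differ between the three Fst tracks")
  }
  dplyr::mutate(fst_ab[, c("chrom", "start", "end", "n_snps")],
                value = (fst_ab$value + fst_ac$value - fst_bc$value) / 2)
}

#' Flag candidate windows in the empirical right tail
#'
#' The threshold is the empirical (1 - tail) quantile of the finite window
#' values using the "higher" rule: with N finite values, the threshold is
#' the ceil(tail * N)-th largest value and every window with value >= the
#' threshold is flagged, so exactly ceil(tail * N) windows are flagged when
#' values are distinct (ties at the threshold are all flagged and may push
#' the count higher).
#'
#' @param windows a window track (`value` column).
#' @param tail right-tail mass in (0, 0.5).
#' @return the track with a logical `candidate` column; attributes
#'   `threshold` and `n_flagged`.
#' @export
call_candidates <- function(windows, tail = 0.03) {
  if (tail <= 0 || tail >= 0.5) stop("tail must be in (0, 0.5)")
  v <- windows$value
  finite <- is.finite(v)
  if (!any(finite)) stop("no finite window values")
  vf <- sort(v[finite], decreasing = TRUE)
  thr <- vf[ceiling(tail * length(vf))]
  if (vf[1] == vf[length(vf)]) {
    warning("all window values are equal; every window flagged")
  }
  out <- dplyr::mutate(windows, candidate = finite & v >= thr)
  attr(out, "threshold") <- thr
  attr(out, "n_flagged") <- sum(out$candidate)
  out
}

#' Intersect two candidate scans and merge windows into regions
#'
#' Keeps windows flagged in both scans (e.g. Fst and XP-EHH), then merges
#' windows that overlap or abut (with step < window, neighbours overlap)
#' into maximal disjoint regions.
#'
#' @param cand_a,cand_b window tracks from [call_candidates()] on the same
#'   grid.
#' @return tibble of regions `chrom`, `start`, `end`, `n_windows`,
#'   `length_bp`, sorted; attribute `total_length_bp`.
#' @export
intersect_and_merge <- function(cand_a, cand_b) {
  if (nrow(cand_a) != nrow(cand_b) ||
      !all(cand_a$chrom == cand_b$chrom & cand_a$start == cand_b$start)) {
    stop("window grids differ between the two scans")
  }
  both <- cand_a[cand_a$candidate & cand_b$candidate,
                 c("chrom", "start", "end")]
  merge_windows(both)
}

#' Merge flagged windows into maximal disjoint regions
#'
#' @param windows tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return region tibble (`chrom`, `start`, `end`, `n_windows`,
#'   `length_bp`); attribute `total_length_bp`.
#' @export
merge_windows <- function(windows) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          length_bp = numeric())
  if (nrow(windows) == 0) {
    attr(empty, "total_length_bp") <- 0
    return(empty)
  }
  windows <- dplyr::arrange(windows, .data$chrom, .data$start)
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (is.null(cur)) {
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L)
    } else if (w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end); cur$n <- cur$n + 1L
    } else {
      regions[[length(regions) + 1]] <- cur
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L)
    }
  }
  regions[[length(regions) + 1]] <- cur
  out <- purrr::map_dfr(regions, function(r) {
    tibble::tibble(chrom = r$chrom, start = r$start, end = r$end,
                   n_windows = r$n, length_bp = r$end - r$start)
  })
  attr(out, "total_length_bp") <- sum(out$length_bp)
  out
}
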