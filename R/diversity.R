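#' Per-breed observed and expected heterozygosity
#'
#' For each breed, per site: Ho = heterozygous genotypes / called genotypes;
#' He = 2*p*(1-p) from the breed allele frequency (the plug-in estimator, so
#' He <= 0.5 exactly for a biallelic site). Breed values are means over sites
#' with at least one called genotype in that breed.
#'
#' @param panel a `genotype_panel`.
#' @param popmap population map tibble (`sample`, `breed`, `group`).
#' @param unbiased apply the n/(n-1) small-sample correction to He
#'   (off by default, matching the PLINK plug-in convention).
#' @return tibble with columns `breed`, `n_samples`, `ho`, `he`.
#' @export
heterozygosity <- function(panel, popmap, unbiased = FALSE) {
  check_popmap(panel, popmap)
  purrr::map_dfr(split(popmap$sample, popmap$breed), function(ids) {
    g <- panel$geno[ids, , drop = FALSE]
    called <- colSums(!is.na(g))
    if (all(called == 0)) stop("breed has zero called genotypes at every site")
    het <- colSums(g == 1, na.rm = TRUE)
    p <- colSums(g, na.rm = TRUE) / (2 * called)
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * called / pmax(called - 1, 1)
    use <- called > 0
    tibble::tibble(n_samples = length(ids),
                   ho = mean(het[use] / called[use]),
                   he = mean(he[use]))
  }, .id = "breed")
}

#' Detect runs of homozygosity for one sample (PLINK-style)
#'
#' Implements the PLINK `--homozyg` sliding-window algorithm: a 50-SNP window
#' slides one SNP at a time along each chromosome; a window is called
#' homozygous when it contains at most `max_het_per_window` heterozygous and
#' at most `max_miss_per_window` missing calls; each SNP's hit rate is the
#' fraction of windows covering it that are homozygous, and SNPs with hit
#' rate >= `hom_window_fraction` (PLINK `--homozyg-window-threshold`) form
#' candidate runs. Runs are split at inter-SNP gaps above `max_gap_bp`, then
#' must satisfy the minimum SNP count, minimum physical length and maximum
#' bp-per-SNP density to be reported.
#'
#' Chromosomes with fewer SNPs than one window are skipped with a message.
#' Sex chromosomes and MT are excluded by default (autosomal ROH only).
#'
#' @param panel a `genotype_panel`.
#' @param sample sample id.
#' @param window_snps window size in SNPs.
#' @param max_het_per_window,max_miss_per_window per-window tolerance for
#'   genotyping error and missingness.
#' @param min_snps minimum SNPs in a reported run.
#' @param min_length_bp minimum physical length of a reported run (1 Mb,
#'   excluding short LD-driven stretches).
#' @param hom_window_fraction minimum fraction of covering windows that must
#'   be homozygous for a SNP to join a run.
#' @param density_bp_per_snp maximum average bp per SNP within a run.
#' @param max_gap_bp maximum gap between consecutive run SNPs.
#' @param autosomes_only drop chromosomes named like X/Y/MT.
#' @return tibble with columns `sample`, `chrom`, `start`, `end` (0-based
#'   half-open bp), `n_snps`, `length_bp`, sorted by chrom and start.
#' @export
detect_roh <- function(panel, sample, window_snps = 50,
                       max_het_per_window = 1, max_miss_per_window = 5,
                       min_snps = 100, min_length_bp = 1e6,
                       hom_window_fraction = 0.05,
                       density_bp_per_snp = 50000, max_gap_bp = 1e6,
                       autosomes_only = TRUE) {
  stopifnot(sample %in% panel$samples)
  empty <- tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_snps = integer(), length_bp = numeric())
  chroms <- unique(panel$sites$chrom)
  if (autosomes_only) chroms <- chroms[!is_sex_chrom(chroms)]
  segs <- list()
  for (ch in chroms) {
    idx <- which(panel$sites$chrom == ch)
    m <- length(idx)
    if (m < window_snps) {
      message("detect_roh: skipping ", ch, " (", m, " SNPs < window of ",
              window_snps, ")")
      next
    }
    g <- panel$geno[sample, idx]
    pos <- panel$sites$pos[idx]
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    ch_cum <- c(0L, cumsum(het))
    ms_cum <- c(0L, cumsum(mis))
    nw <- m - window_snps + 1L
    w_het <- ch_cum[(window_snps + 1):(m + 1)] - ch_cum[1:nw]
    w_mis <- ms_cum[(window_snps + 1):(m + 1)] - ms_cum[1:nw]
    hom <- as.integer(w_het <= max_het_per_window & w_mis <= max_miss_per_window)
    hom_cum <- c(0L, cumsum(hom))
    i <- seq_len(m)
    lo <- pmax(1L, i - window_snps + 1L)
    hi <- pmin(i, nw)
    n_cover <- hi - lo + 1L
    n_hom <- hom_cum[hi + 1L] - hom_cum[lo]
    eligible <- n_hom / n_cover >= hom_window_fraction
    # maximal runs of eligible SNPs, split at large physical gaps
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      gap_break <- which(diff(pos[run]) > max_gap_bp)
      piece_start <- c(run[1], run[gap_break + 1])
      piece_end <- c(run[gap_break], run[length(run)])
      for (p2 in seq_along(piece_start)) {
        sidx <- piece_start[p2]:piece_end[p2]
        len <- pos[sidx[length(sidx)]] - pos[sidx[1]] + 1
        if (length(sidx) >= min_snps && len >= min_length_bp &&
            len / length(sidx) <= density_bp_per_snp) {
          segs[[length(segs) + 1]] <- tibble::tibble(
            sample = sample, chrom = ch,
            start = pos[sidx[1]] - 1, end = pos[sidx[length(sidx)]],
            n_snps = length(sidx), length_bp = len)
        }
      }
    }
  }
  if (length(segs) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(segs), .data$chrom, .data$start)
}

is_sex_chrom <- function(chrom) {
  grepl("^(chr)?(x|y|mt|m)$", tolower(chrom))
}

#' Autosomal genome length covered by the SNP panel
#'
#' Per chromosome: last SNP position minus first SNP position, summed over
#' autosomes. This is the denominator of F_ROH.
#'
#' @param panel a `genotype_panel`.
#' @return bp count.
#' @export
covered_autosome_length <- function(panel) {
  sites <- panel$sites[!is_sex_chrom(panel$sites$chrom), ]
  if (nrow(sites) == 0) return(0)
  sum(tapply(sites$pos, sites$chrom, function(p) max(p) - min(p)))
}

#' Genomic inbreeding coefficient from runs of homozygosity
#'
#' F_ROH = total ROH length / autosomal genome length covered by the SNPs.
#'
#' @param segments ROH tibble from [detect_roh()] (one sample).
#' @param covered_length bp from [covered_autosome_length()].
#' @return numeric fraction in [0, 1].
#' @export
froh <- function(segments, covered_length) {
  if (covered_length <= 0) stop("covered_length must be positive")
  total <- sum(segments$length_bp)
  if (total > covered_length) stop("ROH total exceeds covered length")
  total / covered_length
}

#' Per-breed diversity summary
#'
#' Combines heterozygosity and ROH-based inbreeding into one table per breed
#' (the shape of a samples-and-diversity summary table: breed, n, Ho, He,
#' F_ROH, ROH count and total length).
#'
#' @param panel a `genotype_panel`.
#' @param popmap population map tibble.
#' @param ... passed to [detect_roh()].
#' @return tibble with columns `breed`, `n_samples`, `ho`, `he`, `f_roh`,
#'   `n_roh`, `total_roh_length`.
#' @export
diversity_summary <- function(panel, popmap, ...) {
  het <- heterozygosity(panel, popmap)
  cov_len <- covered_autosome_length(panel)
  roh <- purrr::map_dfr(panel$samples, function(s) detect_roh(panel, s, ...))
  per_sample <- tibble::tibble(sample = panel$samples) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(roh, .data$sample),
                       n_roh = dplyr::n(),
                       total = sum(.data$length_bp), .groups = "drop"),
      by = "sample") |>
    dplyr::mutate(n_roh = dplyr::coalesce(.data$n_roh, 0L),
                  total = dplyr::coalesce(.data$total, 0),
                  f_roh = .data$total / cov_len) |>
    dplyr::left_join(popmap, by = "sample")
  roh_breed <- dplyr::summarise(dplyr::group_by(per_sample, .data$breed),
                                f_roh = mean(.data$f_roh),
                                n_roh = sum(.data$n_roh),
                                total_roh_length = sum(.data$total),
                                .groups = "drop")
  dplyr::left_join(het, roh_breed, by = "breed")
}
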