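#' Per-site minor allele frequency and call rate
#'
#' MAF is computed over non-missing alleles only; call rate is the fraction
#' of samples with a called genotype.
#'
#' @param panel a `genotype_panel`.
#' @return tibble with columns `chrom`, `pos`, `n_called`, `call_rate`,
#'   `alt_freq`, `maf`.
#' @export
site_stats <- function(panel) {
  g <- panel$geno
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  alt_freq <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  # MAF from integer allele counts so boundary sites (e.g. 4 of 80 alleles)
  # compare exactly against thresholds like 0.05
  dplyr::mutate(
    panel$sites[, c("chrom", "pos")],
    n_called = n_called,
    call_rate = n_called / nrow(g),
    alt_freq = alt_freq,
    maf = ifelse(n_called > 0, pmin(alt, 2 * n_called - alt) / (2 * n_called),
                 NA_real_)
  )
}

#' Filter sites on minor allele frequency and call rate
#'
#' Retains sites with MAF strictly greater than `maf_min` and call rate
#' strictly greater than `call_rate_min` (both strict, matching the usual
#' "MAF > 0.05 and call rate > 0.9" convention). The input panel is left
#' untouched.
#'
#' @param panel a `genotype_panel`.
#' @param maf_min minor-allele-frequency threshold (strict).
#' @param call_rate_min call-rate threshold (strict).
#' @return A new, filtered `genotype_panel` with attribute `n_removed`.
#' @export
filter_variants <- function(panel, maf_min = 0.05, call_rate_min = 0.9) {
  if (n_sites(panel) == 0) stop("panel has no sites")
  st <- site_stats(panel)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$call_rate > call_rate_min
  if (!any(keep)) {
    stop("all ", n_sites(panel), " sites removed; consider lowering maf_min (",
         maf_min, ") or call_rate_min (", call_rate_min, ")")
  }
  out <- subset_panel(panel, sites = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}
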