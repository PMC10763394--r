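# shared fixture builders: tiny panels constructed in code

# panel from explicit haplotype matrices (samples x sites, 0/1/NA)
phased_panel <- function(h1, h2, pos = NULL, chrom = "chr1") {
  n <- nrow(h1)
  m <- ncol(h1)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(rownames(h1))) {
    rownames(h1) <- rownames(h2) <- sprintf("s%02d", seq_len(n))
  }
  sites <- tibble::tibble(chrom = rep(chrom, m), pos = pos,
                          ref = "A", alt = "G")
  genotype_panel(sites, h1 + h2, h1, h2)
}

# unphased panel from a dosage matrix
dosage_panel <- function(geno, pos = NULL, chrom = "chr1") {
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("s%02d", seq_len(nrow(geno)))
  }
  genotype_panel(tibble::tibble(chrom = rep(chrom, m), pos = pos,
                                ref = "A", alt = "G"), geno)
}

popmap_for <- function(panel, breeds, groups = NULL) {
  if (is.null(groups)) groups <- rep("none", length(breeds))
  tibble::tibble(sample = panel$samples, breed = breeds,
                 group = groups[match(breeds, unique(breeds))])
}

# standard demo simulation used across scan tests: one swept TEB-like breed,
# black/white/wild neutral breeds, 2 Mb chromosome, 100 kb sweep
demo_sim <- function(seed, missing_rate = 0) {
  cfg <- sim_config(
    n_breeds = 4, samples_per_breed = 12,
    breed_names = c("A", "B", "C", "D"),
    breed_groups = c(A = "TEB", B = "black", C = "white", D = "wild"),
    n_chromosomes = 1, chrom_length = 2e6, snp_density = 1 / 1000,
    drift_F = 0.05, missing_rate = missing_rate,
    sweep_spec = sweep_spec("chr1", 9e5, 1e6, "A"),
    seed = seed)
  simulate_panel(cfg)
}

# independent per-site transcription of the Weir-Cockerham (1984)
# two-population components, scalar, symbol by symbol
wc_terms_oracle <- function(ga, gb) {
  n1 <- sum(!is.na(ga)); n2 <- sum(!is.na(gb))
  p1 <- sum(ga, na.rm = TRUE) / (2 * n1); p2 <- sum(gb, na.rm = TRUE) / (2 * n2)
  h1 <- sum(ga == 1, na.rm = TRUE) / n1; h2 <- sum(gb == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  c(a = a, abc = a + b + c_)
}

# brute-force EHH by string grouping over the extension
ehh_oracle <- function(hap, core, target) {
  n <- nrow(hap)
  if (target == core) return(1)
  cols <- if (target > core) (core + 1):target else (target):(core - 1)
  keys <- apply(hap[, cols, drop = FALSE], 1, paste, collapse = "")
  sizes <- table(keys)
  sum(choose(sizes, 2)) / choose(n, 2)
}
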