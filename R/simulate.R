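#' Configure a synthetic multi-breed panel simulation
#'
#' The simulator emulates a multi-breed resequencing panel with breed-level
#' drift under the Balding-Nichols model: ancestral allele frequencies are
#' uniform on (0.05, 0.95), each breed's frequency at a site is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) so that the expected pairwise Fst between two
#' breeds with the same drift parameter F is approximately F, and haplotypes
#' are sampled i.i.d. within breed. Onto this neutral background the
#' simulator can plant (i) a sweep: a fixed haplotype over an interval in
#' designated breeds, emulating a selected regulatory haplotype near
#' fixation, and (ii) autozygosity tracts: intervals made fully homozygous in
#' designated samples, emulating runs of homozygosity from inbreeding.
#' Missingness is applied last, so truth records refer to the pre-mask state.
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed integer vector (recycled) of samples per breed.
#' @param breed_names breed labels; defaults to LETTERS.
#' @param breed_groups named character vector mapping breed to a phenotype
#'   group label (e.g. "TEB", "black", "white", "wild"); defaults to "none".
#' @param n_chromosomes,chrom_length chromosome count and length in bp.
#'   Chromosomes are named "chr1", "chr2", ...
#' @param snp_density expected SNPs per bp (sites are sorted uniform draws).
#' @param anc_freq_range range of the uniform ancestral allele-frequency
#'   draw (defaults keep sites away from fixation so the MAF spectrum spans
#'   both sides of common filter thresholds).
#' @param drift_F per-breed Balding-Nichols differentiation in (0, 1),
#'   recycled.
#' @param sweep_spec optional `sweep_spec()` describing the planted sweep.
#' @param roh_spec optional list of `list(sample=, chrom=, start=, end=)`
#'   half-open bp intervals to make homozygous.
#' @param missing_rate i.i.d. genotype missingness probability in [0, 1).
#' @param seed integer RNG seed; identical configs give identical panels.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 4, samples_per_breed = 10,
                       breed_names = NULL, breed_groups = NULL,
                       n_chromosomes = 1, chrom_length = 5e6,
                       snp_density = 1 / 1000, anc_freq_range = c(0.05, 0.95),
                       drift_F = 0.05,
                       sweep_spec = NULL, roh_spec = NULL,
                       missing_rate = 0, seed = 1) {
  if (is.null(breed_names)) {
    breed_names <- if (n_breeds <= 26) LETTERS[seq_len(n_breeds)] else
      paste0("B", seq_len(n_breeds))
  }
  stopifnot(length(breed_names) == n_breeds)
  samples_per_breed <- rep_len(as.integer(samples_per_breed), n_breeds)
  drift_F <- rep_len(drift_F, n_breeds)
  if (sum(samples_per_breed) <= 0) stop("need at least one sample")
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (any(drift_F <= 0 | drift_F >= 1)) stop("drift_F must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (is.null(breed_groups)) {
    breed_groups <- stats::setNames(rep("none", n_breeds), breed_names)
  }
  structure(list(
    n_breeds = n_breeds, samples_per_breed = samples_per_breed,
    breed_names = breed_names, breed_groups = breed_groups,
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    snp_density = snp_density, anc_freq_range = anc_freq_range,
    drift_F = drift_F,
    sweep_spec = sweep_spec, roh_spec = roh_spec,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Describe a planted sweep
#'
#' @param chrom chromosome id (e.g. "chr1").
#' @param start,end half-open bp interval of the sweep.
#' @param swept_breeds breed labels whose samples all carry the haplotype.
#' @param haplotype optional 0/1 integer vector over the sweep sites; when
#'   `NULL` a random allele string is drawn during simulation.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end, swept_breeds, haplotype = NULL) {
  if (end <= start) stop("sweep end must exceed start")
  structure(list(chrom = chrom, start = start, end = end,
                 swept_breeds = swept_breeds, haplotype = haplotype),
            class = "sweep_spec")
}

#' Simulate a phased multi-breed genotype panel with known truth
#'
#' @param config a `sim_config()`.
#' @return A list with elements `panel` (phased `genotype_panel`), `popmap`
#'   (tibble sample/breed/group), `sweep_truth` (`NULL` or a list with the
#'   sweep interval, breeds, site indices and planted haplotype) and
#'   `roh_truth` (tibble of planted tracts, zero rows if none).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n_per_chrom <- max(2L, round(config$chrom_length * config$snp_density))
  sites <- dplyr::bind_rows(lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length, n_per_chrom))
    tibble::tibble(chrom = ch, pos = pos, ref = "A", alt = "G")
  }))
  m <- nrow(sites)
  breeds <- rep(config$breed_names, config$samples_per_breed)
  samples <- unlist(lapply(seq_len(config$n_breeds), function(b) {
    sprintf("%s_%02d", config$breed_names[b], seq_len(config$samples_per_breed[b]))
  }))
  n <- length(samples)

  p_anc <- stats::runif(m, config$anc_freq_range[1], config$anc_freq_range[2])
  h1 <- matrix(NA_integer_, n, m, dimnames = list(samples, NULL))
  h2 <- h1
  for (b in seq_len(config$n_breeds)) {
    f <- config$drift_F[b]
    pb <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    rows <- which(breeds == config$breed_names[b])
    for (i in rows) {
      h1[i, ] <- stats::rbinom(m, 1L, pb)
      h2[i, ] <- stats::rbinom(m, 1L, pb)
    }
  }

  sweep_truth <- NULL
  sw <- config$sweep_spec
  if (!is.null(sw)) {
    if (!(sw$chrom %in% chroms) || sw$start < 0 || sw$end > config$chrom_length) {
      stop("sweep interval outside simulated coordinates")
    }
    if (!all(sw$swept_breeds %in% config$breed_names)) {
      stop("swept_breeds not among simulated breeds")
    }
    idx <- which(sites$chrom == sw$chrom & sites$pos > sw$start & sites$pos <= sw$end)
    hap <- sw$haplotype
    if (is.null(hap)) hap <- stats::rbinom(length(idx), 1L, 0.5)
    if (length(hap) != length(idx)) {
      stop("sweep haplotype length ", length(hap), " != ", length(idx), " sweep sites")
    }
    rows <- which(breeds %in% sw$swept_breeds)
    h1[rows, idx] <- matrix(hap, length(rows), length(idx), byrow = TRUE)
    h2[rows, idx] <- matrix(hap, length(rows), length(idx), byrow = TRUE)
    sweep_truth <- list(chrom = sw$chrom, start = sw$start, end = sw$end,
                        swept_breeds = sw$swept_breeds, site_index = idx,
                        haplotype = as.integer(hap))
  }

  roh_truth <- tibble::tibble(sample = character(), chrom = character(),
                              start = numeric(), end = numeric())
  if (!is.null(config$roh_spec)) {
    specs <- config$roh_spec
    roh_truth <- dplyr::bind_rows(lapply(specs, tibble::as_tibble))
    for (s in unique(roh_truth$sample)) {
      tr <- dplyr::arrange(roh_truth[roh_truth$sample == s, ], .data$chrom, .data$start)
      for (ch in unique(tr$chrom)) {
        trc <- tr[tr$chrom == ch, ]
        if (nrow(trc) > 1 && any(trc$start[-1] < trc$end[-nrow(trc)])) {
          stop("overlapping planted ROH tracts for sample ", s)
        }
      }
    }
    for (k in seq_len(nrow(roh_truth))) {
      s <- roh_truth$sample[k]
      if (!(s %in% samples)) stop("ROH spec names unknown sample ", s)
      idx <- which(sites$chrom == roh_truth$chrom[k] &
                     sites$pos > roh_truth$start[k] &
                     sites$pos <= roh_truth$end[k])
      h2[s, idx] <- h1[s, idx]
    }
  }

  geno <- h1 + h2
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    geno[mask] <- NA_integer_
    h1[mask] <- NA_integer_
    h2[mask] <- NA_integer_
  }

  popmap <- tibble::tibble(
    sample = samples, breed = breeds,
    group = unname(config$breed_groups[breeds])
  )
  list(panel = genotype_panel(sites, geno, h1, h2), popmap = popmap,
       sweep_truth = sweep_truth, roh_truth = roh_truth)
}

#' Write a simulated panel as a plain-text fixture set
#'
#' Emits `panel.vcf` (phased GT, or "/"-separated when `phased = FALSE` for
#' negative tests), `popmap.tsv`, `truth.json`, and `genes.gff3` — a toy
#' annotation with genes tiling each chromosome so region-to-gene overlap is
#' testable.
#'
#' @param sim result of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @param phased write phased GT separators.
#' @param gene_span,gene_gap bp span of each toy gene and gap between genes.
#' @return Named character vector of file paths.
#' @export
write_fixture <- function(sim, dir, phased = TRUE,
                          gene_span = 30000, gene_gap = 20000) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "truth.json"),
             gff = file.path(dir, "genes.gff3"))
  write_vcf(sim$panel, paths[["vcf"]], phased = phased)
  utils::write.table(sim$popmap, paths[["popmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- list(
    sweep = if (is.null(sim$sweep_truth)) NULL else
      sim$sweep_truth[c("chrom", "start", "end", "swept_breeds", "haplotype")],
    roh = sim$roh_truth
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)

  sites <- sim$panel$sites
  lines <- "##gff-version 3"
  gid <- 0
  for (ch in unique(sites$chrom)) {
    len <- max(sites$pos[sites$chrom == ch])
    starts <- seq(1, len, by = gene_span + gene_gap)
    for (s in starts) {
      gid <- gid + 1
      e <- min(s + gene_span - 1, len)
      lines <- c(lines, paste(ch, "sweepscan", "gene", s, e, ".", "+", ".",
                              sprintf("ID=gene%04d;Name=gene%04d", gid, gid),
                              sep = "\t"))
    }
  }
  writeLines(lines, paths[["gff"]])
  paths
}

#' Build a toy annotated genome for SNP-class tests
#'
#' Generates a random reference sequence plus a GFF3 gene model set with
#' exons and CDS (strands alternating, CDS lengths divisible by 3) and
#' writes both as plain text, so SNPs can be classified as
#' intergenic / intronic / exonic and synonymous / nonsynonymous against a
#' known answer.
#'
#' @param dir output directory.
#' @param chrom_length reference length in bp.
#' @param n_genes gene count, evenly spaced.
#' @param seed RNG seed.
#' @return Named character vector with `fasta` and `gff` paths.
#' @export
write_toy_genome <- function(dir, chrom_length = 20000, n_genes = 8, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
               collapse = "")
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", seq), fasta)

  # each gene: two 150 bp exons separated by a 200 bp intron; CDS == exons
  spacing <- floor(chrom_length / (n_genes + 1))
  lines <- "##gff-version 3"
  for (g in seq_len(n_genes)) {
    s <- (g - 1) * spacing + 500
    strand <- if (g %% 2 == 1) "+" else "-"
    e1 <- c(s, s + 149); e2 <- c(s + 350, s + 499)
    gene_id <- sprintf("gene%02d", g)
    tx_id <- sprintf("tx%02d", g)
    add <- function(type, st, en, phase, parent) {
      paste("chr1", "toy", type, st, en, ".", strand, phase, parent, sep = "\t")
    }
    lines <- c(
      lines,
      add("gene", e1[1], e2[2], ".", sprintf("ID=%s;Name=%s", gene_id, gene_id)),
      add("mRNA", e1[1], e2[2], ".", sprintf("ID=%s;Parent=%s", tx_id, gene_id)),
      add("exon", e1[1], e1[2], ".", sprintf("Parent=%s", tx_id)),
      add("exon", e2[1], e2[2], ".", sprintf("Parent=%s", tx_id)),
      add("CDS", e1[1], e1[2], if (strand == "+") "0" else "0",
          sprintf("ID=cds%02d;Parent=%s", g, tx_id)),
      add("CDS", e2[1], e2[2], if (strand == "+") "0" else "0",
          sprintf("ID=cds%02d;Parent=%s", g, tx_id))
    )
  }
  gff <- file.path(dir, "toy.gff3")
  writeLines(lines, gff)
  c(fasta = fasta, gff = gff)
}
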