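#' Genotype panel container
#'
#' A `genotype_panel` holds a biallelic SNP panel: a site table, an
#' alt-allele dosage matrix (samples x sites, values 0/1/2/NA) and, when the
#' source data are phased, the two haplotype matrices (values 0/1/NA).
#' Positions are stored 1-based as in VCF; every exported interval is
#' BED-style 0-based half-open, converted only at the I/O boundary.
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based bp), `ref`, `alt`.
#' @param geno integer matrix, samples x sites, alt-allele dosage in
#'   \{0, 1, 2, NA\}; rownames are sample ids.
#' @param h1,h2 optional integer haplotype matrices (0/1/NA) of the same
#'   dimension as `geno`; both present or both `NULL`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, geno, h1 = NULL, h2 = NULL) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = max(1L, NROW(geno)))
  if (ncol(geno) != nrow(sites)) {
    stop("geno has ", ncol(geno), " columns but sites has ", nrow(sites), " rows")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("sample_", seq_len(nrow(geno)))
  }
  if (xor(is.null(h1), is.null(h2))) stop("h1 and h2 must both be given or both NULL")
  if (!is.null(h1)) {
    stopifnot(identical(dim(h1), dim(geno)), identical(dim(h2), dim(geno)))
    dos <- h1 + h2
    both <- !is.na(dos) & !is.na(geno)
    if (any(dos[both] != geno[both])) stop("dosage inconsistent with haplotypes")
  }
  # positions strictly increasing within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      bad <- which(diff(p) <= 0)[1]
      stop("positions not strictly increasing on ", ch, " near pos ", p[bad + 1])
    }
  }
  structure(
    list(sites = sites, geno = geno, h1 = h1, h2 = h2,
         samples = rownames(geno)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$samples), " samples x ", nrow(x$sites),
      " sites on ", length(unique(x$sites$chrom)), " chromosome(s); ",
      if (is_phased(x)) "phased" else "unphased", "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$samples)

#' Is the panel phased?
#' @param panel a `genotype_panel`.
#' @return `TRUE` if haplotype matrices are present.
#' @export
is_phased <- function(panel) !is.null(panel$h1)

#' Subset a panel by site index and/or sample ids
#'
#' @param panel a `genotype_panel`.
#' @param sites integer or logical index into the site table (optional).
#' @param samples character vector of sample ids (optional).
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(panel)) else sites
  sa <- if (is.null(samples)) panel$samples else samples
  stopifnot(all(sa %in% panel$samples))
  genotype_panel(
    panel$sites[si, , drop = FALSE],
    panel$geno[sa, si, drop = FALSE],
    if (is_phased(panel)) panel$h1[sa, si, drop = FALSE],
    if (is_phased(panel)) panel$h2[sa, si, drop = FALSE]
  )
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Reads a VCFv4.2 file with a GT field. Multiallelic and non-SNP records are
#' skipped (a message reports the count). Phase is captured only when every
#' non-missing genotype in the file uses the "|" separator; otherwise the
#' panel is unphased and haplotype-based operations will refuse it.
#'
#' @param path path to a VCF file (plain text or bgzip).
#' @return A `genotype_panel` with attribute `n_skipped` (count of skipped
#'   records).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(v@gt) == 0 || !("FORMAT" %in% colnames(v@gt))) {
    stop("VCF has no genotype columns")
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT format field")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped, " multiallelic/non-SNP record(s)")
  }
  if (sum(keep) == 0) stop("no biallelic SNP records in ", path)
  gt <- v@gt[keep, setdiff(colnames(v@gt), "FORMAT"), drop = FALSE]
  # GT is the first colon-separated field
  gt <- sub(":.*$", "", gt)
  samples <- colnames(gt)
  gt[is.na(gt)] <- ".|."  # vcfR reads missing GT as NA
  sep_bar <- grepl("|", gt, fixed = TRUE)
  sep_slash <- grepl("/", gt, fixed = TRUE)
  phased <- all(sep_bar | gt == ".") && !any(sep_slash)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!(a %in% c("0", "1"))] <- NA_integer_
    out
  }
  h1 <- matrix(to_int(a1), nrow = nrow(gt))
  h2 <- matrix(to_int(a2), nrow = nrow(gt))
  h2[a2 == ""] <- NA_integer_  # haploid-style entries treated as missing
  dos <- h1 + h2
  sites <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep]
  )
  # vcfR keeps file order; enforce sortedness rather than silently reordering
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      bad <- which(diff(p) <= 0)[1]
      stop("VCF positions not strictly increasing on ", ch, " at pos ", p[bad + 1])
    }
  }
  geno <- t(dos); rownames(geno) <- samples
  panel <- genotype_panel(
    sites, geno,
    if (phased) t(h1) else NULL,
    if (phased) t(h2) else NULL
  )
  if (phased) { rownames(panel$h1) <- samples; rownames(panel$h2) <- samples }
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a genotype panel to a plain-text VCFv4.2 file
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @param phased write "|"-separated genotypes from the haplotype matrices
#'   (requires a phased panel); with `FALSE`, "/"-separated genotypes are
#'   written from dosages (heterozygotes as 0/1).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, phased = is_phased(panel)) {
  if (phased && !is_phased(panel)) stop("panel is unphased; cannot write phased GT")
  n <- n_samples(panel)
  m <- n_sites(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  if (phased) {
    a1 <- panel$h1; a2 <- panel$h2; sep <- "|"
  } else {
    a1 <- ifelse(panel$geno >= 1, 1L, 0L)
    a2 <- ifelse(panel$geno == 2, 1L, 0L)
    a1[is.na(panel$geno)] <- NA_integer_
    a2[is.na(panel$geno)] <- NA_integer_
    sep <- "/"
  }
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), sep, ifelse(is.na(a2), ".", a2)),
               nrow = n)
  gt[is.na(a1) | is.na(a2)] <- paste0(".", sep, ".")
  lines <- vapply(seq_len(m), function(j) {
    paste(c(panel$sites$chrom[j], panel$sites$pos[j], ".",
            panel$sites$ref[j], panel$sites$alt[j], ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a population map
#'
#' A population map assigns each sample to a breed and each breed to a
#' phenotype group (e.g. TEB / black / white / wild). File format: TSV with
#' three columns `sample`, `breed`, `group` (no header required; a header
#' line is detected and dropped).
#'
#' @param path TSV path.
#' @return tibble with columns `sample`, `breed`, `group`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "breed", "group"),
                          colClasses = "character")
  if (nrow(df) > 0 && identical(tolower(df$sample[1]), "sample")) {
    df <- df[-1, , drop = FALSE]
  }
  tibble::as_tibble(df)
}

#' Validate a population map against a panel
#'
#' @param panel a `genotype_panel`.
#' @param popmap tibble with `sample`, `breed`, `group`.
#' @return The popmap, invisibly, after checking every panel sample is mapped.
#' @export
check_popmap <- function(panel, popmap) {
  missing <- setdiff(panel$samples, popmap$sample)
  if (length(missing) > 0) {
    stop("samples missing from population map: ", paste(missing, collapse = ", "))
  }
  invisible(popmap)
}

# sample ids belonging to one or more breeds
breed_samples <- function(popmap, breeds) {
  popmap$sample[popmap$breed %in% breeds]
}
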