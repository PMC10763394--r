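#' Genes overlapping candidate regions
#'
#' Reports every gene whose span intersects a region (half-open interval
#' intersection). A gene is listed once per region it touches; the attribute
#' `n_genes` counts distinct genes genome-wide, the figure usually quoted
#' for a scan ("N genes in the selected regions").
#'
#' @param regions tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param gff path to a GFF3 file (records of type "gene" are used).
#' @param flank_bp optional symmetric flank added to each gene span.
#' @return tibble `chrom`, `start`, `end`, `gene_id`, `gene_start`,
#'   `gene_end` (one row per region x overlapping gene; regions with no
#'   gene are absent); attribute `n_genes`.
#' @export
genes_in_regions <- function(regions, gff, flank_bp = 0) {
  anno <- rtracklayer::import(gff)
  genes <- anno[anno$type == "gene"]
  if (length(genes) == 0) stop("no gene records in ", gff)
  shared <- intersect(unique(regions$chrom),
                      as.character(GenomeInfoDb::seqnames(genes)@values))
  if (nrow(regions) > 0 && length(shared) == 0) {
    stop("no shared chromosome names; regions use ",
         paste(unique(regions$chrom), collapse = ","), " but annotation has ",
         paste(unique(as.character(GenomeInfoDb::seqnames(genes))), collapse = ","))
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  gg <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(genes)),
    IRanges::IRanges(pmax(1, GenomicRanges::start(genes) - flank_bp),
                     GenomicRanges::end(genes) + flank_bp))
  hits <- GenomicRanges::findOverlaps(rg, gg)
  ids <- if (!is.null(genes$ID)) genes$ID else genes$Name
  out <- tibble::tibble(
    chrom = regions$chrom[S4Vectors::queryHits(hits)],
    start = regions$start[S4Vectors::queryHits(hits)],
    end = regions$end[S4Vectors::queryHits(hits)],
    gene_id = ids[S4Vectors::subjectHits(hits)],
    gene_start = GenomicRanges::start(genes)[S4Vectors::subjectHits(hits)] - 1,
    gene_end = GenomicRanges::end(genes)[S4Vectors::subjectHits(hits)]
  )
  attr(out, "n_genes") <- length(unique(out$gene_id))
  out
}

#' Classify SNPs as intergenic / intronic / exonic and, within CDS, as
#' synonymous or nonsynonymous
#'
#' Precedence across overlapping transcripts is exonic > intronic >
#' intergenic. For CDS SNPs the reference and alternate codons are built
#' from the spliced, strand-oriented CDS (standard genetic code) and their
#' amino acids compared. Transcripts whose concatenated CDS length is not a
#' multiple of 3 are skipped with a warning. The reference base of every
#' site is checked against the FASTA and a mismatch is an error.
#'
#' @param sites tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param gff GFF3 path with gene/mRNA/exon/CDS records.
#' @param fasta reference FASTA path.
#' @return `sites` with an added `class` column, one of "intergenic",
#'   "intronic", "exonic_noncoding", "synonymous", "nonsynonymous".
#' @export
classify_snps <- function(sites, gff, fasta) {
  anno <- rtracklayer::import(gff)
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  for (k in seq_len(nrow(sites))) {
    base <- as.character(Biostrings::subseq(ref[[sites$chrom[k]]],
                                            sites$pos[k], sites$pos[k]))
    if (base != sites$ref[k]) {
      stop("reference mismatch at ", sites$chrom[k], ":", sites$pos[k],
           " (FASTA ", base, ", site ", sites$ref[k], ")")
    }
  }
  genes <- anno[anno$type == "gene"]
  exons <- anno[anno$type == "exon"]
  cds <- anno[anno$type == "CDS"]
  # spliced CDS per transcript (Parent of the CDS records)
  cds_parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  txs <- unique(stats::na.omit(cds_parent))
  tx_models <- list()
  for (tx in txs) {
    pieces <- cds[!is.na(cds_parent) & cds_parent == tx]
    pieces <- pieces[order(GenomicRanges::start(pieces))]
    total <- sum(GenomicRanges::width(pieces))
    if (total %% 3 != 0) {
      warning("CDS length of ", tx, " not divisible by 3; transcript skipped")
      next
    }
    tx_models[[tx]] <- pieces
  }
  snp_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
  in_gene <- IRanges::overlapsAny(snp_gr, genes)
  in_exon <- IRanges::overlapsAny(snp_gr, exons)
  cls <- ifelse(in_exon, "exonic_noncoding",
                ifelse(in_gene, "intronic", "intergenic"))
  code <- Biostrings::GENETIC_CODE
  for (k in which(in_exon)) {
    hit_tx <- NULL
    for (tx in names(tx_models)) {
      if (IRanges::overlapsAny(snp_gr[k], tx_models[[tx]])) {
        hit_tx <- tx; break
      }
    }
    if (is.null(hit_tx)) next
    pieces <- tx_models[[hit_tx]]
    strand <- as.character(BiocGenerics::strand(pieces))[1]
    seqs <- vapply(seq_along(pieces), function(i) {
      as.character(Biostrings::subseq(ref[[sites$chrom[k]]],
                                      GenomicRanges::start(pieces)[i],
                                      GenomicRanges::end(pieces)[i]))
    }, character(1))
    spliced <- paste(seqs, collapse = "")
    # offset of the SNP within the spliced plus-strand CDS
    off <- 0
    for (i in seq_along(pieces)) {
      s <- GenomicRanges::start(pieces)[i]; e <- GenomicRanges::end(pieces)[i]
      if (sites$pos[k] >= s && sites$pos[k] <= e) {
        off <- off + (sites$pos[k] - s + 1)
        break
      }
      off <- off + (e - s + 1)
    }
    ref_nt <- sites$ref[k]; alt_nt <- sites$alt[k]
    if (strand == "-") {
      spliced <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
      off <- nchar(spliced) - off + 1
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_nt <- comp[[ref_nt]]; alt_nt <- comp[[alt_nt]]
    }
    codon_i <- (off - 1) %/% 3
    within <- (off - 1) %% 3 + 1
    codon <- substr(spliced, codon_i * 3 + 1, codon_i * 3 + 3)
    stopifnot(substr(codon, within, within) == ref_nt)
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt_nt
    cls[k] <- if (code[[codon]] == code[[alt_codon]]) "synonymous"
      else "nonsynonymous"
  }
  dplyr::mutate(sites, class = cls)
}

#' Read a BED file of intervals (e.g. chromatin-accessibility peaks)
#'
#' @param path BED path (>= 3 columns, 0-based half-open).
#' @return tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(st) || is.na(en) || en <= st) {
      stop("malformed BED line ", i, " in ", path)
    }
    out[[i]] <- tibble::tibble(chrom = f[1], start = st, end = en,
                               name = if (length(f) >= 4) f[4] else
                                 paste0("peak_", i))
  }
  dplyr::bind_rows(out)
}

#' Overlap of candidate regions with interval peaks
#'
#' Per region, the total overlapped bp with a peak track, the fraction of
#' the region covered, and the ids of overlapping peaks. Symmetric interval
#' intersection on 0-based half-open coordinates.
#'
#' @param regions tibble `chrom`, `start`, `end`.
#' @param peaks path to a BED file or a tibble from [read_bed()].
#' @return `regions` with added `overlap_bp`, `overlap_frac`, `peaks`
#'   (comma-separated ids, "" when none).
#' @export
peak_overlap <- function(regions, peaks) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  ob <- numeric(nrow(regions))
  ids <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    p <- peaks[peaks$chrom == regions$chrom[i], ]
    if (nrow(p) == 0) next
    ov <- pmax(0, pmin(p$end, regions$end[i]) - pmax(p$start, regions$start[i]))
    ob[i] <- sum(ov)
    ids[i] <- paste(p$name[ov > 0], collapse = ",")
  }
  dplyr::mutate(regions, overlap_bp = ob,
                overlap_frac = ob / (regions$end - regions$start),
                peaks = ids)
}
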