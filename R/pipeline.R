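#' Default pipeline configuration
#'
#' Returns the demo configuration: a four-breed panel (one TEB-like swept
#' breed, one black, one white, one wild reference) on a 2 Mb chromosome
#' with a 100 kb sweep planted in the TEB breed, followed by the full
#' analysis with the standard parameter set (MAF > 0.05, call rate > 0.9,
#' 40 kb windows at 20 kb step, 3% right tail, PLINK ROH rules, haplotype
#' count > 2). Override any entry by passing a partial list to
#' [run_pipeline()].
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_breeds = 4, samples_per_breed = 12,
      breed_names = c("A", "B", "C", "D"),
      breed_groups = c(A = "TEB", B = "black", C = "white", D = "wild"),
      n_chromosomes = 1, chrom_length = 2e6, snp_density = 1 / 1000,
      drift_F = 0.05, missing_rate = 0.02,
      sweep = list(chrom = "chr1", start = 9e5, end = 1e6,
                   swept_breeds = "A")
    ),
    filter = list(maf_min = 0.05, call_rate_min = 0.9),
    roh = list(),
    scan = list(pop_a = "TEB", pop_b = "wild", window_bp = 40000,
                step_bp = 20000, tail = 0.03,
                lsbl = list(a = "TEB", b = "black", c = "white")),
    haplo = list(min_count = 2)
  )
}

# deterministic per-stage seed from the master seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + h) %% 2147483647L
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or load VCF + popmap), filter,
#' diversity (heterozygosity, ROH, F_ROH), structure (IBS and Fst matrices,
#' NJ trees, PCA), scan (windowed Fst + XP-EHH + optional LSBL, candidate
#' regions), haplotypes (blocks, frequency table, network, sharing matrix
#' over the top candidate region), annotation (genes in regions, when a
#' GFF3 is configured or simulated). Every stage writes a TSV into the run
#' directory and a `manifest.json` records parameters, seeds and row
#' counts. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config configuration list (see [default_config()]), a path to a
#'   YAML file, or a partial list merged over the defaults.
#' @param out_dir run directory (created).
#' @return the run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("sweepscan")),
                   seed = config$seed, config = config, rows = list())
  path <- function(f) file.path(out_dir, f)

  # -- stage 1: input panel ------------------------------------------------
  if (!is.null(config$input)) {
    panel <- read_vcf(config$input$vcf)
    popmap <- read_popmap(config$input$popmap)
    truth <- NULL
    gff <- config$input$gff
  } else {
    sc <- config$simulate
    sw <- if (!is.null(sc$sweep)) {
      do.call(sweep_spec, sc$sweep)
    }
    cfg <- sim_config(
      n_breeds = sc$n_breeds, samples_per_breed = sc$samples_per_breed,
      breed_names = sc$breed_names, breed_groups = unlist(sc$breed_groups),
      n_chromosomes = sc$n_chromosomes, chrom_length = sc$chrom_length,
      snp_density = sc$snp_density, drift_F = sc$drift_F,
      sweep_spec = sw, roh_spec = sc$roh_spec,
      missing_rate = sc$missing_rate,
      seed = stage_seed(config$seed, "simulate"))
    sim <- simulate_panel(cfg)
    fx <- write_fixture(sim, out_dir)
    panel <- sim$panel
    popmap <- sim$popmap
    truth <- sim$sweep_truth
    gff <- fx[["gff"]]
  }
  check_popmap(panel, popmap)
  manifest$rows$input_sites <- n_sites(panel)
  manifest$rows$samples <- n_samples(panel)

  # -- stage 2: filter -----------------------------------------------------
  panel <- filter_variants(panel, config$filter$maf_min,
                           config$filter$call_rate_min)
  manifest$rows$filtered_sites <- n_sites(panel)
  cov_len <- covered_autosome_length(panel)
  manifest$rows$covered_autosome_bp <- cov_len

  # -- stage 3: diversity --------------------------------------------------
  div <- do.call(diversity_summary, c(list(panel, popmap), config$roh))
  manifest$rows$diversity <- write_tsv(div, path("diversity.tsv"))
  roh <- purrr::map_dfr(panel$samples, function(s)
    do.call(detect_roh, c(list(panel, s), config$roh)))
  manifest$rows$roh_segments <- write_tsv(roh, path("roh.tsv"))

  # -- stage 4: structure --------------------------------------------------
  ibs <- ibs_distance(panel)
  utils::write.table(ibs, path("ibs_distance.tsv"), sep = "\t", quote = FALSE)
  fstm <- pairwise_fst_matrix(panel, popmap)
  utils::write.table(fstm, path("fst_matrix.tsv"), sep = "\t", quote = FALSE)
  ape::write.tree(neighbor_joining(ibs), path("nj_samples.nwk"))
  if (nrow(fstm) >= 3) {
    ape::write.tree(neighbor_joining(fstm), path("nj_breeds.nwk"))
  }
  pca <- panel_pca(panel, n_components = min(4, n_samples(panel) - 1))
  manifest$rows$pca_samples <- write_tsv(pca$scores, path("pca.tsv"))

  # -- stage 5: selection scan ---------------------------------------------
  scn <- config$scan
  scan <- sweep_scan(panel, popmap, scn$pop_a, scn$pop_b,
                     window_bp = scn$window_bp, step_bp = scn$step_bp,
                     tail = scn$tail, lsbl_pops = scn$lsbl)
  manifest$rows$windows <- write_tsv(tidy(scan), path("windows.tsv"))
  regions <- scan$regions
  manifest$rows$regions <- write_tsv(regions, path("regions.tsv"))
  writeLines(sprintf("%s\t%d\t%d", regions$chrom, as.integer(regions$start),
                     as.integer(regions$end)), path("regions.bed"))
  manifest$thresholds <- as.list(scan$thresholds)
  manifest$rows$total_region_bp <- attr(regions, "total_length_bp")
  manifest$rows$genome_fraction <-
    attr(regions, "total_length_bp") / cov_len

  # -- stage 6: haplotype analysis of the top region -----------------------
  if (nrow(regions) > 0 && is_phased(panel)) {
    fst_track <- scan$tracks$fst
    best_w <- fst_track[which.max(fst_track$value), ]
    hit <- regions[regions$chrom == best_w$chrom &
                     regions$start < best_w$end &
                     regions$end > best_w$start, ]
    top <- if (nrow(hit) > 0) hit[1, ] else regions[1, ]
    hs <- extract_haplotypes(panel, top$chrom, top$start, top$end, popmap)
    blocks <- find_blocks(hs)
    manifest$rows$blocks <- write_tsv(blocks, path("blocks.tsv"))
    tab <- haplotype_table(hs, min_count = config$haplo$min_count)
    manifest$rows$haplotypes <- write_tsv(tab, path("haplotypes.tsv"))
    distinct <- dplyr::distinct(tab[, c("hap_id", "haplotype", "n_total")])
    if (nrow(distinct) >= 2) {
      net <- haplotype_network(distinct)
      write_tsv(net$edges, path("network_edges.tsv"))
    }
    utils::write.table(sharing_matrix(hs), path("sharing_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  }

  # -- stage 7: annotation -------------------------------------------------
  if (!is.null(gff) && nrow(regions) > 0) {
    hits <- genes_in_regions(regions, gff)
    manifest$rows$region_genes <- write_tsv(hits, path("region_genes.tsv"))
    manifest$rows$n_genes <- attr(hits, "n_genes")
  }
  if (!is.null(truth)) {
    manifest$truth <- truth[c("chrom", "start", "end", "swept_breeds")]
  }
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(out_dir, "manifest") <- manifest
  invisible(out_dir)
}

#' Summarise a completed pipeline run
#'
#' Reads the run directory written by [run_pipeline()] and returns the
#' headline tables: the per-breed diversity table (breed, n, Ho, He,
#' F_ROH), the candidate-region summary (count, total length, fraction of
#' the covered autosomal genome, recomputed from the region table), and the
#' haplotype frequency table.
#'
#' @param run_dir directory from [run_pipeline()].
#' @return list with `diversity`, `regions` (tibble plus attributes
#'   `n_regions`, `total_length_bp`, `genome_fraction`), `haplotypes`; of
#'   class `pipeline_report` with a printed summary.
#' @export
pipeline_report <- function(run_dir) {
  need <- c("manifest.json", "diversity.tsv", "regions.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    stop("incomplete run: missing ", paste(missing, collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  rd <- function(f, classes = NA) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) {
      tibble::as_tibble(utils::read.table(p, sep = "\t", header = TRUE,
                                          colClasses = classes))
    }
  }
  regions <- rd("regions.tsv")
  total <- if (nrow(regions) > 0) sum(regions$end - regions$start) else 0
  out <- list(
    diversity = rd("diversity.tsv"),
    regions = regions,
    haplotypes = rd("haplotypes.tsv",
                    classes = c(hap_id = "character",
                                haplotype = "character")),
    n_regions = nrow(regions),
    total_length_bp = total,
    genome_fraction = total / manifest$rows$covered_autosome_bp
  )
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Diversity by breed ==\n")
  print(x$diversity)
  cat(sprintf("\n== Candidate regions ==\n%d region(s), %.2f Mb total, %.2f%% of covered autosomes\n",
              x$n_regions, x$total_length_bp / 1e6, 100 * x$genome_fraction))
  if (x$n_regions > 0) print(x$regions)
  if (!is.null(x$haplotypes) && nrow(x$haplotypes) > 0) {
    cat("\n== Haplotype frequencies (top candidate region) ==\n")
    print(x$haplotypes)
  }
  invisible(x)
}
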