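#' Resolve a population specification against a population map
#'
#' Accepts breed labels, group labels, or sample ids and returns sample ids.
#'
#' @param popmap population map tibble.
#' @param pop character vector of breeds, groups, or samples.
#' @return character vector of sample ids.
#' @export
resolve_pop <- function(popmap, pop) {
  if (all(pop %in% popmap$breed)) return(popmap$sample[popmap$breed %in% pop])
  if (all(pop %in% popmap$group)) return(popmap$sample[popmap$group %in% pop])
  if (all(pop %in% popmap$sample)) return(pop)
  stop("population spec not found in popmap breeds/groups/samples: ",
       paste(pop, collapse = ", "))
}

#' Windowed selection scan between two populations
#'
#' Runs the windowed Weir-Cockerham Fst scan and (for phased panels) the
#' standardised windowed XP-EHH scan between population A (putatively
#' selected) and population B (reference), optionally adds the
#' locus-specific branch length (LSBL) track from a three-population design,
#' flags the empirical right tail of each track, and intersects the Fst and
#' XP-EHH candidates into merged candidate regions.
#'
#' @param panel a filtered `genotype_panel`.
#' @param popmap population map tibble.
#' @param pop_a,pop_b breed/group/sample specs for the two scan populations.
#' @param window_bp,step_bp window geometry.
#' @param tail right-tail mass for candidate calling.
#' @param methods subset of c("fst", "xpehh").
#' @param lsbl_pops optional list(a=, b=, c=) of population specs for the
#'   LSBL track (A the focal population).
#' @param cutoff,max_extend_bp EHH truncation parameters.
#' @return object of class `sweep_scan`: list with `tracks` (named list of
#'   candidate-flagged window tibbles), `regions` (merged Fst-and-XP-EHH
#'   candidate regions, or single-method regions when only one method ran),
#'   `thresholds`, and `params`.
#' @export
sweep_scan <- function(panel, popmap, pop_a, pop_b,
                       window_bp = 40000, step_bp = 20000, tail = 0.03,
                       methods = c("fst", "xpehh"), lsbl_pops = NULL,
                       cutoff = 0.05, max_extend_bp = 1e6) {
  check_popmap(panel, popmap)
  methods <- match.arg(methods, several.ok = TRUE)
  sa <- resolve_pop(popmap, pop_a)
  sb <- resolve_pop(popmap, pop_b)
  windows <- make_windows(panel, window_bp, step_bp)
  tracks <- list()
  thresholds <- c()
  if ("fst" %in% methods) {
    tr <- call_candidates(windowed_fst(panel, sa, sb, windows = windows), tail)
    thresholds["fst"] <- attr(tr, "threshold")
    tracks$fst <- tr
  }
  if ("xpehh" %in% methods) {
    sc <- xpehh_scan(panel, sa, sb, cutoff = cutoff,
                     max_extend_bp = max_extend_bp)
    tr <- call_candidates(standardize_and_window_xpehh(sc, windows), tail)
    thresholds["xpehh"] <- attr(tr, "threshold")
    tracks$xpehh <- tr
  }
  if (!is.null(lsbl_pops)) {
    a <- resolve_pop(popmap, lsbl_pops$a)
    b <- resolve_pop(popmap, lsbl_pops$b)
    cc <- resolve_pop(popmap, lsbl_pops$c)
    tr <- lsbl(windowed_fst(panel, a, b, windows = windows),
               windowed_fst(panel, a, cc, windows = windows),
               windowed_fst(panel, b, cc, windows = windows))
    tr <- call_candidates(tr, tail)
    thresholds["lsbl"] <- attr(tr, "threshold")
    tracks$lsbl <- tr
  }
  regions <- if (all(c("fst", "xpehh") %in% names(tracks))) {
    intersect_and_merge(tracks$fst, tracks$xpehh)
  } else {
    first <- tracks[[1]]
    merge_windows(first[first$candidate, c("chrom", "start", "end")])
  }
  structure(list(tracks = tracks, regions = regions, thresholds = thresholds,
                 params = list(pop_a = pop_a, pop_b = pop_b,
                               window_bp = window_bp, step_bp = step_bp,
                               tail = tail)),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan> methods: ", paste(names(x$tracks), collapse = ", "),
      "; ", nrow(x$tracks[[1]]), " windows; ", nrow(x$regions),
      " merged candidate region(s), ",
      attr(x$regions, "total_length_bp"), " bp total\n", sep = "")
  invisible(x)
}

#' Tidy a selection scan into one long window table
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return tibble with `method`, `chrom`, `start`, `end`, `n_snps`, `value`,
#'   `candidate`.
#' @export
tidy.sweep_scan <- function(x, ...) {
  purrr::map_dfr(x$tracks, ~.x, .id = "method")
}

#' One-row summary of a selection scan
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return tibble with window/candidate counts per method and merged-region
#'   count and total length.
#' @export
glance.sweep_scan <- function(x, ...) {
  out <- tibble::tibble(
    n_windows = nrow(x$tracks[[1]]),
    n_regions = nrow(x$regions),
    total_region_bp = attr(x$regions, "total_length_bp")
  )
  for (m in names(x$tracks)) {
    out[[paste0("n_candidate_", m)]] <- sum(x$tracks[[m]]$candidate)
    out[[paste0("threshold_", m)]] <- unname(x$thresholds[m])
  }
  out
}

#' Plot the window tracks of a selection scan
#'
#' Window statistic against genomic midpoint, one facet per method,
#' candidate windows highlighted and the empirical tail threshold drawn.
#'
#' @param object a `sweep_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  df <- tidy(object)
  thr <- tibble::tibble(method = names(object$thresholds),
                        threshold = unname(object$thresholds))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$value,
                                   colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(method ~ chrom, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = "window statistic",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample coordinates
#'
#' @param object a `panel_pca`.
#' @param popmap optional population map for colouring by breed.
#' @param ... unused.
#' @return a ggplot of the first two components.
#' @export
autoplot.panel_pca <- function(object, popmap = NULL, ...) {
  df <- object$scores
  if (!is.null(popmap)) df <- dplyr::left_join(df, popmap, by = "sample")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(popmap)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$breed))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Plot a haplotype network
#'
#' Minimum-spanning-network layout (Kamada-Kawai, deterministic), node area
#' proportional to haplotype count, edges labelled with Hamming distance.
#'
#' @param object a `haplotype_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes$hap_id)
  xy <- igraph::layout_with_kk(g, weights = object$edges$weight)
  lay <- tibble::tibble(hap_id = igraph::V(g)$name,
                        x = xy[, 1], y = xy[, 2]) |>
    dplyr::left_join(object$nodes, by = "hap_id")
  ed <- object$edges |>
    dplyr::left_join(lay[, c("hap_id", "x", "y")],
                     by = c(from = "hap_id")) |>
    dplyr::left_join(lay[, c("hap_id", "x", "y")],
                     by = c(to = "hap_id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size),
                        colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$hap_id),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(size = "chromosomes") +
    ggplot2::theme_void()
}
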