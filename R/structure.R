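#' Identity-by-state distance matrix between samples
#'
#' d(i, j) = 1 - shared alleles / (2 x sites called in both samples); sites
#' missing in either sample are excluded from that pair. For dosages g, the
#' shared-allele count at one site is 2 - |g_i - g_j|.
#'
#' @param panel a `genotype_panel` with >= 2 samples.
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
ibs_distance <- function(panel) {
  n <- n_samples(panel)
  if (n < 2) stop("need >= 2 samples")
  g <- panel$geno
  d <- matrix(0, n, n, dimnames = list(panel$samples, panel$samples))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      if (!any(ok)) {
        stop("samples ", panel$samples[i], " and ", panel$samples[j],
             " share no co-called sites")
      }
      d[i, j] <- d[j, i] <- sum(abs(gi[ok] - gj[ok])) / (2 * sum(ok))
    }
  }
  d
}

#' Pairwise Weir-Cockerham Fst matrix between breeds
#'
#' Genome-wide ratio-of-sums Weir-Cockerham (1984) estimator for each breed
#' pair. Negative genome-wide estimates are floored at zero for use as a
#' distance; the raw values are kept in attribute `raw`.
#'
#' @param panel a `genotype_panel`.
#' @param popmap population map tibble; every breed needs >= 2 samples.
#' @return symmetric breed x breed matrix, attribute `raw` holds unfloored
#'   estimates.
#' @export
pairwise_fst_matrix <- function(panel, popmap) {
  check_popmap(panel, popmap)
  breeds <- unique(popmap$breed)
  if (length(breeds) < 2) stop("need >= 2 breeds")
  sizes <- table(popmap$breed)
  if (any(sizes < 2)) {
    stop("breeds with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  k <- length(breeds)
  raw <- matrix(0, k, k, dimnames = list(breeds, breeds))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      terms <- fst_site_terms(panel, breed_samples(popmap, breeds[i]),
                              breed_samples(popmap, breeds[j]))
      raw[i, j] <- raw[j, i] <-
        sum(terms$a, na.rm = TRUE) / sum(terms$abc, na.rm = TRUE)
    }
  }
  out <- pmax(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths, an
#' artefact of NJ on noisy distances, are clamped to zero with a message.
#'
#' @param dm symmetric distance matrix with labels (samples or breeds).
#' @return an \pkg{ape} `phylo` tree (write with [ape::write.tree()]).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 labels")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix is not symmetric")
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    message("neighbor_joining: clamped ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' PCA of the genotype matrix (GRM convention)
#'
#' Eigendecomposition of the sample covariance of the centred,
#' frequency-standardised genotype matrix: each site is centred at 2p and
#' divided by sqrt(2p(1-p)) (the GCTA genetic-relationship-matrix
#' convention); missing genotypes are mean-imputed; monomorphic sites are
#' dropped. The sign of each component is fixed so that its
#' largest-magnitude score is positive.
#'
#' @param panel a `genotype_panel`.
#' @param n_components number of components to return.
#' @return object of class `panel_pca`: list with `scores` (tibble: sample,
#'   PC1..PCk) and `var_explained` (fractions of total variance,
#'   non-increasing, summing to <= 1).
#' @export
panel_pca <- function(panel, n_components = 2) {
  g <- panel$geno
  n <- nrow(g)
  if (n < 2) stop("need >= 2 samples")
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & p > 0 & p < 1
  if (sum(poly) < n_components) {
    stop(sum(poly), " polymorphic sites < ", n_components, " components")
  }
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  grm <- tcrossprod(x) / ncol(x)
  eig <- eigen(grm, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vex <- lambda / sum(lambda)
  scores <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(n_components)]), n_components)
  for (k in seq_len(n_components)) {
    if (scores[which.max(abs(scores[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = panel$samples),
                              tibble::as_tibble(scores)),
    var_explained = vex[seq_len(n_components)]
  ), class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("<panel_pca> ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components (",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
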