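#' Extract phased haplotypes over a genomic region
#'
#' Collects the two haplotypes of every sample over the sites inside a
#' 0-based half-open region. Samples with any missing call in the region are
#' excluded (a message reports how many), so every retained chromosome is a
#' complete 0/1 allele string.
#'
#' @param panel a phased `genotype_panel`.
#' @param chrom,start,end region (0-based half-open bp).
#' @param popmap population map tibble.
#' @return object of class `haplotype_set`: list with `chrom`, `start`,
#'   `end`, `pos` (site positions), `chromosomes` (tibble: sample, copy,
#'   breed, group, haplotype string), `alleles` (chromosomes x sites 0/1
#'   matrix) and `n_excluded`.
#' @export
extract_haplotypes <- function(panel, chrom, start, end, popmap) {
  if (!is_phased(panel)) stop("panel is unphased; phased input required")
  check_popmap(panel, popmap)
  idx <- which(panel$sites$chrom == chrom &
                 panel$sites$pos > start & panel$sites$pos <= end)
  if (length(idx) == 0) stop("region contains no sites")
  h1 <- panel$h1[, idx, drop = FALSE]
  h2 <- panel$h2[, idx, drop = FALSE]
  complete <- !(rowSums(is.na(h1)) > 0 | rowSums(is.na(h2)) > 0)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message("extract_haplotypes: excluded ", n_excluded,
            " sample(s) with missing calls in region")
  }
  if (!any(complete)) stop("no sample has complete calls in region")
  keep <- panel$samples[complete]
  alleles <- rbind(h1[keep, , drop = FALSE], h2[keep, , drop = FALSE])
  strings <- apply(alleles, 1, paste, collapse = "")
  meta <- popmap[match(keep, popmap$sample), ]
  chromosomes <- tibble::tibble(
    sample = rep(keep, 2),
    copy = rep(1:2, each = length(keep)),
    breed = rep(meta$breed, 2),
    group = rep(meta$group, 2),
    haplotype = strings
  )
  rownames(alleles) <- paste0(chromosomes$sample, "_h", chromosomes$copy)
  structure(list(chrom = chrom, start = start, end = end,
                 pos = panel$sites$pos[idx], chromosomes = chromosomes,
                 alleles = alleles, n_excluded = n_excluded),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", x$chrom, ":", x$start, "-", x$end, ", ",
      length(x$pos), " sites, ", nrow(x$chromosomes), " chromosomes, ",
      length(unique(x$chromosomes$haplotype)), " distinct haplotypes\n",
      sep = "")
  invisible(x)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Classical two-locus LD from the 2x2 haplotype table: D = p_AB - p_A p_B,
#' D' = D / Dmax, r^2 = D^2 / (p_A q_A p_B q_B). Sites are addressed by
#' index into the set's site list.
#'
#' @param hapset a `haplotype_set`.
#' @param i,j site indices.
#' @return tibble with `r2` and `dprime` (NA if either site is monomorphic).
#' @export
ld_pair <- function(hapset, i, j) {
  a <- hapset$alleles[, i]
  b <- hapset$alleles[, j]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    return(tibble::tibble(r2 = NA_real_, dprime = NA_real_))
  }
  pab <- mean(a == 1 & b == 1)
  d <- pab - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  tibble::tibble(r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)),
                 dprime = if (dmax == 0) NA_real_ else abs(d) / dmax)
}

# likelihood-based confidence interval for |D'| (Gabriel/Haploview style):
# profile the multinomial likelihood of the 4 haplotype counts over a grid
# of |D'| in [0,1] at the observed allele frequencies, normalise, and read
# off the 5th / 95th percentiles of the normalised curve
dprime_ci <- function(a, b, grid = seq(0, 1, by = 0.001)) {
  pa <- mean(a); pb <- mean(b)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  d_obs <- mean(a == 1 & b == 1) - pa * pb
  dmax <- if (d_obs >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  sgn <- if (d_obs >= 0) 1 else -1
  d <- sgn * grid * dmax
  f11 <- pmax(pa * pb + d, 1e-12)
  f10 <- pmax(pa * (1 - pb) - d, 1e-12)
  f01 <- pmax((1 - pa) * pb - d, 1e-12)
  f00 <- pmax((1 - pa) * (1 - pb) + d, 1e-12)
  ll <- n11 * log(f11) + n10 * log(f10) + n01 * log(f01) + n00 * log(f00)
  lk <- exp(ll - max(ll))
  cum <- cumsum(lk) / sum(lk)
  c(low = grid[which(cum >= 0.05)[1]], high = grid[which(cum >= 0.95)[1]])
}

#' Haplotype blocks by the Gabriel confidence-interval rule
#'
#' Classifies each polymorphic site pair by the confidence interval of |D'|:
#' "strong LD" when the CI lower bound >= `ci_low` (0.70) and upper bound >=
#' `ci_high` (0.98); "strong recombination" when the upper bound <
#' `recomb_high` (0.90). A candidate block [i, j] requires its outermost
#' pair to be in strong LD and at least `strong_frac` (95%) of its
#' informative pairs (those classified one way or the other) to be strong
#' LD. Maximal non-overlapping blocks are accepted greedily by decreasing bp
#' span (ties to the left), which is deterministic.
#'
#' @param hapset a `haplotype_set` with >= 2 polymorphic sites.
#' @param ci_low,ci_high,recomb_high,strong_frac Gabriel rule parameters
#'   (Haploview defaults).
#' @return tibble of blocks: `first`, `last` (site indices), `n_snps`,
#'   `start`, `end` (0-based half-open bp), `span_bp`; zero rows when no
#'   pair qualifies.
#' @export
find_blocks <- function(hapset, ci_low = 0.70, ci_high = 0.98,
                        recomb_high = 0.90, strong_frac = 0.95) {
  al <- hapset$alleles
  m <- ncol(al)
  empty <- tibble::tibble(first = integer(), last = integer(),
                          n_snps = integer(), start = numeric(),
                          end = numeric(), span_bp = numeric())
  if (m < 2) return(empty)
  # pair classification: 1 strong LD, -1 strong recombination, 0 uninformative
  cls <- matrix(0L, m, m)
  poly <- apply(al, 2, function(x) length(unique(x)) > 1)
  for (i in seq_len(m - 1)) {
    if (!poly[i]) next
    for (j in (i + 1):m) {
      if (!poly[j]) next
      ci <- dprime_ci(al[, i], al[, j])
      if (ci["low"] >= ci_low && ci["high"] >= ci_high) {
        cls[i, j] <- 1L
      } else if (ci["high"] < recomb_high) {
        cls[i, j] <- -1L
      }
    }
  }
  cand <- expand.grid(first = seq_len(m - 1), last = seq_len(m))
  cand <- cand[cand$last > cand$first, ]
  ok <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand$first[k]; j <- cand$last[k]
    if (cls[i, j] != 1L) return(FALSE)
    sub <- cls[i:j, i:j]
    n_strong <- sum(sub == 1L)
    n_recomb <- sum(sub == -1L)
    n_strong + n_recomb > 0 && n_strong / (n_strong + n_recomb) >= strong_frac
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand$span <- hapset$pos[cand$last] - hapset$pos[cand$first]
  cand <- cand[order(-cand$span, cand$first), ]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$first[k]; j <- cand$last[k]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1]] <- tibble::tibble(
      first = i, last = j, n_snps = j - i + 1L,
      start = hapset$pos[i] - 1, end = hapset$pos[j],
      span_bp = hapset$pos[j] - hapset$pos[i] + 1)
  }
  dplyr::arrange(dplyr::bind_rows(blocks), .data$first)
}

#' Breed-stratified haplotype frequency table
#'
#' Haplotypes with total count strictly greater than `min_count` are
#' retained and labelled `hap_1`, `hap_2`, ... by descending total count
#' (ties broken by allele string). For each retained haplotype and breed the
#' table reports the chromosome count and the number of samples homozygous
#' for the haplotype — homozygous carriage restricted to particular breeds
#' is the hallmark of a breed-defining sweep haplotype.
#'
#' @param hapset a `haplotype_set`.
#' @param min_count strict total-count threshold (default 2: "frequency
#'   greater than 2").
#' @return tibble with `hap_id`, `haplotype`, `n_total`, `breed`, `n_chrom`,
#'   `n_hom` (one row per retained haplotype x breed with presence).
#' @export
haplotype_table <- function(hapset, min_count = 2) {
  ch <- hapset$chromosomes
  totals <- sort(table(ch$haplotype), decreasing = TRUE)
  totals <- totals[order(-totals, names(totals))]
  keep <- names(totals)[as.integer(totals) > min_count]
  if (length(keep) == 0) {
    return(tibble::tibble(hap_id = character(), haplotype = character(),
                          n_total = integer(), breed = character(),
                          n_chrom = integer(), n_hom = integer()))
  }
  ids <- stats::setNames(paste0("hap_", seq_along(keep)), keep)
  # homozygous carriers: both copies of a sample equal the haplotype
  wide <- tidyr::pivot_wider(ch[, c("sample", "breed", "copy", "haplotype")],
                             names_from = "copy", values_from = "haplotype")
  purrr::map_dfr(keep, function(h) {
    sub <- ch[ch$haplotype == h, ]
    hom <- wide[wide$`1` == h & wide$`2` == h, ]
    counts <- dplyr::count(sub, .data$breed, name = "n_chrom")
    counts$n_hom <- vapply(counts$breed, function(b) sum(hom$breed == b),
                           integer(1), USE.NAMES = FALSE)
    dplyr::mutate(counts, hap_id = ids[[h]], haplotype = h,
                  n_total = as.integer(totals[[h]]), .before = 1)
  })
}

#' Minimum spanning network of haplotypes
#'
#' Builds the minimum spanning network over Hamming distances between
#' distinct haplotype strings: all edges of a minimum spanning tree plus
#' every tie-equal alternative (edges of a given weight joining components
#' that are still separate when that weight level begins). Deterministic
#' under node order.
#'
#' @param haplotypes tibble with columns `hap_id`, `haplotype` and a count
#'   column `n_total` (e.g. the distinct rows of [haplotype_table()]), or a
#'   `haplotype_set` (distinct haplotypes with counts are derived).
#' @return object of class `haplotype_network`: list with `nodes` (tibble:
#'   hap_id, haplotype, size) and `edges` (tibble: from, to, weight).
#' @export
haplotype_network <- function(haplotypes) {
  if (inherits(haplotypes, "haplotype_set")) {
    tab <- haplotype_table(haplotypes, min_count = 0)
    haplotypes <- dplyr::distinct(tab[, c("hap_id", "haplotype", "n_total")])
  }
  haps <- haplotypes$haplotype
  if (anyDuplicated(haps)) stop("duplicate haplotype strings; aggregate counts first")
  k <- length(haps)
  if (k < 2) stop("need >= 2 haplotypes")
  al <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  dmat <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dmat[i, j] <- dmat[j, i] <- sum(al[i, ] != al[j, ])
    }
  }
  # minimum spanning network: Kruskal by level, adding every edge of the
  # current weight that joins two components as they stood at level start
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- list()
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  w <- dmat[upper.tri(dmat)]
  for (lev in sort(unique(w))) {
    comp_at_start <- vapply(seq_len(k), find, integer(1))
    lev_pairs <- pairs[w == lev, , drop = FALSE]
    added <- lev_pairs[comp_at_start[lev_pairs[, 1]] !=
                         comp_at_start[lev_pairs[, 2]], , drop = FALSE]
    for (r in seq_len(nrow(added))) {
      i <- added[r, 1]; j <- added[r, 2]
      edges[[length(edges) + 1]] <- tibble::tibble(
        from = haplotypes$hap_id[i], to = haplotypes$hap_id[j], weight = lev)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    if (length(unique(vapply(seq_len(k), find, integer(1)))) == 1) break
  }
  structure(list(
    nodes = tibble::tibble(hap_id = haplotypes$hap_id, haplotype = haps,
                           size = haplotypes$n_total),
    edges = dplyr::bind_rows(edges)
  ), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges, total weight ", sum(x$edges$weight), "\n",
      sep = "")
  invisible(x)
}

#' Chromosome-by-chromosome haplotype sharing matrix
#'
#' Entry (i, j) is the fraction of region sites at which chromosomes i and j
#' carry identical alleles; symmetric with unit diagonal. The input order of
#' chromosomes (sample h1 copies then h2 copies) is preserved in the labels.
#'
#' @param hapset a `haplotype_set`.
#' @return numeric matrix labelled `sample_h1` / `sample_h2`.
#' @export
sharing_matrix <- function(hapset) {
  al <- hapset$alleles
  n <- nrow(al)
  m <- ncol(al)
  s <- matrix(1, n, n, dimnames = list(rownames(al), rownames(al)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <- sum(al[i, ] == al[j, ]) / m
    }
  }
  s
}
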