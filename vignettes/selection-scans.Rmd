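---
title: "Selection-signature scans on multi-breed SNP panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans on multi-breed SNP panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# Scope

`sweepscan` implements the statistical machinery of a whole-genome
selection-signature study in structured livestock populations: genetic
diversity (observed/expected heterozygosity, runs of homozygosity, F~ROH~),
population structure (IBS and pairwise-Fst distance matrices,
neighbor-joining trees, genotype PCA), windowed sweep scans (Weir–Cockerham
Fst, cross-population EHH, locus-specific branch length) with empirical
right-tail candidate calling and region merging, haplotype analysis of
candidate loci (Gabriel LD blocks, breed-stratified haplotype frequencies,
minimum spanning networks, sharing matrices), and interval annotation of
candidate regions against GFF3 gene models and BED peak tracks.

Everything upstream of a genotyped VCF — read alignment, variant calling and
hard filtering, statistical phasing, ancestry estimation with ADMIXTURE-type
programs, GO/KEGG enrichment — is out of scope. Haplotype-based operations
require phased input and refuse "/"-separated genotypes rather than phasing
or imputing.

# The synthetic panel generator

Real multi-breed resequencing panels are large and access-restricted, so the
package ships a generator whose output has *known* truth, making every stage
testable end to end.

**Drift model.** Each site draws an ancestral allele frequency
$p \sim \mathrm{Uniform}(0.05, 0.95)$; each breed $b$ with drift parameter
$F_b$ draws its own frequency from the Balding–Nichols distribution
$\mathrm{Beta}\!\left(p\frac{1-F_b}{F_b},\,(1-p)\frac{1-F_b}{F_b}\right)$,
and haplotypes are sampled i.i.d. Bernoulli within breed. This model was
chosen over coalescent simulation because it has a closed-form expectation
usable as an oracle: the among-breed variance of the drifted frequency is
$F\,p(1-p)$, so the expected pairwise Weir–Cockerham Fst between two breeds
with common $F$ is approximately $F$. The test suite verifies recovery within
0.02 at 20,000 sites.

**Planted structure.** A sweep is planted by overwriting both haplotypes of
every sample in designated breeds with one fixed allele string over the sweep
interval — the limit case of a regulatory haplotype driven to fixation, which
is the signal all three scan statistics must detect. Autozygosity is planted
by copying one haplotype onto the other inside per-sample tracts, giving
literal runs of homozygosity with known boundaries. Missingness is masked
i.i.d. *after* planting, so truth records always refer to the pre-mask state.

**What the generator does not emulate.** Positions are sorted uniform draws
and there is no recombination map: background LD decays with haplotype
diversity rather than with crossover distance, which is sufficient to create
the contrast between a homogeneous swept region and a diverse neutral
background but does not reproduce realistic LD decay curves. There is no
mutation-rate heterogeneity, no allele-frequency spectrum from demography,
and sweeps are hard (fully fixed) rather than partial. Passing the
parameter-recovery tests therefore demonstrates correctness of the
*estimators* under the stated model, not field performance on real genomes.

# Analysis defaults and where they come from

All defaults follow the standard practice for this analysis type and are
overridable everywhere:

* **Site filter**: MAF > 0.05 and call rate > 0.9, both strict; MAF is
  computed from non-missing allele counts (integer arithmetic, so boundary
  sites like 4 alt alleles in 80 compare exactly).
* **ROH** (PLINK `--homozyg` semantics): 50-SNP sliding windows, at most 1
  heterozygous and 5 missing calls per window, SNP joins a run when at least
  5% of covering windows are homozygous (`--homozyg-window-threshold`),
  minimum 100 SNPs and 1 Mb per run, at most 50 kb/SNP density, runs split at
  gaps above 1 Mb. The 1 Mb minimum excludes short LD-driven homozygosity.
  Heterozygote tolerance is applied per window only, not per final segment,
  as in PLINK.
* **F~ROH~** = total ROH length divided by the covered autosomal length
  (per chromosome, last SNP minus first SNP, summed). X/Y/MT are excluded
  from ROH and windowed scans throughout.
* **Windows**: 40 kb sliding windows at 20 kb step, anchored at position 0 of
  each chromosome; a trailing partial window is kept when it contains a SNP;
  windows with no usable SNP are NA and excluded from quantiles.
* **Windowed Fst**: two-population Weir–Cockerham (1984) variance
  components, windowed as ratio of sums (the vcftools "weighted" estimator).
* **XP-EHH**: EHH of a population's full haplotype sample (both core
  alleles pooled), truncated below 0.05 or beyond 1 Mb; iHH is the
  trapezoidal integral over physical distance on both sides; the score is
  ln(iHH~A~/iHH~B~), z-standardised genome-wide, then averaged (signed) per
  window. Truncation is per population, which makes the score exactly
  antisymmetric in the two populations. Missing alleles inside a phased
  extension are treated as a third allele class, which can only break — never
  extend — haplotype homozygosity.
* **LSBL** for focal population A against B and C:
  $(F_{st}^{AB} + F_{st}^{AC} - F_{st}^{BC})/2$, elementwise on one window
  grid; the B and C branches use the permuted formula and branch lengths are
  additive ($\mathrm{lsbl}_A + \mathrm{lsbl}_B = F_{st}^{AB}$).
* **Candidate calling**: empirical 3% right tail with the "higher" quantile
  rule — with $N$ finite windows the threshold is the
  $\lceil 0.03N \rceil$-th largest value and every window at or above it is
  flagged, so the flagged count is exactly $\lceil 0.03N \rceil$ for distinct
  values; ties at the threshold are all flagged and reported.
* **Regions**: windows flagged by *both* Fst and XP-EHH are intersected and
  merged with neighbours that overlap or abut (at step < window, neighbours
  overlap) into maximal disjoint regions, reported with count, total length
  and fraction of the covered autosomal genome.
* **Haplotype table**: total count strictly greater than 2 ("frequency
  greater than 2"), labels `hap_1, hap_2, ...` by descending count with ties
  broken by allele string; per-breed chromosome counts and homozygous-carrier
  counts are reported because homozygous carriage restricted to specific
  breeds is the hallmark of a breed-defining haplotype.

# Design choices that were genuinely open

**Gabriel blocks.** The confidence interval of |D′| is profiled from the
multinomial likelihood of the four observed haplotype counts over a
|D′| ∈ [0, 1] grid at observed allele frequencies (the Haploview approach;
phased data make the EM step unnecessary), reading the 5th/95th percentiles
of the normalised curve. Pairs are "strong LD" at CI bounds ≥ 0.70/0.98 and
"strong recombination" below 0.90; a block needs its outermost pair in
strong LD and ≥ 95% strong-LD among informative pairs. Blocks are accepted
greedily by decreasing physical span with leftmost tie-break — deterministic,
which matters for reproducible pipelines.

**Haplotype network.** A minimum spanning network over Hamming distances
(all MST edges plus every tie-equal alternative at each weight level)
replaces median-joining: it is deterministic, has an exact Kruskal oracle for
testing, and is adequate at the haplotype counts involved. Median vectors
(inferred intermediate haplotypes) are a possible extension.

**NJ input.** Breed trees use raw pairwise Fst as distance (matching the
"NJ tree based on pairwise Fst" convention) rather than linearised
Fst/(1−Fst); sample trees use 1 − IBS similarity. Negative NJ branch
lengths are clamped to zero with a message.

**PCA.** GCTA GRM convention: genotypes centred at $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$, missing values mean-imputed, monomorphic sites
dropped, components signed so the largest-magnitude score is positive. No LD
pruning by default (a pruning step can be applied upstream by subsetting).

**Window XP-EHH sign.** The window value is the signed mean of standardised
per-SNP scores; `absolute = TRUE` gives the |score| variant, since published
descriptions of "averaged XP-EHH" are ambiguous on this point.

**Haplotype-region sample exclusion.** Samples with any missing call in the
analysis region are dropped from haplotype operations rather than imputed
(statistical phasing/imputation is out of scope); the exclusion count is
reported.

# Numerical and degenerate-input behaviour

* Monomorphic sites across both scan populations contribute (0, 0) variance
  components and are flagged; sites with no called genotype in either
  population are NA and excluded from window sums.
* `xpehh()` returns NA when either integrated EHH is zero (degenerate
  haplotype sets), and the genome scan skips cores monomorphic in the
  combined populations.
* `call_candidates()` warns and flags everything when all window values are
  equal; it rejects tails outside (0, 0.5).
* Chromosomes with fewer SNPs than one ROH window are skipped with a
  message, not an error.
* Identical seeds reproduce byte-identical panels, window tracks and run
  directories; the pipeline derives per-stage seeds from the master seed by
  a stable arithmetic hash, so stages are independently reproducible.

# Problem sizes

The bundled demo configuration simulates 4 breeds × 12 samples on a 2 Mb
chromosome at 1 SNP/kb with a 100 kb sweep in the TEB-like breed — large
enough that the sweep spans several windows and the empirical tail is
non-trivial (~100 windows), small enough that the full pipeline runs in a
few seconds. Parameter-recovery tests use 20,000 sites for drift estimation
and 20 seeded replicates of the demo scan for sweep recovery; oracle
equivalence tests run on instances of at most a few hundred SNPs where
exhaustive enumeration is fast.

# Known limitations

* XP-EHH integrates over physical distance; genetic-map support is limited
  to a constant rate by rescaling positions upstream.
* iHS, nSL, composite-likelihood scans and Tajima's D are not implemented.
* The Gabriel CI uses the profiled likelihood at observed allele
  frequencies, not the joint likelihood over frequencies; with very few
  chromosomes the CIs are conservative.
* Gene overlap is any-overlap of the gene span (optionally flanked); no
  promoter/UTR modelling.
* The annotation module handles one transcript per CDS SNP (the first
  overlapping transcript); overlapping isoforms with conflicting
  consequences are not ranked.

# A minimal end-to-end run

```{r, eval = FALSE}
dir <- tempfile("demo")
run_pipeline(list(seed = 3), dir)
pipeline_report(dir)
```

The report prints the per-breed diversity table (breed, n, Ho, He, F~ROH~),
the candidate-region summary (count, total length, fraction of covered
autosomes) and the haplotype frequency table of the top candidate region —
the three headline tables of this analysis type.
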