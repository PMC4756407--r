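---
title: "fripflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fripflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: what
each method assumes, which knobs matter, what the synthetic-data generator
does and does not emulate, and the places where the design was genuinely
open and a choice had to be made.

## The measurement model

fRIP-Seq compares an immunoprecipitated (IP) RNA library against a matched
input library. The package works from fragment counts per feature. Abundance
is expressed in FPKM (fragments per kilobase of feature per million mapped
fragments). Two normalization details matter more than they look:

* **Composition-corrected depth.** IP libraries spend a large share of
  their depth on long unspliced pre-RNA features, so raw per-million
  scaling shifts every fold change by a library-composition factor, and a
  pseudocount then converts that global shift into a spurious
  abundance-dependent trend. All fold-change paths therefore compute FPKM
  against TMM effective library sizes (`effective_library_sizes()`,
  `effective_gene_fpkm()`). The consequence — shared with any relative
  normalization — is that fold changes are centered on the typical gene:
  a uniform, panel-wide enrichment is not identifiable.
* **Pseudocount.** Fold changes are `log2((FPKM_IP + c)/(FPKM_input + c))`
  with `c = 1` FPKM by default. The pseudocount stabilises low-abundance
  genes at the cost of shrinking their fold changes toward zero; analyses
  of abundance dependence must keep this attenuation in mind.

### The enrichment test

Cuffdiff-style isoform-resolved differential testing is out of scope; the
package substitutes a replicate-aware negative-binomial test that is small
enough to verify by simulation:

1. counts are size-normalized;
2. a single NB dispersion is pooled across genes by method of moments from
   *within-condition* variances (so genuine enrichment does not inflate
   it). The pooled estimate solves `v = m + phi * m^2` by iteratively
   reweighted least squares with weights `1/(m + phi m^2)^2` — the inverse
   sampling variance of a per-gene variance estimate. Unweighted pooling
   lets the few largest genes dominate and produced dispersion estimates
   scattered by a factor of three in simulation; the IRLS estimator is
   stable to about two percent at 2,000 genes;
3. each gene gets a two-sided NB likelihood-ratio test (edgeR GLM at the
   pooled dispersion). The LRT was chosen over the classical exact
   conditional test after calibration runs: with an accurate pooled
   dispersion the exact test stays conservative at low counts (type-I
   0.045 at a nominal 0.05 over twenty null simulations), while the LRT
   sits at 0.052 — the closest to nominal of every variant tried
   (exact, quasi-likelihood, Wald on log counts, moderated t);
4. genes below the testability filter — FPKM ≥ 1 in at least one sample —
   are flagged untested and excluded from BH correction. The threshold is
   a config value (`min_fpkm`); 1 FPKM is a conventional proxy for "high
   enough to test".

A gene is called **bound** when q < 0.05 *and* at least one IP replicate is
more than 2-fold over the mean input. Both constants are config values; the
2-fold arm protects against statistically significant but tiny shifts at
high depth.

## Augmented annotations

`add_prerna_isoforms()` appends one single-exon isoform per unique
(start, end) span over a gene's spliced isoforms — "unique pair", not the
cross-product of starts with ends, the more conservative reading.
`add_intron_isoforms()` adds one isoform per intron, extended to include
both flanking exons, duplicates collapsed. Coordinates are 0-based
half-open in memory and 1-based inclusive in GTF, so round trips are
bit-exact. Strand affects only which end is called the TSS; interval
arithmetic is strand-agnostic. Genes are treated independently even when
they share coordinates.

`exonic_contribution()` is the percentage of gene FPKM on spliced isoforms;
it is invariant under uniform rescaling of FPKM and undefined (NA) for a
gene with zero total FPKM.

## Binding profiles

* **Hierarchical clustering**: Pearson correlation distance (1 − r) with
  Ward linkage (`ward.D2`). Zero-variance rows have undefined correlation;
  they are assigned distance 1 to everything rather than erroring.
* **k-medoids**: PAM with Euclidean distance, k = 10 by default, run from
  the deterministic build start plus ten seeded random restarts keeping the
  best objective (the classical initialization is not specified anywhere;
  restarts cost little and remove the dependence on it). Input is the
  bound-gene fold-change matrix.
* **Specificity**: profiles must be non-negative, so log2 fold changes are
  linearized as `max(log2FC, 0)` before scoring — negative values mean
  depletion, not binding. Whether the original metric was computed on fold
  changes or abundance-like estimates is not recoverable; the transform is
  exposed rather than hidden (`linearize_enrichment()`).
* **Abundance matching** uses 20 equal-width log10-FPKM bins over the
  combined range and samples candidates to the target's bin frequencies at
  the largest feasible size; target mass in bins with no candidates is
  dropped with a warning.
* **Mann–Whitney comparisons** report the tie-corrected normal Z (sign
  positive when the first set is stochastically larger). The p-value is
  exact for small samples — the Wilcoxon null distribution when tie-free,
  full enumeration when tied and feasible — because the plain normal
  approximation misses an exact oracle by up to 0.015 at n ≈ 8, and the
  package promises agreement to 0.01.
* **Metagene profiles** rescale each transcript's coverage to unit mean,
  bin to 100 positional bins, and average; the bias index is
  `log2(last quartile / first quartile)`. Transcripts shorter than the bin
  count are linearly interpolated; zero-coverage transcripts are excluded
  and counted.

## Structure preferences

Length and exon number are strongly correlated in any realistic annotation,
so marginal correlations cannot attribute binding to one or the other. The
semipartial correlation regresses the fold change on the controlled
attribute by ordinary least squares (a rank-based variant is exposed via
`rank_based = TRUE`; the regression form is otherwise unspecified) and
rank-correlates the residual with the tested attribute. The abundance trend
uses `stats::lowess` with span 0.3 evaluated on an even log10-FPKM grid;
span is a config value, and any monotone-respecting smoother would serve.

## Sequence preferences

The seed-size rule restricts transcripts to within √10 of the median length
(closed bounds — boundary handling is unstated elsewhere, and closed bounds
keep the max pairwise ratio at exactly 10) and returns the smallest k whose
chance-occurrence probability at the window's **upper** bound is below 1 %,
with the Poisson-clumping approximation `1 − exp(−(L−k+1)/4^k)` under
uniform base composition. Evaluating at the upper bound is the only reading
that yields 10-mers from a 1997-nt median (the median itself gives k = 9);
the probability model is validated against Monte-Carlo sequence simulation
in the test suite.

Motif discovery discretizes the statistic into three equal-population bins
(the bin count for continuous statistics is a config value), scores every
k-mer seed by mutual information, and assesses significance by permuting
the statistic across genes: a per-seed z-score and an empirical FDR over
the whole k-mer family (expected permuted exceedances over observed
exceedances at each MI threshold, made monotone). Per-seed permutation
p-values BH-corrected across 4^k seeds are useless here — their resolution
floor is 1/(n_perm+1) — which is why the family-level FDR is the
significance currency. Surviving seeds are greedily generalized over IUPAC
codes, one base addition at a time, accepting a step only while the mean MI
over three held-out thirds increases. The full FIRE robustness machinery
(jackknife robustness scores, over-representation profiles) is deliberately
not reproduced; recovery and dose–response are the properties exercised.
Occurrence counting is sense-strand only (RNA) with overlaps allowed.

The k-mer ridge regression standardizes k-mer counts per kilobase and fits
ridge weights over a penalty grid chosen by five-fold cross-validated MSE,
reporting held-out variance explained. A scale caveat: with fewer genes
than features (4^k), L2 regression cannot isolate a single sparse driver —
recovery of a planted k-mer driver with variance explained near 1 holds in
the n ≫ 4^k regime (verified at k = 4 with 600 genes), while at k = 7 the
feature space outnumbers any desk-scale gene set and held-out variance
explained is the honest casualty.

TE association compares fold changes of transcripts containing versus
lacking each family × orientation (Mann–Whitney Z, BH across tests),
requiring at least 20 containing transcripts.

## Chromatin linkage

Promoter windows are 3 kb centered on the strand-aware TSS; body windows
are the transcript span. Region scores are
`log2((chip + 1)/chip_total) − log2((input + 1)/input_total)` — one read
per window as pseudocount, applied before depth normalization — and gene
scores are FPKM-weighted means over isoforms. Pre-aggregated per-window
scores (e.g. RRBS promoter methylation fractions) pass through the same
interface; no bisulfite processing is implemented.

The lowess gap fits score-versus-log10(FPKM) within bound and unbound
genes separately (span 0.3, 2 robustness iterations; the smoother's
parameters are config values) and averages the curve difference over *all*
genes' abundances — i.e. the difference integrated against the empirical
FPKM distribution, which weights likely abundance levels most. A kernel
density estimate would be the alternative weighting; the empirical
distribution is used because it is exactly "the mean over observed genes"
with no bandwidth to choose. Curves are clamped to their boundary fit
outside a group's observed range to avoid extrapolation artifacts. The
permutation p shuffles bound labels (500 permutations by default), which
preserves the score–abundance relationship under the null.

## The synthetic-data generator

The generator is the package's ground-truth instrument. It emulates, per
gene: log-normal transcript lengths (median 1997 nt, sdlog 0.9); exon
counts coupled to length (1 + Poisson with rate `min(L, 10 kb)/250` times a
log-normal factor of sdlog 0.4, giving the ~0.85 length–exon rank
correlation real annotations show while retaining genuine exon variation at
fixed length); log-normal input abundance (meanlog 1, sdlog 1.5 in FPKM
units) with lncRNAs shifted down one decade; true per-protein log2
enrichment linear in log10 abundance, exon count, log10 length and
implanted motif count plus Gaussian noise (default SD 0.5 — replicate noise
magnitude is a free parameter, chosen as a mid-range value for IP-grade
libraries), clamped to ±8 log2 (256-fold, the realistic dynamic range; the
clamp also keeps NB means finite under heavy-tailed covariates); an
`intron_fraction` of IP FPKM assigned to the pre-RNA isoform; and
negative-binomial replicate counts (dispersion 0.05, typical of cell-line
RNA-seq) at a default depth of 2 × 10⁷ fragments. Fragments are simulated
per isoform and FPKM is recomputed through `compute_fpkm()`, so simulations
exercise the same quantification path as real data. Chromatin scores are
linear in log10 abundance with an additive shift on bound genes.

What it does **not** emulate: read-level artifacts (no FASTQ, no alignment
or GC bias), isoform diversity beyond one spliced isoform per gene,
positional coverage biases within the counting model, correlated noise
across proteins, or batch structure. Passing recovery tests therefore
demonstrates that the statistics recover the effects they target under the
stated noise model — not robustness to mapping artifacts or annotation
error in real data.

Determinism: every stochastic function takes a seed and restores the
global RNG state afterward; the pipeline derives stage seeds from one
master seed, and identical configurations reproduce byte-identical
reports.

## Numerical and edge-case conventions

* Degenerate inputs return sentinels rather than errors where the spec of
  the quantity allows it: zero-FPKM exonic contribution → NA; all-zero
  specificity profile → NA; all-tied Mann–Whitney → Z = 0; too-few genes in
  the lowess gap → NA with group counts.
* Dispersion estimates are floored at 1e-4; with no replicated condition a
  fallback dispersion of 0.1 is used with a warning.
* Equal-population binning breaks ties by first occurrence
  (`rank(..., ties.method = "first")`), making MI invariant to bin
  relabeling and deterministic under ties.
* The pooled-dispersion IRLS runs a fixed three iterations — convergence
  is geometric and further iterations change nothing at test precision.

## Problem sizes used by the test suite

The suite validates calibration at 20 × 2,000 genes × 3 replicates (null
type-I error), structure recovery at 5,000 genes, motif recovery at 1,500
genes with 200 permutations, chromatin-shift recovery at 2,000 genes with
500 permutations, and pipeline determinism at 300 genes — sizes at which
every property above is statistically decidable on a single core in
minutes.

## Known limitations

* Gene-level testing only; isoform-level differential deconvolution is a
  non-goal.
* The specificity metric depends on the chosen linearization of fold
  changes; alternatives (e.g. abundance-scaled binding estimates) would
  shift absolute scores, though not the lncRNA-versus-mRNA ordering the
  tests check.
* Functional-term enrichment of clusters, CLIP peak calling, conservation
  scoring and external-dataset comparisons are out of scope.
* The NB test's calibration is demonstrated under the generator's noise
  model; strongly gene-specific dispersion (not pooled) would call for
  per-gene shrinkage estimators instead.
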