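---
title: "Methods: cfDNA 5hmC peaks, fragmentation profiles and the integrated classifier"
author: "hmcfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA 5hmC peaks, fragmentation profiles and the integrated classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic-cohort generator does and does not emulate, and the
design choices made where the method description left room.

## 1. The two signals

Cell-free DNA circulates predominantly as mono-nucleosomal fragments with
a length mode near 167 bp. In 5hmC-enriched (hMe-Seal-style) libraries,
two layers of information separate cancer patients from healthy donors:
locus-level hydroxymethylation strength, and the genome-wide balance of
short (80–150 bp) versus long (151–250 bp) fragments. The package turns
both into sample-by-feature matrices and trains penalized logistic
classifiers on them.

## 2. Peak features

Per-sample MACS2 summits are extended ±100 bp into 201-bp fixed-width
peaks (`fixedWidthPeaks()`, `half_width = 100`). Raw peak scores are
normalized to score-per-million within each sample (`scorePerMillion()`),
making peak strength comparable across sequencing depths; by construction
each sample's spm values sum to 10^6.

Overlap removal (`removeOverlaps()`) is greedy by descending spm with
ties broken by (chromosome, start): the method description says only that
overlapping peaks are removed, so we adopt the fixed-width-peak
convention — deterministic, order-independent, and idempotent. Abutting
half-open intervals do not overlap.

Group-level reproducibility (`reproduciblePeaks()`): pooled per-sample
peaks are candidates; a sample supports a candidate when any of its peaks
with spm ≥ 5 overlaps it by ≥ 1 bp (support is defined by overlap because
per-sample summits at the same locus jitter). Candidates supported by at
least `ceiling(0.10 · n)` samples survive — "at least 10 %" on an integer
sample count. Survivors are de-overlapped preferring higher support, then
higher mean spm. Cancer- and healthy-specific lists are merged and
de-overlapped again (`consensusPeaks()`), and `filterPeaks()` drops peaks
in the exclusion blacklist, peaks running past chromosome ends (including
those pushed to negative coordinates by the summit extension) and peaks
on chrX/Y/M.

Quantification (`quantifyFpkm()`) counts a fragment into a peak when they
overlap by ≥ 1 bp (midpoint counting is available via
`countMethod = "midpoint"`); fragments were chosen as the counting unit
because the data are paired-end and the fragment is the analysis unit
everywhere else. FPKM(s,k) = C(s,k) / (width_kb(k) · library(s)/10^6)
with the library size equal to the sample's total fragment count.

## 3. Differential hydroxymethylation

`differentialLoci()` tests each consensus peak with a two-sided Wilcoxon
rank-sum test using the tie-corrected normal approximation — the test is
not named in the method description, and the rank-sum test matches the
distribution-free treatment used for score comparisons elsewhere. The
fold change is `log2((mean_cancer + 1) / (mean_healthy + 1))`; the
pseudocount of 1 FPKM (configurable) guards unobserved loci and is
negligible at typical FPKM magnitudes (10^3–10^4 in simulated data).
Benjamini–Hochberg is the adjustment ("adjusted p" is not otherwise
specified, and BH is the field default). A locus passes at
`p < 0.001`, `adjusted p < 0.05`, `|log2FC| ≥ 0.5`. In the pipeline the
test runs on training samples only, keeping the validation set untouched
by any feature-level decision.

## 4. Fragmentation profiles

The genome is tiled into 100-kb bins (`binGenome()`); incomplete terminal
tiles and bins touching the exclusion blacklist are dropped, and each
bin carries the length-weighted mean GC of the genome's GC track.
Mappability filtering is folded into the blacklist input because
synthetic genomes have no mappability track.

`countShortLong()` assigns each fragment to the bin containing its
midpoint (integer division, so even-length ties go to the lower
coordinate) — one bin per fragment, each fragment counted exactly once.
Lengths 80–150 are short, 151–250 long (both inclusive); "total" counts
lengths in [80, 250], the union of the two classes, since no other
definition is stated; all three ranges are configurable.

GC correction (`gcCorrect()`) fits `stats::lowess` (span 0.75, 3
robustness iterations) of counts versus GC separately per fragment class
and per sample, at 100-kb resolution, before any window aggregation. The
corrected value is `count − fitted + mean(fitted)`: re-centring by the
mean of the fitted curve (rather than the raw mean, from which it differs
by a vanishing constant) preserves the per-sample mean coverage exactly.
The constant is immaterial downstream because features are z-scored per
sample. With constant GC the correction is the identity; with fewer than
10 bins it refuses to fit.

`aggregateWindows()` groups each chromosome's bins, in positional order,
into consecutive runs of `window_width / bin_width` bins (50 by default),
dropping an incomplete trailing run — fixed-width windows, even when
blacklisted bins leave gaps. Corrected short/total coverages are summed
per window; RoSL = Σshort/Σlong from raw counts, flagged missing when a
window has no long fragments. The median healthy profile is the
per-window median RoSL across healthy training samples (even counts:
mean of the two middle values; missing values excluded), and
`profileCorrelation()` is the plain Pearson correlation over shared
non-missing windows (≥ 3 required; zero variance is an error, not a 0).
`fragmentationFeatures()` z-scores each sample's short and total window
vectors separately, yielding 2 × n_windows features named
`short@window` and `total@window`.

## 5. Stability selection and the final fit

`splitCohort()` makes a stratified 4:1 train/validation split (class
balance within one sample). `stabilitySelect()` then:

1. splits the training set into five stratified crosses;
2. in each cross, runs 100 elastic-net logistic fits on the other four
   folds, each on a fresh stratified 80 % subsample — the description
   does not say what varies across the "100 repeats", and random
   subsampling is the stability-selection convention;
3. chooses λ per fit by internal 3-fold cross-validated deviance over a
   30-point path (fixing a λ grid per repeat would multiply runtime for
   no benefit; the outer grid's α governs the final fit);
4. keeps features with nonzero coefficients in ≥ 95 % of a cross's
   repeats, and finally features kept in ≥ `min_crosses` crosses.

`min_crosses` defaults to 4 for the 5hmC model and 5 for the
fragmentation model; the two documented values disagree for 5hmC
("at least one cross" versus "at least 4 crosses"), so the cutoff is a
parameter and the default follows the stricter, reported panel. The
selection-time mixing parameter is a single α (default 0.5,
configurable); the final fit performs the documented grid search.

`fitFinal()` grid-searches α ∈ {0.05, …, 1} × λ ∈ 10^[−5, 0] (50
log-spaced points) by mean cross-validated AUC on the training set
(fivefold; tenfold and α from 0 for the integrated model), refits on the
full training set at the winner, and resolves grid ties toward larger λ,
then smaller α — sparser and smoother models first. The fold count is
capped at the minority-class size so every held-out fold contains both
classes. Coefficients are reported on the original feature scale
(standardization is internal to glmnet), so the weighted diagnosis score
is literally `wd = Σ coef(k) · feature(k)` with no intercept; the
intercept would only shift all scores and cannot change ranks, AUC, or
any threshold decision made on the same scale.

`integrateModels()` concatenates the marker-restricted FPKM block (raw
FPKM, as the wd-score formula implies) and the fragmentation block (per-
sample z-scores) without renormalizing either. When stability selection
returns nothing (null data), the pipeline builds an intercept-only model
that scores every sample 0 — chance-level AUC by the tie rule — rather
than failing; `fitFinal()` itself still rejects an empty marker set.

`evaluateModel()` computes AUC by the Mann–Whitney rank formulation with
half credit for ties, and sensitivity/specificity at the threshold
maximizing Youden's J on training scores (ties toward the larger
threshold), applied unchanged to validation scores — standard practice
that avoids validation leakage, as no threshold policy is documented.

## 6. The synthetic-cohort generator

The generator exists so every downstream stage has inputs with the
statistical structure the analysis assumes; the original cohort is not
openly deposited. A `SyntheticGenome` (default 2 × 20 Mb, 100-kb track
windows — small enough that a full run takes about a minute) carries
three smooth AR(1) tracks:

* `gc` — drives fragment placement via the weight
  `max(0.05, 1 + gc_bias_strength · (gc − mean gc))`, a monotone bias for
  the LOWESS correction to remove (Poisson-thinning style);
* `shortness` — modulates the baseline short-fragment probability
  (`base_short_prob · exp(0.8 · shortness)`, clamped), giving healthy
  fragmentation profiles genuine regional structure shared across
  samples. Without it, healthy RoSL profiles would be exchangeable noise,
  the median healthy profile would be meaningless, and a spatially
  uniform cancer excess would cancel out of the per-sample z-scored
  features;
* `aberration` — concentrates the cancer-specific excess: cancer samples
  move `short_excess_cancer` of fragment mass (in expectation over the
  placement distribution) into the 80–150 bp range, weighted by
  `exp(aberration)` across windows.

Fragment lengths mix a discretized normal (mode 167 bp, sd 10) with a
uniform short component on [80, 150] — the published evidence is an
empirical length distribution, not a generative law, and this mixture
reproduces its two salient features (the mono-nucleosomal mode and the
cancer short excess). A `peak_fraction` (0.3) of fragments is drawn from
120 fixed peak loci; in cancer samples the draw weight of the 20
differential loci is scaled by `2^effect_log2fc`, as are their summit
scores, so the 5hmC effect appears in both the summit files and the
FPKM matrix. Summit scores are integers (MACS2-like); their absolute
scale is irrelevant after spm normalization. Each sample also receives
20 private low-score noise summits that the reproducibility filter is
expected to remove. All randomness derives from one root seed through
fixed offsets; identical inputs give byte-identical files.

Default effect sizes (log2FC 2 at 20 of 120 loci; 10 % short excess;
40 samples per arm at 20,000 fragments) are chosen for testability at
desk scale: they are large relative to sampling noise at this depth, so
the pipeline's validation AUCs saturate at 1 and recovery tests have
headroom. What the generator does **not** emulate: real read-level
artifacts, mappability structure, batch effects, biological inter-sample
heterogeneity beyond the modelled tracks, stage/subtype structure, and
realistic feature dimensionality (hundreds of thousands of peaks,
hundreds of windows). Passing tests therefore demonstrate the
correctness and calibration of the computations, not clinical
performance on real cohorts.

## 7. Numerical conventions and degenerate inputs

* Coordinates are BED (0-based half-open) on disk and `GRanges` (1-based
  closed) in memory; conversion happens only in the readers/writers.
* Overlap always means ≥ 1 bp; abutting half-open intervals do not
  overlap.
* All-zero peak scores cannot be spm-normalized (error); empty marker
  panels score 0; constant features test at p = 1 with log2FC 0; RoSL
  with no long fragments is missing, and missing windows drop out of
  medians and correlations.
* Grid ties in the final fit prefer larger λ then smaller α; equal-spm
  overlaps prefer the smaller start; Youden ties prefer the larger
  threshold.
* Every stochastic step derives a child seed from the root seed by fixed
  offsets (kept below 2^31); runs are single-threaded and reproducible
  byte for byte from (config, seed, package version).

## 8. Problem sizes used in the test suite

Unit tests run on toy instances (tens of intervals, ≤ 10^4 fragments).
The end-to-end recovery and null-calibration checks simulate ten cohorts
each at the default study conditions (40/arm, split 0.75 into 30/arm
training and 10/arm validation — the stated evaluation design), and the
determinism check runs the bundled demo configuration twice. These sizes
were chosen once, as the package's own evaluation design, so the whole
suite completes in well under half an hour on a single CPU.

## 9. Known limitations

* The FPKM counting unit (fragments, any-overlap) and the "total"
  fragment-class range are conventions where the method description is
  silent; both are configurable.
* The stability-selection subsampling scheme and selection-time α are
  package choices (see §5).
* Sensitivity/specificity depend on the Youden threshold policy;
  AUC does not.
* The generator's effect-size defaults favour testability over realism;
  absolute metric values on synthetic data (e.g. AUC = 1) say nothing
  about performance on real cohorts.
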