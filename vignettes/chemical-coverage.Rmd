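---
title: "Measuring and planning chemical diversity coverage in natural product libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and planning chemical diversity coverage in natural product libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemcov)
```

## The problem

Natural product screening libraries are usually assembled opportunistically:
isolates are collected, cultured and extracted without a quantitative notion
of how much *new* chemistry each additional isolate contributes. chemcov
treats library construction as a coverage problem. Isolates are partitioned
two ways — genetically (clades from a barcode phylogeny, consumed here as
labels) and chemically (clusters from their LC-MS metabolome) — and the
accumulation of distinct chemistry with collection size is modeled with the
incidence-based machinery of community ecology: a chemical feature detected
in an isolate plays the role of a species detected at a site.

Two units of chemistry are supported. A **feature** is a deconvoluted LC-MS
component identified by its (m/z, retention time) pair. A **scaffold** is a
connected component of a modified-cosine molecular network over the
features' MS/MS spectra — a proxy for a shared carbon skeleton, which
matters because biosynthetic pathways emit families of related analogs
rather than single compounds.

## Preprocessing model

The pipeline order is fixed: blank filtering, total-ion-current (TIC)
normalization, replicate merging, binarization.

* **Blank filtering** is categorical by default: a feature with any nonzero
  peak area in any extraction blank is removed outright. This is the
  strictest reading of "present in controls and samples"; an optional
  fold-change rescue (`mode = "fold"`, keep when max culture area is at
  least `fold` times the max blank area) is provided but off by default,
  since a ratio rule cannot be justified from presence/absence wording
  alone.
* **TIC normalization** divides each sample column by its total ion
  current. It precedes replicate merging because the TIC is a property of a
  single injection, not of an isolate.
* **Replicate merging** has no canonical answer when only duplicate
  cultures are stated. The default takes the mean of the normalized
  replicate columns (and renormalizes), which preserves quantitative
  Bray-Curtis structure; a `union` mode (per-feature maximum) is available
  for purely presence/absence work. Tests and defaults use `mean`.
* **Binarization** uses threshold 0: after blank filtering, any detected
  peak counts as presence. The threshold is exposed because instrument
  noise floors differ; presence sets shrink monotonically as it rises.

## Chemical partitioning

Isolate dissimilarity is Bray-Curtis on the TIC-normalized, replicate-merged
abundances, `d = sum|x - y| / sum(x + y)` — computed on quantitative, not
binarized, data, since relative intensity carries real signal about
chemotypes. Ordination is classical PCoA (Gower double-centering and
eigendecomposition); because Bray-Curtis is non-Euclidean, negative
eigenvalues can occur. They are dropped, not corrected (no Cailliez or
Lingoes constant), and flagged in the result so the choice is auditable.

Clusters come from an average-linkage (UPGMA) tree cut at every candidate
`k`, scored by the mean silhouette width computed from the same distance
matrix; the `k` maximizing mean silhouette wins, with ties broken toward
smaller `k` (parsimony). The linkage is a parameter: UPGMA is assumed as
the common default of the ordination toolchains used for this kind of data,
not dictated by theory.

Group separation is tested by one-way PERMANOVA with the pseudo-F
decomposition of squared distances and label permutation. The p-value uses
the add-one convention `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` so the
observed statistic is a member of its own reference set and `p` can never be
exactly zero — at 999 permutations the floor is 0.001.

## Richness, rarefaction and coverage targets

Per-isolate richness is the column sum of the incidence matrix; group
differences are tested by one-way ANOVA with pairwise Tukey HSD using
Tukey-Kramer standard errors (clade sizes are very unequal). Balanced
subsampling (`balanced_subsample()`) draws an equal number of isolates from
every sufficiently large group to confirm that richness differences are not
sample-size artifacts; smaller groups are kept whole.

The accumulation machinery is incidence-based with `T` isolates, per-item
incidence frequencies `T_i`, and uniques/duplicates `Q1`/`Q2`:

* **Interpolation** uses the exact hypergeometric expectation
  `E[S(t)] = S_obs - sum_i C(T - T_i, t) / C(T, t)`, evaluated with
  log-space binomial coefficients (stable for `T` in the hundreds). A
  resampled collector's-curve mean is retained purely as a cross-check; the
  analytic form removes Monte-Carlo noise from the coverage solver.
* **Extrapolation** uses the incidence-based Chao2 estimate of unseen
  richness, `Q0 = ((T-1)/T) Q1^2 / (2 Q2)` (bias-corrected form when
  `Q2 = 0`), and
  `S(T + t*) = S_obs + Q0 [1 - (1 - Q1/(Q1 + T Q0))^t*]`, out to an
  endpoint of 500 isolates by default.
* **Coverage targets** solve, for each fraction `p`, for the smallest `t`
  with `E[S(t)] >= p * S_obs`. Coverage is defined against the *observed*
  total of the dataset or group, not the Chao2 asymptote: with singletons
  present the interpolated curve reaches `S_obs` only at `t = T`, which is
  the behavior a collection planner actually faces.
* **The end slope** `E[S(T)] - E[S(T-1)]` reduces algebraically to `Q1/T`,
  the rate at which the last isolate still contributes unique chemistry; a
  small value means the group is near saturation.

## Scaffold consolidation

The modified cosine scores two spectra by matching fragment peaks either
directly or offset by the precursor mass difference, on square-root-scaled,
unit-normalized intensities. Matching uses a greedy one-to-one assignment in
descending intensity-product order rather than optimal bipartite matching:
it is deterministic, standard practice in networking tools, and the
difference is immaterial at the tolerances used (documented approximation).
Network edges require score ≥ 0.7, ≥ 6 matched peaks, and mutual top-10
rank; these are conventional feature-based-networking defaults, all exposed
in the API since the original acquisition parameters for any given dataset
may differ. Maximum-component-size splitting (used by some networking
servers to break up giant components) is deliberately not implemented; it
does not change component counting on data at this scale. Connected
components are the scaffolds; scaffold-level incidence is the union of
member-feature presence per isolate, with singleton scaffolds flaggable and
removable.

## Reporting conventions

Venn partitions assign each item to the exact subset of groups containing
it; "core" is the all-groups subset. Percentages are rounded half away from
zero at one decimal — the convention that reproduces printed percentages in
published tables (e.g. 539/1,661 → 32.5, where round-half-even would give
32.4). In ordered group-wise accumulation the final increment absorbs the
rounding residue so the cumulative column prints exactly 100.0; unrounded
values are emitted alongside.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces the full data bundle with known ground truth.
Its defaults describe a stylized collection modeled on a real-world scale:
198 isolates in 5 clades of sizes 111/30/25/18/14, duplicate cultures,
6 blanks, a 30-feature core pool, clade-specific pools of 150/120/80/70/100
features, 60 features shared by random clade pairs, and isolate-singleton
features injected until they are 18% of the final feature set. Two planted
genetics/chemistry mismatches make the clustering problem non-trivial: clade
V hides two chemotypes (so the true cluster count is 6), and isolates in
clades U and X are, with probability 0.05, reassigned the chemotype of
cluster 2 ("embedded" members). One chemotype is geographically restricted
to a western bounding box; the rest span the full study area.

Deliberate simplifications, each chosen to make a statistic exactly
recoverable or a filter exactly verifiable:

* Singletons are injected post hoc as one-isolate features rather than
  emerging from detection noise, so the 18% fraction is a controllable,
  recoverable parameter.
* Blank-background features appear in *every* blank (not probabilistically),
  so the strict blank filter must remove exactly the ground-truth artifact
  set.
* Abundances are log-normal around per-feature characteristic levels
  (log-sd 1.5 across features) with isolate-level (0.4) and replicate-level
  (0.2) log-scale variation — features span orders of magnitude, isolates
  vary moderately around their chemotype's profile, as in real peak-area
  data.
* Spectra are scaffold templates (12-18 peaks) with at most 3 peaks shifted
  by the member's precursor offset plus 2 faint noise peaks, guaranteeing
  at least 6 alignable peaks between members of a scaffold and essentially
  none across scaffolds.
* Geography is a uniform draw inside a per-cluster bounding box; there is
  no spatial autocorrelation model.
* The detection model produces almost no incidence-2 features under the
  default pool sizes (`Q2` near 0), so Chao2 takes its bias-corrected
  branch on the full synthetic dataset; real feature tables have smoother
  incidence distributions.

Consequently, passing recovery tests demonstrates that the estimators and
the clustering machinery behave correctly under the assumed statistical
structure; it does not validate chromatographic alignment, adduct handling,
retention-time drift, or any other acquisition-level artifact, all of which
are upstream of this package's inputs.

The split strength between the hidden chemotypes (`split_overlap`, default
0.05: 5% of the split clade's pool is shared by both chemotypes) is exposed
as a parameter because the underlying biology does not pin it down; the
default was fixed, together with the pool sizes above, as the weakest
separation at which silhouette selection reliably identifies the true
cluster count across seeds — the property the generator is required to
have to be useful for validation.

## Numerical choices and degenerate inputs

* Binomial coefficients in the rarefaction expectation are computed in log
  space; `C(n, k)` with `k > n` contributes exactly zero.
* The coverage solver compares against `p * S_obs` with a `1e-9` relative
  guard so floating error cannot push the `p = 1` answer past `T`.
* Both all-zero vectors given to `bray_curtis()` raise `undefined-distance`
  rather than returning `NaN`; all-zero feature rows are dropped (and
  counted) at binarization; all-zero sample columns abort TIC
  normalization.
* Silhouette selection refuses inputs with all-zero distances or fewer
  than 3 samples; within-group variance identically zero everywhere aborts
  the richness ANOVA.
* `permanova()`, `balanced_subsample()`, `collector_curve()` and the
  generator take explicit seeds and restore the caller's RNG state, so the
  same inputs always produce the same outputs without side effects.

## Problem sizes used in the test suite

Unit tests run on a 3-clade, 40-isolate configuration (~150 features);
recovery and calibration checks run the full 198-isolate default across 5
seeds, 1,000-permutation collector means, 200 brute-force rarefaction
oracles (T ≤ 8, where exhaustive subset enumeration is exact), and 500
label-shuffled PERMANOVA null datasets at 99 permutations each. These sizes
were chosen so every claim is backed by an exact oracle or a planted truth
while the whole suite completes in about a minute.

## Known limitations

* Clade labels are consumed as given; no phylogenetic inference or
  sequence handling is included.
* Only richness (Hill order q = 0) is modeled; no abundance-weighted
  diversity or coverage-standardized comparison.
* Scaffold networking scores all spectrum pairs (O(n²)); at tens of
  thousands of spectra a blocked or indexed implementation would be needed.
* The fold-change blank rescue and the `union` replicate merge are provided
  but untested against any published convention, because none is stated for
  this workflow.
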