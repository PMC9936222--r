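---
title: "Sex-specific PET radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific PET radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Amino-acid PET (e.g. ¹¹C-methionine) is an established metabolic imaging
modality in glioma work-up, and radiomic features of the tracer-avid lesion
carry information about molecular markers such as the IDH1 mutation, the
key prognostic stratifier of astrocytic tumours. Two questions shape this
package: do female and male glioma patients present different radiomic
profiles, and does tumour-to-background (TBR) normalization — dividing
lesion SUVs by the mean uptake of a contralateral normal-brain reference
region — change which features discriminate IDH-mutant from IDH-wildtype
disease? Because feature distributions, not prediction models, are the
object of interest, the pipeline deliberately stops at feature ranking and
distributional inference; no classifier is fitted.

`petrad` implements the full analysis as composable, tested stages:

1. **Cohort ingestion or simulation** — per-patient SUV volume, lesion
   mask, contralateral background mask, and sex/IDH labels.
2. **Eligibility filter** — lesions below a minimum voxel count are
   excluded (texture matrices are unstable on tiny ROIs).
3. **Feature extraction** — 154 IBSI-conform features per lesion, in an
   SUV and a TBR configuration sharing one code path.
4. **Redundancy reduction** — correlation clustering at |r| > 0.85 with
   highest-variance representatives, independently per dataset.
5. **Aligned Monte-Carlo resampling** — 100 train/holdout splits per
   labeling (sex, IDH), holding out one patient per class, identical
   splits for the SUV and TBR tables.
6. **Fold diagnostics** — Tomek-link borderline and isolation-forest
   outlier scores per training subset.
7. **Ranking and inference** — per-fold R² ranking, occurrence counting,
   a strict >90% occurrence rule, and Bonferroni-corrected Mann–Whitney
   confirmation on the full cohort.

## Feature extraction

### Manifest

The extractor emits exactly 154 features (`feature_manifest()`): intensity
statistics (18), intensity histogram (23), intensity–volume histogram (7),
grey-level co-occurrence (25), run length (16), size zone (16), distance
zone (16), neighbourhood grey-tone difference (5), neighbouring grey-level
dependence (17), local intensity (2) and mesh-free morphology (9). The
*count* is the binding constraint on the manifest; the composition follows
the IBSI family cardinalities, with nine morphology descriptors chosen so
that no mesh construction is required (volume and surface from voxel
counting and exposed faces, compactness/sphericity derived from them,
centre-of-mass shift, maximum 3D diameter over surface-voxel centres).

### Discretization

Histogram and texture features operate on grey levels from `discretize()`.
The default is **fixed bin size**, width 0.1 SUV, anchored at the ROI
minimum. This choice is deliberate: published SUV/TBR feature tables show
the histogram coefficient of variation differing slightly between the two
configurations (e.g. 0.440 vs 0.438), which can only happen under a
scale-*sensitive* discretization — fixed-bin-number discretization is
invariant under the positive rescaling that TBR normalization applies and
would make the two columns identical. Fixed-bin-number (default 32 bins)
remains available, and the package's tests verify the corresponding
invariance property in both directions.

### Aggregation conventions

All texture summaries use the simplest IBSI-sanctioned fully-3D scheme:

* GLCM and GLRLM are **merged over the 13 unique 3D directions** into a
  single matrix (GLCM symmetric; run percentage is normalized by
  13 × the voxel count).
* GLSZM zones are 26-connected components of equal-level voxels; one
  matrix per VOI.
* GLDZM reuses those zones; the zone distance is the minimum over zone
  voxels of the 6-connected city-block distance to the ROI border, with
  border voxels at distance 1 (voxels at the image edge count as border).
* NGTDM/NGLDM use the full 26-neighbourhood restricted to ROI voxels;
  the NGLDM coarseness parameter is α = 0 and the dependence index is
  the same-level neighbour count plus one.

Every matrix builder is cross-checked in the test suite against an
independent brute-force enumeration (flood fill, explicit run walking,
breadth-first distance search) on random small grids.

### Degenerate-value conventions

Features never go missing; degenerate inputs resolve by documented rules,
unit-tested in `test-firstorder.R` and `test-texture.R`: zero-variance
input has skewness and excess kurtosis 0; any feature with a zero
denominator (coefficient of variation of a constant ROI, GLCM correlation
of a single-level image, NGTDM busyness with one occupied level) is 0; a
single-level histogram has zero gradients; the NGTDM coarseness of a
perfectly homogeneous neighbourhood system is capped at 10⁶.

## TBR normalization

TBR values are lesion SUVs divided by the mean SUV of the contralateral
background region (sample n−1 SD is reported for the background spread,
matching common clinical reporting). Division by a positive scalar
preserves rank order, so `stat.skew`, `stat.kurt` and `stat.cov` are
mathematically identical between the SUV and TBR runs — the package treats
this as a testable invariant. Numerically, each voxel division rounds
once, perturbing the data at machine precision; for lesions whose skewness
happens to lie near zero this floor is irreducible for *any*
implementation, so the identity test uses a tolerance of 10⁻¹² on the unit
scale of the statistic (`|Δ| ≤ 10⁻¹² · max(1, |s|)`) rather than a pure
relative comparison, which is ill-posed across a zero crossing. Observed
differences sit near 10⁻¹⁴.

## Redundancy reduction

Clusters are connected components of the graph with an edge wherever
|Pearson r| exceeds 0.85. Connected components are parameter-free,
order-independent, and guarantee the post-reduction invariant that no
retained pair exceeds the threshold (cross-component correlations are
below it by construction). The representative of each cluster is its
highest-variance member, computed on raw feature values — scale-sensitive
by design, since the procedure is defined on unstandardized features —
with ties broken by manifest order. The strict `>` edge rule is the
default; a `strict = FALSE` toggle gives `≥`, since printed reduction
counts (154 → 31 SUV, 154 → 30 TBR in the motivating cohort) cannot
disambiguate the boundary convention. Constant columns are dropped and
reported separately. The reduction is unsupervised: labels play no role.

## Monte-Carlo resampling

Each labeling (sex F/M; IDH +/−) gets `n_folds = 100` train/holdout
configurations: one patient per class held out, pairs drawn uniformly
*without replacement* from all class-A × class-B pairs, so no fold
configuration repeats (with 13 F × 22 M there are 286 possible pairs).
The same plan object is consumed by the SUV and the TBR run, which is the
"alignment" that makes the per-fold comparison between configurations
meaningful.

### Borderline score

The published analyses report Tomek-link-based borderline scores without a
formula; this package defines the score as **the fraction of training
samples participating in at least one Tomek link** (a mutual
nearest-neighbour pair with opposite labels) — the standard use of Tomek
links as borderline-sample detectors, bounded in [0, 1]. Features are
z-scored before Euclidean distances (toggleable); otherwise large-scale
features such as voxel energy would dominate. Nearest-neighbour ties
resolve to the earliest patient row.

### Outlier score

Isolation forest per Liu et al.: 100 random axis-aligned partition trees
on subsamples of size min(256, n), height limit ⌈log₂ ψ⌉, anomaly score
`s(x) = 2^(−E[h(x)]/c(ψ))` with the usual harmonic-number normalizer.
Per-fold seeds derive deterministically from the plan seed. The *absolute*
score scale of an isolation forest is implementation-specific (it depends
on subsampling and the height-limit convention), so only within-run
SUV-vs-TBR comparisons are meaningful; the package does not attempt to
reproduce any published absolute score level.

## Ranking and inference

Per fold, every feature is scored by the R² of a single-feature linear fit
to the 0/1 label — equivalently the squared point-biserial Pearson
correlation, the unique parameter-free reading of "per-feature R² ranking"
for a binary outcome. The top `k = 6` features per fold (a
curse-of-dimensionality allowance for ~33 training samples; configurable)
are recorded; occurrence is the fraction of folds selecting a feature, and
the high-ranking set uses the strict rule *occurrence > 0.90* (a feature
in exactly 90 of 100 folds does not qualify; `strict = FALSE` available).

High-ranking features are confirmed on the **full cohort** (the printed
tables of the motivating study report a single p per feature, not per-fold
p-values) with a Mann–Whitney U test: U is the pair count
`#[a > b] + ½#[a = b]`, reported as min(U_A, U_B); the two-sided p is
exact by enumeration when n_A + n_B ≤ 20 with no ties and a
tie-and-continuity-corrected normal approximation otherwise. The
Bonferroni factor defaults to the **larger of the two post-reduction
feature counts**, applied identically to both datasets and recomputed from
the actual reduction on new data; with α = 0.05 and m = 31 the displayed
threshold is 0.0016 (decisions use the unrounded α/m). Subgroup summaries
report mean ± sample SD per sex × IDH cell, with single-patient cells
reporting SD as unavailable.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` simulates the
reference cohort structure so every stage is testable end to end. The
default spec encodes the study conditions: 35 patients (13 F: 6 IDH+/7
IDH−; 22 M: 8 IDH+/14 IDH−), per-cell lesion SUV means ± SD (1.20 ± 0.26,
1.78 ± 0.64, 1.40 ± 0.25, 1.38 ± 0.31) and background means ± SD
(1.19 ± 0.31, 1.11 ± 0.16, 1.15 ± 0.16, 1.03 ± 0.16), within-lesion
coefficient-of-variation targets from the subgroup histogram-CV cells
(0.264/0.440/0.308/0.385) and skewness targets from the subgroup skewness
cells (−0.327/0.483/−0.123/0.519). Cell SDs are interpreted as
*between-patient* spread of per-lesion means; the within-lesion CV and
skewness govern the voxel distribution inside each lesion.

Within-lesion intensities come from a moment-targeted family: a shifted
gamma with shape k = 4/γ² (gamma skewness 2/√k), reflected for negative
γ, a normal for γ = 0, a constant for CV = 0. The gamma family was chosen
because its closed-form moments provide an analytic oracle for the
recovery tests. Values are clipped to stay positive and the clipping rate
is reported.

Geometry and free parameters (nothing in the source text fixes them; each
default is a one-time choice):

* grid 64 × 64 × 35 voxels at 3.64 × 3.64 × 4.25 mm — half-resolution
  in-plane relative to a 128 × 128 PET matrix, native slice count;
* one spherical lesion per patient, radius uniform in 4–8 voxels
  (≈ 270–2100 voxels, all above the default 64-voxel eligibility floor),
  placed in one hemisphere of an ellipsoidal "brain"; the background
  reference sphere is its mirror image across the midline, guaranteeing
  disjoint masks;
* normal-brain voxels are Gaussian around the patient's background mean
  with a within-patient CV of 0.10;
* optional isotropic Gaussian smoothing, default σ = 1 voxel for realism
  (PET-like partial-volume blur). Smoothing perturbs the within-lesion
  moments, so all moment-recovery tests run with σ = 0, as does the
  800-patient recovery check (200 per cell, fixed radius 8, 44 × 32 × 32
  grid) that verifies subgroup skewness means land within ±0.1 of their
  targets;
* WHO grade labels are sampled to match the per-sex grade composition of
  the reference cohort (6/6/1 for females, 7/13/2 for males) and carried
  as metadata only.

What the generator does **not** emulate: anatomically realistic brains,
scanner/reconstruction physics, irregular lesion shapes, or spatial
texture structure beyond what smoothing induces. Passing tests therefore
demonstrate the correctness and calibration of the *analysis machinery*,
not clinical reproduction: with 35 simulated patients the pipeline yields
reductions, score tables and rankings of the same shape and magnitude as
the clinical study, but cohort-level values (which features rank highest,
exact reduction counts such as 154 → 31/30, absolute borderline/outlier
levels) depend on the undeposited patient data and are not expected to
match.

## The eligibility threshold

The clinical minimum-voxel criterion for this kind of analysis lives in
unpublished supplementary material; `min_voxels` defaults to 64 — a
4 × 4 × 4-equivalent ROI, roughly the smallest volume on which 3D texture
matrices are meaningfully populated — and is fully configurable.

## Problem sizes and runtime

The default end-to-end synthetic run (35 patients, two datasets, two
labelings, 100 folds each, 154 features) completes in about a minute on a
single CPU; the test suite's end-to-end blocks use 8-patient cohorts with
10 folds, and the heavier calibration checks (20-seed planted-signal
recovery with 30 noise features, a 500-permutation null, the 800-patient
moment recovery) were sized to run in a few minutes total. Oracle
cross-checks run on ≤ 5 × 5 × 5 grids where brute-force enumeration is
exact and fast.

## Known limitations

* The 154-feature manifest matches the published *count*; the exact
  published feature list is not recoverable, so identifiers follow IBSI
  nomenclature and family cardinalities.
* Only 3D-merged aggregation is implemented; 2D/slice-wise dialects,
  image resampling and filtered-image (e.g. wavelet) features are out of
  scope, as are delineation itself and inter-grid registration (masks are
  inputs on the volume's grid).
* The Mann–Whitney confirmation is two-group and unadjusted beyond
  Bonferroni; no effect sizes beyond mean ± SD, and no multivariable
  modelling, by design.
* Isolation-forest scores are comparable within a run only.
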