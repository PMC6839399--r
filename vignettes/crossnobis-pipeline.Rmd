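---
title: "Cross-validated Mahalanobis RSA: models, estimators, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated Mahalanobis RSA: models, estimators, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnobis)
```

## The scientific question and the design

The pipeline in this package asks whether two presentation modalities of
the same concepts — spoken words and signs, each produced by two
speakers/signers ("language models") — evoke shared neural semantic
representations, and at what grain: individual items, or only semantic
categories. The design crosses 9 items (3 per category: fruit, animals,
transport) with 2 modalities and 2 speakers/signers, giving 36 conditions
per run over 6 runs. The analysis proceeds in two stages:

1. **Searchlight discovery.** A spherical searchlight (8 mm, 65 voxels on
   a 3 × 3 × 4 mm grid) maps the mean cross-validated Mahalanobis
   (crossnobis) distance over selected RDM cells. Within-modality
   distances are computed only *across* speakers/signers, so that
   low-level perceptual similarity between tokens from the same person
   cannot create apparent structure. Group cluster inference on these
   maps defines regions of interest.
2. **ROI model comparison.** Within each ROI, per-searchlight RDMs are
   averaged into one representative RDM per subject, and theoretical
   model RDMs are fit by Kendall tau-a, converted to Fisher z, and tested
   at the group level against noise ceilings.

## Estimators

### Crossnobis distances

For conditions $i, j$, runs $m \ne n$, voxel count $P$ and noise
covariance $\hat\Sigma$:

$$ d_{ij} = \frac{1}{P\,R(R-1)} \sum_{m \ne n}
   (b_i^m - b_j^m)^\top \hat\Sigma^{-1} (b_i^n - b_j^n). $$

Cross-validating the two difference vectors across independent runs makes
the estimator unbiased: under identical true patterns its expectation is
exactly zero, individual estimates may be negative, and the statistic can
be tested directly against zero. Distances are normalized by $P$ so that
spheres truncated at mask edges remain comparable (spheres are kept when
at least half their offsets are in-mask; both choices are stated nowhere
in the source protocol and are fixed here for reproducibility).

$\hat\Sigma$ is estimated per subject from the run-wise GLM residual
frames: the population-convention ($1/N$) sample covariance of each run
is shrunk toward its diagonal, $(1-\lambda)S + \lambda\,\mathrm{diag}(S)$,
with the Ledoit–Wolf-type analytic weight (mean of per-run estimates)
unless supplied, and averaged over runs. In the searchlight, the
covariance is estimated per sphere; `prewhiten()` exposes the equivalent
square-root formulation (whitened-Euclidean ≡ direct Mahalanobis, a
property the tests check to 1e−10).

### Model fitting

Model RDMs predict dissimilarities on a tested-cell mask:

- **semantic feature** — cosine distance between item feature vectors,
  tiled over the masked cells (same-item cells predicted 0);
- **item** — 0 for same-item cells, 1 otherwise (uniqueness only, no
  between-item structure);
- **category** — the feature model restricted to different-item cells
  (the between-item component of the semantic model);
- **speaker/signer identity** — over *all* within-modality cells of one
  modality: 0 for same-speaker pairs, 1 for different-speaker pairs;
- **iconicity** — absolute difference of 1–7 iconicity ratings;
- a normalized phoneme-level Levenshtein distance is provided for
  confound screening of candidate models (`model_correlation()`, which for
  item-level matrices correlates the 36 unordered item pairs).

Fits use Kendall **tau-a** — the untied-pair denominator — because the
models contain many tied predictions, and a correlation that rewards
predicting ties would favor degenerate models. Tied pairs in either
variable contribute nothing. A brute-force $O(m^2)$ reference and a
merge-sort $O(m\log m)$ fast path agree exactly (tested on 1000 random
instances). Tau is converted to Pearson's $r$ by Greiner's relation
$r = \sin(\pi\tau/2)$ (the mapping consistent with an underlying
bivariate normal; the protocol cites the conversion without a formula)
and then Fisher-transformed, clamping $|r|$ at $1-10^{-12}$ so that
degenerate perfect fits stay finite.

Group tests are one-tailed one-sample t tests against zero for model
fits (negative model correlations are not interpretable as fits) and
two-tailed paired t tests for fit differences, on the z values, with
$d_z$ = mean/SD. The alpha level is divided by the number of
tests/clusters and rounded *half-up* to 3 decimals, which reproduces
0.008, 0.017, 0.013 and 0.010 for k = 6, 3, 4, 5 (base R's banker's
rounding would give 0.012 for k = 4).

### Noise ceilings

The lower bound is the mean z-transformed tau-a between each subject's
RDM and the leave-one-out group mean; the upper bound includes the
subject. On pure noise the lower bound is unbiased around zero while the
inclusive upper bound retains a small positive bias (each subject's own
contribution to the grand mean; ~0.45 z at n = 5, shrinking with n) — a
known property of this estimator, not a defect; the bounds' ordering
lower ≤ upper is what the pipeline relies on.

### Cluster inference and circularity control

Group maps are thresholded one-sided at the t quantile for an
uncorrected cluster-forming p (default 0.005); connected components use
18-connectivity (faces + edges). Cluster-level p values come from a
sign-flip permutation null of maximum cluster extent — exact under
subject exchangeability — with Benjamini–Hochberg correction across
clusters at q = 0.05. This deliberately replaces random-field-theory
topological FDR, so published voxel-extent thresholds obtained with RFT
are not comparable quantities.

Because ROIs are selected for large mean distances over the selecting
cells, any model whose tested cells lie within those cells is orthogonal
to selection (the correlation removes the mean). The identity models are
not: they predict a mean difference between across-speaker cells (which
drove selection) and same-speaker cells. `orthogonality_guard()` blocks
them in same-data ROIs; `leave_one_out_rois()` re-estimates the group map
without each subject in turn (threshold p < 0.001 uncorrected), giving n
statistically independent ROI families in which the identity models are
fit. Leave-one-out clusters are matched to full-group ROIs by maximal
voxel overlap.

### Non-metric MDS

Group-average RDMs are visualized with Kruskal's non-metric MDS
(`MASS::isoMDS`), consistent with the rank-based fitting. Crossnobis
RDMs may contain negative cells; when any off-diagonal dissimilarity is
non-positive the matrix is shifted by its minimum plus a small epsilon —
rank-preserving, hence innocuous for a non-metric solution. Ten restarts
by default (classical-scaling start plus random starts), best stress-1
kept, coordinates mean-centered, deterministic given the seed.

## The synthetic testbed

`generate_cohort()` builds multi-subject, multi-run beta patterns plus
residual frames with *planted* representational geometry, so the whole
pipeline is testable end-to-end without imaging data. Defaults emulate
the study scale: 17 subjects × 6 runs × 36 conditions, 3 × 3 × 4 mm
voxels, spatially correlated noise (white Gaussian fields smoothed with
a 6 mm FWHM kernel and rescaled to the configured SD — the protocol
states no noise model; any correlated structure exercises the
multivariate noise normalization), 100 residual frames per run, and a
multiplicative per-subject, per-region amplitude jitter
(lognormal, sdlog 0.2). Noise is injected at the beta level rather than
simulating time series and an HRF-level GLM, which the pipeline does not
consume. The trial-level design generator reproduces the protocol
bookkeeping (91 trials per run = 72 core + 6 target fillers + 6
non-target fillers + 7 nulls; 48 presentations per item; no concept on
consecutive trials; fillers placed uniformly at random subject to a
minimum gap of one core trial).

### Planted geometry

True patterns per region are sums of amplitude-weighted component
vectors: a modality-invariant semantic component (category-level), a
modality-specific item component, an optional modality-invariant item
component, speaker/signer identity components, and a modality-opposed
item-divergence component. Three choices matter and are deliberate:

- **Orthonormal components.** All subjects share one true-pattern
  realization (only jitter and noise differ), so any finite-voxel
  sampling wobble in the planted RDM would appear as a consistent group
  effect, not as noise. Component vectors are therefore jointly
  orthonormalized (QR, rescaled to norm $\sqrt V$), making every planted
  squared distance equal its expectation exactly. For regions with fewer
  voxels than components, raw Gaussian draws are used.
- **Graded, tie-rich norms.** The synthetic feature norms are binary
  with equal unique-feature counts per item and all-or-none category
  blocks, plus cross-category shared features that grade the
  between-category similarities. Predictions within a block are exactly
  tied — important because tau-a excludes tied model pairs: norms with
  continuous random weights would pit thousands of near-tied predictions
  against structureless data and roughly double the category model's
  per-subject tau variance. The planted semantic component mixes the
  unit-normalized category-centroid feature vectors through the
  orthonormal basis, so planted between-category distances are exactly
  proportional to the model's centroid cosine dissimilarities.
- **Across-modality item divergence.** In the `shared_semantic`
  archetype, the same item presented in the two modalities is made *no
  closer* than different items of the same category — in fact its cell is
  raised into the middle of the between-item distance distribution
  ($a_{div}^2 = 0.75\,a_{cat}^2$ balances the item model's concordant and
  discordant pairs at expectation). This is the empirical signature of
  category-only sharing. Without it, the binary item model partially
  inherits the category structure across modality (same-item pairs are a
  subset of same-category pairs) and no amplitude regime dissociates the
  two models.

Archetypes: `shared_semantic` (category + within-modality item structure,
item-divergent across modality), `speech_form` / `sign_form` (item and
speaker/signer identity structure in one modality only), `null` (no
structure).

### Study conditions for parameter recovery

`archetype_scene()` freezes the desk-scale recovery conditions used by
the test suite: 17 subjects, 6 runs, a 12 × 12 × 8 grid with one
10 × 10 × 4 planted region, 60 residual frames per run, and base
amplitude 0.04 in units of the unit noise SD. That amplitude puts the
group effects in the published range (d_z ≈ 0.6–2.7) rather than at
saturation, where every model fits everything. Null calibration
(family-wise error of surviving clusters) runs 200 smaller cohorts
(8 subjects, 4 runs, 6 × 6 × 4 grid, 5 mm searchlight, 200 sign-flip
permutations).

### What passing tests do and do not show

The generator shares one grid across subjects (no anatomy, no
normalization error), injects stationary Gaussian noise (no physiology,
motion or drift), and plants geometry from the same feature family the
models are built from (a correctly-specified model scenario). Recovery
of the planted dissociations therefore validates the *estimators and
inference machinery* — unbiasedness, calibration, circularity control,
decision logic — not the anatomical claims of any particular dataset,
and says nothing about model misspecification on real data.

## Worked example

```{r example, eval = FALSE}
config <- archetype_scene("shared_semantic")
cohort <- generate_cohort(config, seed = 1)
pipe <- run_roi_pipeline(cohort, n_permutations = 300, seed = 1)
print(pipe)
pipe$fits[[1]]$group
write_report(pipe, "report.md")

# visualize the group-average representational geometry in the ROI
rdms <- lapply(seq_along(cohort$subjects), function(s)
  crossnobis_rdm(cohort$subjects[[s]], cohort$region_masks[[1]]))
emb <- nonmetric_mds(mean_rdm(rdms), seed = 1)
category_centroids(emb, cohort$space)
```

## Known limitations

- Real-data ingestion expects native-space betas and residuals on one
  grid per subject; spatial normalization and anatomical labeling are out
  of scope (subject maps are assumed pre-aligned).
- The permutation null assumes subject exchangeability; with n = 17
  there are 2^17 sign patterns, amply more than the default 300–1000
  draws, but p values are Monte-Carlo estimates.
- Tau-a on the 630-cell RDM is exact but the merge-sort path should be
  preferred for repeated fitting; the brute-force path exists as the
  reference oracle.
- The inclusive noise-ceiling upper bound is positively biased on pure
  noise at small n (see above).
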