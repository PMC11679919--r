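---
title: "Building emotion atlases from task fMRI and applying them to resting-state cohorts"
author: "emotionatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building emotion atlases from task fMRI and applying them to resting-state cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emotionatlas)
```

## The problem

Block-design emotional-stimulation fMRI alternates short periods of picture
viewing with rest. Because the BOLD response lags neural activity by roughly
8–12 s, the volumes acquired 11–20 s after stimulus onset carry the developed
stimulus response, and the volumes 31–40 s after onset (the second half of
the following rest period) represent the recovered baseline. `emotionatlas`
turns such runs into voxel-level *emotion atlases* — one per stimulus
polarity — and then uses those atlases to analyse an independent two-group
resting-state cohort (patients vs controls) by cost-sensitive classification
and voxelwise ALFF statistics.

The pipeline has two halves:

1. **Atlas construction.** Runs are segmented into task blocks (one per
   40 s stimulus+rest cycle; five volumes per window at TR = 2 s). Each
   block yields one stimulus-state and one rest-state observation: per
   region (or per voxel), the block's ten time points are min–max
   normalized jointly and each five-point window averaged, so every feature
   lies in [0, 1]. Region-level SVM-RFE selects *characteristic regions*;
   within each, voxel-level SVM-RFE selects *characteristic sub-ROI*
   voxels; finally, voxels of non-characteristic regions whose time course
   correlates with any sub-ROI reference series above a strict threshold
   (Pearson r > 0.95) are recruited as external voxels. Sub-ROI plus
   external voxels form the atlas.
2. **Group application.** For a resting cohort, per-subject features are
   the ALFF of each atlas region's mean series; an RBF-SVM grid search
   (C ∈ {0.25, 0.5, 1, 2, 4}, γ ∈ {0.5, 1, 2, 4, 8, 15}, stratified
   10-fold CV) with asymmetric misclassification costs classifies patients
   vs controls. In parallel, voxelwise ALFF maps are compared by a
   covariate-adjusted two-sample t-test with BH-FDR control (q = 0.01) and
   the surviving voxels reported as connected clusters with peak
   statistics and physical sizes.

## The ranking statistic

For balanced stimulus/rest labels $y_k \in \{-1, +1\}$ the soft-margin
linear SVM dual is solved (libsvm), giving $w = \sum_k \alpha_k y_k x_k$
and decision $D(x) = w \cdot x + b$. Each surviving feature's ranking
criterion in one fold is $c_i = w_i^2$; the score used for elimination is
the average over the ten stratified folds, $a_i = \sum_j c_{ij} / 10$.
One feature — the smallest $a_i$, ties broken by input order — is deleted
per round, and the 10-fold CV accuracy of the survivors is recorded after
every deletion. After the full traversal, the retained subset is the
survivor set at the maximum of the accuracy trajectory, preferring the
earliest (largest) subset on ties; this operationalizes "stop when accuracy
no longer improves" as an auditable rule. Fold assignment is stratified,
seeded, and fixed for the whole traversal.

Two consequences of this stopping rule are worth knowing. On cleanly
separable data the trajectory is flat at 1.0, so the rule retains almost
all features — informative features are then recovered with certainty, but
the subset is not parsimonious. On noisy data the trajectory has an
interior maximum and the rule behaves like classical RFE. Both regimes are
exercised by the tests.

## Normalization scope

Min–max normalization is applied per feature *per task block over the
block's combined ten time points* (stimulus + recovery windows jointly),
after which each five-point window is averaged. The joint scope is what
makes the stimulus–rest contrast recoverable: a constant stimulus elevation
normalized within its own window alone would be erased entirely. A
constant ten-point series maps to zeros, keeping all features inside
[0, 1].

## The synthetic generators

Real task and resting scans are replaced by seeded generators whose
defaults are the study conditions:

* **Parcellation** — an ellipsoidal "brain" inscribed in the grid,
  partitioned into contiguous regions grown from seeded centroids by
  multi-source BFS. Desk scale is a 20×20×20 grid with 30 regions
  (3 mm isotropic voxels); a 246-region whole-brain-template configuration
  is supported and used for the structural-count checks.
* **Task runs** — 21 subjects; 20 s rest lead-in then six 40 s cycles
  alternating positive/negative stimulation at TR = 2 s (260 s, 130
  volumes). The signal model is `baseline + effect × delayed-boxcar +
  i.i.d. Gaussian noise`: active voxels (a fixed fraction of each active
  region, taken deterministically so truth is recoverable) are raised by
  the effect size while run time lies within `[onset + delay, end +
  delay)`. The default 10 s delay is the midpoint of the 8–12 s BOLD lag;
  with it, window-mean differencing recovers the effect exactly at zero
  noise, which pins the whole segmentation/feature chain to an analytic
  identity. A boxcar rather than a double-gamma HRF keeps those identities
  exact; the cost is that within-window dynamics are unrealistically flat.
* **Resting cohorts** — 46 patients and 20 controls by default; white
  Gaussian noise plus, in each implanted cluster of a group, a
  band-limited sinusoid (default 0.04 Hz) of chosen amplitude with random
  per-subject phase. Ages are drawn from the cohort demographics (patients
  33.0 ± 9.5 y, controls 34.2 ± 8.5 y), sexes assigned at the cohort
  ratios (10 M : 36 F and 6 M : 14 F).

What the generators deliberately omit: physiological noise and its
autocorrelation, motion, field inhomogeneity, spatial smoothness, and
anatomically realistic geometry. Passing tests therefore demonstrate that
the *machinery* is correct and calibrated under its stated noise model —
not that effect sizes of real cohorts would be recovered at the same
rates.

## Numerical choices

* **Tunable parameters.** RFE box constraint C = 1 (exposed); FC threshold
  0.95, strict inequality, signed correlation; ALFF band 0.01–0.08 Hz
  (the resting-stage band; preprocessing-style band-pass 0.01–0.1 Hz is
  available separately); FDR level q = 0.01; cluster connectivity 26
  (6/18 available); no minimum cluster extent, so one-voxel clusters are
  reported (27 mm³ at 3 mm voxels). Costs default to 2:1
  (false-negative : false-positive), entering as per-class weights on C
  normalized by the smaller cost, so equal costs reduce exactly to the
  unweighted SVM; the grid-search objective is mean CV misclassification
  cost, with ties broken by higher recall, then smaller C, then smaller γ.
* **ALFF.** Linear detrend, DFT, per-bin amplitude `2|X_k|/n`, mean over
  the band bins. ALFF is absolutely homogeneous after detrending;
  out-of-band exact-bin sinusoids contribute nothing (up to the detrend's
  own leakage, which vanishes for phase-symmetric series).
* **Covariates.** Age and sex are removed by a single pooled OLS
  regression before the two-sample t-test; group is *not* in the nuisance
  design, so group signal survives. Degrees of freedom are reduced by the
  two covariates.
* **Degenerate inputs.** Constant windows normalize to zeros; constant
  series make Pearson correlation an error (and FC candidates with zero
  variance are simply never retained); zero-variance voxels are masked out
  of the t-map with a warning; regions with fewer than two voxels are
  retained wholesale by voxel-level selection with a warning.
* **Determinism.** Every stochastic operation takes a seed and restores
  the caller's RNG state; pipeline stages derive their seeds from one
  master seed, so `runBuildAtlas()`/`runGroupAnalysis()` are bit-for-bit
  reproducible.

## Open design points and how they were resolved

* *Voxel-level RFE per characteristic region, not pooled* — each region's
  voxels are selected against that region's own feature matrix, which
  reads most naturally from the construction and keeps per-region audit
  trails.
* *FC reference series* — the mean over a sub-ROI's voxels of the
  concatenated block time courses (stimulus then recovery windows, block
  order). The source material never names the series; this choice uses
  exactly the data the atlas was built from.
* *Resting-stage feature representation* — per-region ALFF over atlas
  voxels (`region_alff`), consistent with the ALFF emphasis of the group
  stage; a `voxel_mean` mode is provided as the alternative reading.
* *Voxelwise test scope* — whole foreground by default, with an
  atlas-restricted option (`scope = "atlas"`), covering both readings of
  "differences under the atlas".
* *Window convention* — volume k (0-based) has onset 2k s; "11–20 s" maps
  to onsets {10, …, 18}, so exactly five volumes result. The initial five
  volumes are discarded for stability bookkeeping; windows are indexed
  relative to the trimmed run.

## Problem sizes used by the checks

The test suite runs region-level recovery at the 20³/30-region desk scale
(20 generator seeds), the end-to-end voxel-level coverage suite on a
10³/6-region geometry (10 seeds, 21 subjects each), the group statistics
on 12³ cohorts of 46 vs 20 with the implant amplitude calibrated in a
pilot to a per-voxel ALFF effect of d = 1.5, and the classification suites
at n = 66. `scripts/acceptance.R` reruns the structural counts on a
16³/246-region template and the full pipeline on a 16³/30-region
configuration with the full 21-subject task stage and 46/20 resting
cohort. These sizes are the package's own reproducibility conditions; the
full 246-region, whole-brain geometry runs through the identical code
paths.

## Known limitations

* The boxcar response model makes window identities exact but cannot probe
  HRF-shape misspecification.
* The stopping rule's largest-subset preference yields conservative
  (large) atlases on highly separable data; real, noisier data produce the
  parsimonious subsets classical RFE is known for.
* External-voxel recruitment at r > 0.95 rarely fires under the default
  noise model (independent noise decorrelates candidates from references);
  the tests exercise it with engineered correlation structure.
* BH-FDR controls the expected false-discovery proportion per map; no
  cluster-level familywise correction is provided.
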