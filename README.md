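# emotionatlas

Voxel-level **emotion atlas construction** from block-design task fMRI, and
**two-group resting-state analysis** under those atlases.

Emotional-stimulation experiments alternate short picture-viewing blocks
with rest. Because the BOLD response lags neural activity by ~8–12 s, the
five volumes acquired 11–20 s after stimulus onset carry the developed
response and the five volumes 31–40 s after onset the recovered baseline
(TR = 2 s). `emotionatlas` turns those windows into balanced stimulus/rest
feature matrices (per-block min–max normalization, window means), selects
discriminative brain regions and then voxels by **SVM-RFE with
cross-validation-averaged ranking scores**

> per fold *j*: fit a soft-margin linear SVM, *w* = Σₖ αₖ yₖ xₖ;
> score cᵢⱼ = wᵢⱼ²; average aᵢ = Σⱼ cᵢⱼ / 10;
> delete argminᵢ aᵢ, record 10-fold CV accuracy; keep the survivor set at
> the trajectory maximum,

recruits external voxels from non-characteristic regions by functional
connectivity (Pearson r > 0.95, strict), and assembles positive/negative
emotion atlases exportable as NIfTI masks with provenance tables.

The resting-state stage classifies patients vs controls with a
**cost-sensitive RBF-SVM grid search** (C ∈ {0.25, 0.5, 1, 2, 4},
γ ∈ {0.5, 1, 2, 4, 8, 15}, stratified 10-fold CV, false negatives costed
2:1 against false positives) and compares groups voxelwise by **ALFF**
(mean square-root spectral power over 0.01–0.08 Hz) with age/sex removed
by regression, two-sample t-tests, BH-FDR at q = 0.01, and
connected-cluster reporting (size in mm³, peak coordinate, signed peak t).

A seeded synthetic-data module generates contiguous parcellations,
paradigm-conforming task runs (boxcar response with 10 s hemodynamic
delay) and two-group resting cohorts with implanted band-limited effects,
so the whole pipeline is testable end to end against known ground truth.

Who it is for: methods developers and students who want a fully
inspectable, reproducible implementation of this atlas-construction recipe
with every stage unit-tested against independent oracles.

## Worked example

```r
library(emotionatlas)

cfg <- runConfig(gridShape = c(10, 10, 10), nRegions = 8, nTaskSubjects = 6,
                 nActiveRegions = 2, nPatients = 12, nControls = 8,
                 restDurationS = 300, alffAmplitude = 3, masterSeed = 7)
build <- runBuildAtlas(cfg)
build$positive
#> EmotionAtlas (positive): 256 sub-ROI voxels in 7 regions + 0 external voxels; 7 regions touched

ga <- runGroupAnalysis(cfg, list(build$positive, build$negative),
                       build$parcellation, build$truth)
ga$report
#> ClassificationReport (positive = patient): accuracy 0.600, precision 0.600, recall 1.000, F 0.750
#>   selected C = 0.25 , gamma = 0.5
ga$comparison
#> GroupComparison: q = 0.01 (BH-FDR), covariates: age, sex
#>    1 significant clusters, 6 voxels
clusterTable(ga$comparison)[, c("nVoxels", "sizeMm3", "peakIntensity")]
#>   nVoxels sizeMm3 peakIntensity
#> 1       6     162      18.19476
```

Reading the output: the positive atlas retained 256 characteristic
sub-ROI voxels across 7 regions (no external voxels pass the strict
r > 0.95 rule under independent noise). The cost-sensitive classifier
reaches recall 1.0 — the 2:1 cost ratio pushes it to miss no patients —
at accuracy 0.60 on this deliberately small cohort. The voxelwise ALFF
comparison recovers exactly the 6-voxel cluster implanted in the patient
group (6 × 27 mm³ = 162 mm³), with a strongly positive peak t (patients
higher), as constructed.

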