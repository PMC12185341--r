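# aisquant

Quantitative profilometry and classification of axon-initial-segment (AIS)
fluorescence in neuronal microscopy.

## The problem

In postmortem cortical tissue and iPSC-derived neurons, the distribution of
βIV spectrin — the cytoskeletal scaffold of the AIS — shifts with disease
state and with pharmacological perturbation of AKT/GSK3 signalling. Detecting
those shifts requires (i) reproducible intensity measurements from annotated
images, (ii) cell-level features rich enough for single-cell classification,
and (iii) statistics that respect the hierarchy of the data: hundreds of
cells, but only a handful of subjects or cell lines. `aisquant` implements
that entire analysis as a tested R pipeline, together with a seeded synthetic
cohort generator so every stage can be validated without any imaging data.

## What it computes

**Quantification.** Confocal z-stacks are sum-projected
(`sum_project()`); the soma ROI comes from an Otsu intensity threshold plus
seed-grown connected components (`soma_roi()`, `mean_intensity()`); AIS and
neurite signals are extracted as wide line profiles — samples at 1-px arc
length along an annotated polyline, each averaged over 5 bilinear samples on
the local perpendicular (`profile_along_path()`). Derived measures:
AIS staining length as the longest run above a fraction of the peak
(`ais_length()`), and the AIS/soma polarity ratio (`ais_soma_ratio()`).

**Features.** Traces are calibrated to a common anatomical start and length
(`calibrate_traces()`), then described by DFT magnitudes
`|X_k|, X_k = Σ_n x_n e^{-2πikn/N}` (`dft_features()`) — phase is discarded so
residual alignment shifts do not matter. Masked soma regions are described by
a 14-feature Haralick-family panel computed from the gray-level co-occurrence
(GLCM), dependence (GLDM) and size-zone (GLSZM) matrices
(`texture_features()`).

**Classification.** A repeated-holdout random-forest harness
(`repeated_holdout()`, `run_task()`): 70/30 stratified splits, 10
repetitions, accuracy reported as mean ± SD over repeats, with an optional
subject-level (`group_aware`) split mode that closes the subject-identity
leak inherent in cell-level splitting.

**Group statistics.** `nested_t_test()` (two-group comparison on subject
means, df = n_subjects − 2), `mixed_two_way_anova()` (split-plot ANOVA with
diagnosis between subjects, treatment within, subject as the random effect),
`dunnett_comparisons()` (many-to-one vs control from the within-subject error
stratum, exact multivariate-t adjustment), `sidak_adjust()` and
`qq_log_transform()`.

**Synthetic cohorts.** `synth_config()` + `generate_cohort()` draw a
hierarchical cohort — subject random intercepts, cell-level scatter,
rise-and-decay AIS profiles, textured elliptical somata — whose ground truth
is returned alongside the data.

## Worked example

```r
library(aisquant)
library(dplyr)

cfg <- experiment_config(
  "postmortem_diagnosis",
  synth  = synth_config(n_subjects_per_group = 6, cells_per_subject = 20, seed = 1),
  scheme = split_scheme(n_repeats = 10, seed = 2)
)
res <- run_experiment(cfg, "pm_run")
res
#> <experiment_result> postmortem_diagnosis
#>   output: pm_run
#> # A tibble: 2 × 4
#>   task_label     mean_accuracy sd_accuracy n_cells
#>   <chr>                  <dbl>       <dbl>   <int>
#> 1 ais_diagnosis           77.2       4.59      240
#> 2 soma_diagnosis          99.6       0.671     240

glance(nested_t_test(res$measurements, value = "ais_mean"))
#> # A tibble: 1 × 5
#>   method        statistic    df  p.value n_subjects
#>   <chr>             <dbl> <dbl>    <dbl>      <int>
#> 1 nested t-test      4.71    10 0.000826         12
```

The summary table reports the repeated-holdout random-forest accuracy for
diagnosis from AIS spectral features and from soma texture features: with
the generator's default effect sizes (HC amplitude 100 a.u. vs SCZ 80 a.u.,
subject SD 8, cell SD 10), AIS profiles separate the groups well above
chance at the single-cell level, and the configured group difference in soma
texture correlation length is essentially perfectly classifiable. The nested
t-test confirms a subject-level AIS intensity decrease (t = 4.71 on 12
subject means, p ≈ 0.0008). `make_report(res)` adds the group-mean
calibrated trace plot and the accuracy bar chart.

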