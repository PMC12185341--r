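---
title: "Methods: AIS intensity profilometry, texture features and hierarchical statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AIS intensity profilometry, texture features and hierarchical statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisquant)
library(dplyr)
```

`aisquant` quantifies βIV spectrin fluorescence at the axon initial segment
(AIS) and soma of annotated neurons, turns the measurements into cell-level
feature vectors, classifies cells by diagnosis or treatment, and tests group
differences with statistics that respect the cells-within-subjects hierarchy.
This vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not establish.

## 1. The measurement model

Images are 2D intensity grids in arbitrary fluorescence units (a.u.);
z-stacks are collapsed by per-pixel summation before any measurement, so
slice count affects scale but not shape. All quantities downstream are either
ratios, within-cohort comparisons, or classifier inputs, so the absolute
scale never matters.

**Line profiles.** An AIS or neurite is annotated as a polyline in pixel
coordinates (0-based row/col). `profile_along_path()` samples the image at
unit arc-length steps from the first vertex; at each step the intensity is
the mean of `width_px = 5` bilinear samples spaced 1 px apart along the local
perpendicular. Two conventions needed fixing that common acquisition
software leaves implicit:

* *Sampling step*: exactly 1 px of arc length. The trace length is
  `floor(total arc length) + 1`.
* *Width*: five point samples across the perpendicular, not a 5-px binary
  band. For a locally straight structure wider than the profile, the two
  conventions agree to first order; point sampling is exactly linear in the
  image, which makes the extractor verifiable (a linear ramp image yields a
  linear trace to machine precision).

Perpendicular samples falling outside the image are clamped to the nearest
edge pixel and counted per step; the per-trace clamped fraction is reported
so heavily clipped paths can be excluded at annotation review, mirroring
manual exclusion of paths that cross other structures (which no image-free
rule can reproduce automatically).

**Soma ROI.** `soma_roi()` thresholds with Otsu's method (256 histogram
levels over the observed range) and keeps the connected component containing
the seed point (largest component if unseeded). A constant image has no
threshold and is an explicit error.

**AIS length.** `ais_length()` measures the longest contiguous run of
samples at or above `frac_of_peak` × max, times the pixel size. The staining
length criterion is not standardised in the literature; the default
`frac_of_peak = 0.33` is exposed as an argument, and cohort quantification
applies it to the baseline-subtracted post-anchor trace (baseline estimated
as the median of the pre-anchor lead-in, or the trace minimum when there is
none) so the threshold refers to signal above background rather than to raw
intensity.

## 2. Feature engineering

**Calibration.** Spectral features require a common spatial support.
`calibrate_traces()` re-indexes each trace to its anchor (the annotated AIS
start) and truncates all traces to the shortest post-anchor length; traces
shorter than `min_length = 16` samples are dropped with a recorded reason.

**DFT descriptors.** For a calibrated trace `x` of length `N`,
`X[k] = Σ x[n]·exp(−2πikn/N)`; the feature vector is
`{|X[0]|/N, |X[1]|, …, |X[n_coeff−1]|}` with `n_coeff = 20` by default.
Magnitudes rather than real/imaginary parts: magnitudes are invariant to
circular shifts and reversal, so residual alignment error left after
calibration cannot masquerade as signal. The DC term is scaled to the trace
mean so it reads in intensity units. Twenty coefficients cover spatial
periods down to ~5 px at the default 100-px trace length — below the width
of any real AIS substructure the generator emulates; the count is a plain
argument, not a constant.

**Texture panel.** Soma texture is summarised by 14 features over three
gray-level matrices on the masked, quantized region (32 equal-width bins over
the ROI range; distance 1; four directions, 0°/45°/90°/135°, accumulated
symmetrically — the standard Haralick convention):

* GLCM: contrast, correlation, energy, homogeneity (inverse difference
  moment), entropy, sum entropy;
* GLDM (dependence tolerance α = 0): small/large dependence emphasis,
  dependence non-uniformity (normalised), dependence variance;
* GLSZM (8-connected zones): small/large area emphasis, zone non-uniformity
  (normalised), zone entropy.

The matrix family is fixed by the analysis design; the particular 14 names
are this package's documented default (configurable ground exists in the
code for distance, α, bins and directions). One convention deserves note:
the dependence matrix here indexes pixels by their raw dependent-neighbour
count `d` (0 … 8 at distance 1), and the emphasis/variance features use
`j = d + 1` so that an isolated pixel contributes dependence size 1 — the
same accounting as radiomics toolboxes that count the centre pixel, while
keeping the matrix itself a plain neighbour-count histogram.

Degenerate regions take documented limits: a constant ROI has contrast 0,
energy 1, correlation defined as 1 (zero marginal variance), one zone, and
zero entropies.

## 3. Classification harness

`repeated_holdout()` fits a random forest per repeat on a fresh random
70/30 split, stratified by class; accuracy is the plain fraction correct on
the held-out cells, reported as mean ± sample SD over 10 repeats (both
defaults exposed). Forest defaults are 500 trees and √p features per split —
stable, standard settings; per-repeat seeds derive from the scheme seed, so
a report is a pure function of (data, scheme, model parameters).

Splitting at the cell level matches single-cell classification but has a
known caveat: cells of one subject appear in both halves, so a classifier
can exploit subject identity. The harness therefore also provides
`group_aware = TRUE` subject-level splits, and the report prints the caveat.
The leakage probe in the test suite constructs a cohort whose only structure
is subject identity: cell-level splits score far above chance, subject-level
splits collapse to chance — the caveat is real, which is why both modes
exist rather than one guessed intent.

## 4. Hierarchical statistics

With ~20 cells per subject and ~6 subjects per group, cells are
pseudoreplicates. Three consequences drive the design:

* `nested_t_test()` aggregates to subject means and tests those
  (equal-variance two-sample t, df = n_subjects − 2). A weighted variant
  (weights = cell counts) is available for unbalanced designs; the
  unweighted form is the default because it keeps the subject — not the
  cell — as the unit of inference regardless of how many cells a subject
  contributed. On simulated null cohorts with subject-level variance the
  nested test rejects at ≈ 5% while the naive cell-level t-test rejects at
  ≈ 40% (both rates recomputed by `scripts/acceptance.R`).
* `mixed_two_way_anova()` is a split-plot ANOVA on subject × treatment
  means: diagnosis (between subjects) is tested against the
  subject-within-diagnosis stratum, treatment and the interaction against
  the subject × treatment residual. Aggregation-then-ANOVA, rather than a
  REML mixed model, keeps every sum of squares exactly checkable against a
  first-principles oracle (the suite verifies agreement to 1e−8 on balanced
  designs); under severe cell-count imbalance it is an approximation, and
  the aggregated table is returned so users can inspect it.
* `dunnett_comparisons()` compares each treatment to control within a group
  using the within-subject error stratum; adjusted p-values come from the
  exact many-to-one multivariate-t distribution (pairwise correlation 1/2 in
  the balanced case) evaluated with `mvtnorm` under a fixed integration
  seed. The exact distribution was preferred over Monte-Carlo critical
  values: it is deterministic to the stated 1e−5 tolerance, faster, and
  reduces to the plain paired t-test when there is a single comparison —
  a property the tests assert. `sidak_adjust()` implements
  `1 − (1 − p)^m` for the between-group family.

`qq_log_transform()` automates the usual normality pre-check with an
explicit, recorded criterion — sample skewness > 1 triggers a natural-log
transform — because a reproducible pipeline cannot depend on a visual QQ
judgement. The decision, the skewness and any offset applied for
non-positive values are all returned.

## 5. The synthetic cohort generator

`generate_cohort()` draws, per cell,

```
I(x) = baseline + (A_g + s_j + e_c) · f(x) + ε(x)
```

with `s_j ~ N(0, subject_sd)` a subject random intercept shared by all of a
subject's cells, `e_c ~ N(0, cell_noise_sd)` cell-level scatter,
`ε ~ N(0, trace_noise_sd)` per-sample noise, and `f` a linear rise over
`rise_px = 10` samples followed by exponential decay with length constant
`decay_px = 30` (normalised to max 1) — the simplest shape matching published
AIS profiles, with a corner at the peak that deliberately stresses the
interpolation in the round-trip test. Traces carry a random baseline lead-in
(0–6 px) and length jitter (0–8 px) so calibration has real work to do. Soma
images are ellipses (`soma_size_px = 32` major axis) whose interior is
`soma_level` plus a Gaussian random field: white noise smoothed with a
Gaussian kernel of width `texture_corr_px`, rescaled to SD
`soma_texture_amp`. The correlation length is the single texture knob: short
lengths give rough, disorganised texture (higher GLCM contrast), long
lengths smooth, organised texture.

Default study conditions: 6 subjects per group × 20 cells, baseline 100
a.u., AIS amplitude 100 (HC) vs 80 (SCZ), equal soma levels, texture
correlation 4 px (HC) vs 1.5 px (SCZ), subject SD 8, cell SD 10, sample
noise 3, pixel size 0.1 µm. No published intensity units or effect
magnitudes exist for these contrasts, so the defaults were chosen once as
values a microscopist would call realistic — a ~20% group effect against
~13% combined biological noise — and the treatment grid encodes direction
only (kinase inhibition raises HC amplitude ×1.2, blunted to ×1.0 in the
patient lines; AKT inhibition lengthens the HC decay ×1.2). All randomness
flows from one seed through derived child seeds; identical configurations
yield byte-identical cohorts and, downstream, byte-identical pipeline
outputs (verified per run in the manifest's file hashes).

**What passing tests show — and don't.** The generator emulates the
hierarchical and group structure the analysis assumes: random intercepts,
rise-and-decay profiles, stationary textures, treatment × diagnosis effects.
It does not emulate optics (PSF, z-blur), multi-channel bleed-through,
segmentation failure, or annotation error. Green tests therefore establish
that the pipeline measures what it claims and that its statistics are
calibrated under the assumed model — not that real tissue satisfies that
model.

## 6. Numerical choices and problem sizes

* Bilinear interpolation everywhere a sub-pixel sample is needed; the
  render-then-extract round trip recovers generated traces to < 2% of peak
  over 100 random oblique paths (worst error sits at the profile's peak
  corner, as interpolation theory predicts).
* Otsu threshold on 256 levels; ROI connectivity is 4-connected (solid
  blobs), zone labelling in the GLSZM is 8-connected by flood fill.
* Quantization maps the ROI maximum into the top bin (half-open bins
  elsewhere); a constant region maps to level 1 without error.
* Equal-variance t throughout, two-tailed, α = 0.05.
* Validation problem sizes were chosen to give stable Monte-Carlo estimates
  at interactive runtimes: 100 traces for the DFT oracle, 50 images for the
  texture oracles, 100 cells for the round trip, 600-cell cohorts for
  classifier calibration, 1000–2000 replicates for the type-I-error and
  FWER calibrations (binomial SE ≈ 0.5% at rate 0.05).

## 7. Known limitations

* The mixed ANOVA's aggregation step discards within-cell replication
  weights; strongly unbalanced subject × treatment cell counts shift its
  F statistics relative to a REML fit.
* Cell-level split accuracies on cohorts with large subject effects
  overstate generalisation to new subjects; use `group_aware = TRUE` for
  that question.
* `quantify_images()` trusts annotations: paths are not re-traced, and the
  exclusion of paths crossing other structures must happen at annotation
  time (the clamped-sample fraction is the only automatic flag).
* The texture panel is a fixed 14-feature default; it is a documented
  stand-in for toolbox-specific feature menus, not a claim that these 14
  are optimal.
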