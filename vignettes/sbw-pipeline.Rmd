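---
title: "Object-based single-boll-weight estimation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based single-boll-weight estimation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models inside `cottonsbw`, the
tunable parameters and their defaults, what the synthetic benchmark does and
does not emulate, and the design choices made where several readings were
defensible. It states no empirical result beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The estimation problem

Single-boll weight (SBW, grams per opened boll) is a yield component that
becomes observable from the air only after defoliation, when canopies are a
mixed scene of bright lint, exposed soil and senescent tissue. Canopy-mean
reflectance therefore carries a diluted boll signal. The package treats the
problem in three stages: (i) classify each pixel of a five-band reflectance
raster (blue 475, green 560, red 668, red-edge 717, NIR 842 nm) into
soil / stems-leaves / lint and keep only lint ("object-based" boll
extraction); (ii) summarize lint reflectance per sampling point into
vegetation indices and select the informative ones; (iii) regress measured
SBW on the selected indices and map predictions back onto the raster.

## The synthetic benchmark

No imagery is distributed with the trial the workflow was designed around,
so all testing runs on `generate_scene()`, which emulates the trial's
*statistical* structure:

* **Design.** 48 plots in a 6 × 8 grid (default raster 384 × 512 px), 16
  treatments × 3 replicates: varieties V1–V3 at planting densities D1–D5
  plus a check variety (CK) grown only at D5; three sampling points per
  plot; one scene per year, two years, hence 48 × 3 × 2 = 288 sampling
  points.
* **Spatial layout.** Soil background; stems/leaves as vertical row stripes
  (width 4 px, gap 6 px) mimicking the mulch-row planting pattern; lint as
  2–4 px blobs on the stripes, covering a density-dependent fraction of
  each plot (D1 6 % … D5 14 %, more plants → more bolls per area). The
  layout is stylized: downstream stages consume only spectra and class
  geometry, so no radiative-transfer canopy model is needed.
* **Spectra.** Class-conditional Gaussians per band, clipped to [0, 1].
  Defaults (reflectance): soil bright and flat (0.18–0.30 rising to NIR),
  stems/leaves dark red (0.07) with moderate NIR (0.35), lint the brightest
  class in the visible (0.45–0.52) and spectrally flat — the configuration
  that makes lint/soil confusion plausible for a box classifier. All
  standard deviations default to 0.02 (a realistic per-pixel noise level
  for a calibrated orthomosaic of a bright uniform target); `sigma_scale`
  inflates them to create deliberately overlapping classes. The trial's
  per-class spectral statistics were never published, so these defaults are
  stated choices, not fits.
* **SBW link.** Each plot draws a latent boll quality `q` uniform on a
  density-shifted window of width 0.5 (D1: [0.5, 1] … D5: [0.1, 0.6]).
  The lint class's red-edge and NIR means shift upward by `q·Δ` with
  Δ = 0.10 reflectance, and each sampling point's SBW is
  `4.5 + 25·q·Δ + ε`, `ε ~ N(0, 0.215²)` truncated positive — about
  4.8–7.0 g, a realistic machine-harvest cotton range. Two requirements
  drove the windowed-uniform design: SBW must *decline with planting
  density* (the trial's headline agronomic pattern) and must remain
  *recoverable from lint spectra*. A density-independent latent cannot give
  the first; a density effect added to SBW outside the spectral link would
  destroy the second. Routing the density effect through `q` satisfies
  both. With these defaults `Var(q) ≈ 0.042`, so the spectra-explainable
  share of SBW variance is `(25·0.10)²·0.042 / ((25·0.10)²·0.042 + 0.215²)
  ≈ 0.85`, deliberately above the ~0.80 a fitted model should reach after
  estimation losses.
* **Determinism.** One master seed per scene; per-plot sub-seeds are drawn
  from it, so scenes are bit-reproducible.

What the generator does **not** emulate: illumination/BRDF variation,
mosaicking artifacts, georeferencing error, mixed pixels at boll edges,
within-plot fertility gradients, or any texture/structure signal. Passing
tests therefore demonstrate that the *pipeline mechanics* are correct and
that parameter recovery works when the model family matches the data; they
do not validate accuracy on real imagery.

## Classifiers and their conventions

`fit_class_statistics()` estimates unbiased means and covariances per class
from ROI pixels (≥ 6 pixels per class, i.e. more than the five bands),
priors proportional to ROI pixel counts (or uniform), and a count-weighted
pooled covariance. Near-singular covariances get `λI` added with
`λ = 1e-6 · tr(Σ)/5` plus a 1e-12 absolute floor so a constant-valued class
remains usable.

Conventions that classical desktop implementations leave undocumented are
fixed here explicitly:

* Maximum likelihood ties and Mahalanobis ties break to the smallest class
  index (soil < stems_leaves < lint).
* Mahalanobis uses the *pooled* covariance — the standard remote-sensing
  formulation of the classifier.
* The parallelepiped box half-width `k` defaults to 2 standard deviations
  and is exposed as a parameter; a pixel inside several boxes goes to the
  class with the smallest maximum standardized deviation, and a pixel
  inside none stays unclassified.
* Classification is purely per-pixel; "object-based" extraction is realized
  by converting the lint class into a mask (`extract_boll_mask()`), not by
  segmentation into connected components, which nothing downstream needs.

Accuracy is assessed on a stratified random sample of ground-truth pixels
*disjoint from the training ROIs* (`sample_eval_pixels()`); evaluating on
training ROIs, as desktop tools do by default, inflates accuracy.
Unclassified predictions occupy their own confusion-matrix column and count
as errors in both overall accuracy and the Kappa marginals — this is what
makes the parallelepiped's scores drop on overlapping scenes while the
matrix total is preserved.

## Vegetation indices

The fifteen-index pool is computed from band means per sampling point (not
as means of per-pixel indices — the pixel-level path exists separately for
mapping). Printed formula tables for these indices are frequently corrupted
by typesetting; the canonical literature forms are implemented and
unit-tested against independent transliterations. Two required explicit
decisions, both configurable:

* **RESAVI** uses the canonical red-edge substitution
  `(1+L)(nir−re)/(nir+re+L)`; a product variant
  `(1+L)·(nir−r)/(nir+r+L) · (nir−re)/(nir+re)` matching one plausible
  reading of the corrupted source is selectable via
  `resavi_form = "product"`.
* **MSR** is read as `(nir/r − 1)/(√(nir/r) + 1)`, its standard form.

Zero denominators yield flagged `NA`s with a warning, never silent
infinities; records missing any selected feature are excluded from modeling
with a logged count. Limit identities (each red-edge index collapses to its
red counterpart as `re → r`) are enforced by tests.

## Feature fusion

Pearson |r| with SBW captures linear association; mean |SHAP| from an
XGBoost regression (300 trees, depth 4, learning rate 0.05, subsample 0.8,
seeded — hyperparameters fixed because the source analysis left them
unstated) captures nonlinear contribution, with the tree-path-dependent
TreeSHAP attribution whose per-sample efficiency
(Σ attributions + base = prediction) is asserted in tests against exact
coalition enumeration on small models. The two descriptions of the fusion —
averaging *rankings* versus averaging *values* — conflict; value-averaging
after sum-to-one normalization is the default because a "cumulative
contribution reaches 60 %" selection rule is only meaningful on an additive
score scale, which rank averages do not provide. Rank-averaging remains
available (`method = "rank"`). Ties in the fused ordering break
alphabetically by index name. The selected set is the shortest prefix whose
fused scores sum to the threshold, so selection size is monotone in the
threshold by construction.

SHAP is computed on the full sample table, reflecting analysis-time usage;
for leakage-free modeling the same function accepts the calibration subset.

## Split, models, metrics

The 7:3 calibration/validation split stratifies on year × variety ×
density. With the trial's 32 equal strata of 9 samples, independent
per-stratum rounding cannot reproduce the published margin counts (all of
which equal `round(0.7·margin)`), so the allocator takes `floor(0.7·n)` per
stratum and places the remaining units one at a time on strata whose three
margins are all still under-allocated, preferring the largest total
deficit. The allocation is a deterministic function of the design; the seed
only randomizes membership within strata.

* **Ridge** is the closed form `(XᵀX + αI)⁻¹Xᵀ(y − ȳ)` with an unpenalized
  intercept, over α ∈ {0.001, 0.01, 0.1, 1, 10, 100}. This parameterization
  (penalty added to the raw Gram matrix) is pinned by the package's
  closed-form oracle tests.
* **Random forest** runs on the exact published grid; `min.node.size`
  implements the minimum-samples-to-split parameter and `min.bucket` the
  minimum leaf size.
* **Neural network** is one hidden ReLU layer (the smallest architecture
  consistent with a single `hidden_size` grid), linear output, squared
  error, minibatch Adam, He initialization, fixed epochs, no early
  stopping, seeded end to end. Features are z-scored from calibration
  statistics for ridge and the network (the convention when regularization
  scales or gradient conditioning matter; trees are scale-equivariant and
  use raw features); the network also z-scores the target internally for
  optimizer stability and back-transforms predictions.

Grid search uses five-fold cross-validation with folds stratified by
density, scored by mean out-of-fold R², winner refit on the full
calibration set. `R²` centers on the mean of the *observed* values —
a printed variant that centers on predictions exists behind
`center = "predicted"` for audit, but the observed-mean definition is the
one under which perfect prediction always scores 1.

The test-scale (`profile = "fast"`) grids are: ridge unchanged; random
forest 100 trees, depth {3, 5, 10}, sqrt features, leaf {1, 4}; network
hidden {32, 64}, learning rate 0.01, 200 epochs, batch 16. These are the
problem sizes used by the test suite and the acceptance script; the full
grids are available via `profile = "full"`.

## Pixel mapping and its scale caveat

`predict_pixel_sbw()` recomputes the selected indices from *single-pixel*
reflectance inside the boll mask and applies the trained model — the only
reading consistent with pixel-colored SBW maps. The model, however, was
trained on sampling-point *mean* reflectance. Single-pixel indices are
noisier, and because several indices are nonlinear in the bands, pixel
noise induces a small Jensen-type offset in predictions that aggregation to
plot means does not remove. Consequently plot-aggregated maps carry a
slight overall bias relative to the model's own validation predictions;
relative-error diagnostics stay well inside 15 % on the benchmark, but the
regression-to-the-mean pattern (over-prediction of low-SBW, under-prediction
of high-SBW units) is cleanest on the validation predictions themselves,
and that is where the package's tests assert it.

## Numerical choices and degenerate inputs

* Covariance regularization as above; pooled covariance regularized the
  same way.
* Parallelepiped zero per-band standard deviations are floored at machine
  epsilon with a warning.
* Reflectance is clipped to [0, 1] at generation; SBW draws are truncated
  positive by redrawing.
* Sampling-point polygons with no lint pixels produce flagged invalid
  records and the pipeline continues; an empty boll mask warns and
  downstream zonal operations return flagged missing values.
* All stochastic steps (scene, ROIs, evaluation pixels, folds, subsampled
  boosters, forest and network fits) take explicit seeds; rerunning a
  configuration reproduces the manifest metrics exactly.

## Known limitations

* The synthetic benchmark's simplifications listed above mean measured
  accuracies characterize the method under its own assumptions, not field
  performance.
* The latent-quality link is linear with Gaussian noise; saturation of
  broadband indices at high biomass, a plausible cause of high-end
  underestimation in real canopies, is represented only indirectly through
  the regression-to-the-mean pattern.
* Mahalanobis inherits whatever the pooled covariance mixes together; with
  strongly heteroscedastic classes, maximum likelihood is the better
  default, and the pipeline uses it as such.
* The CLI is a thin wrapper intended for scripted runs on fixture bundles;
  interactive ROI digitization and map rendering beyond GeoTIFF export are
  out of scope.
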