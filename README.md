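# cottonsbw

Estimation of cotton single-boll weight (SBW, the mean dry weight of one
opened boll, in grams) from five-band UAV multispectral reflectance imagery
(blue / green / red / red-edge / NIR). After defoliant application a cotton
canopy is a mixture of bright lint, exposed soil and senescent stems and
leaves, so canopy-averaged spectra are badly diluted for organ-scale traits.
The package implements an object-based workflow for researchers in crop
phenotyping and precision agriculture:

1. **Boll extraction** — supervised per-pixel classification into
   soil / stems-leaves / lint with three classical remote-sensing
   classifiers, trained from labeled regions of interest (ROIs):
   * *maximum likelihood*:
     `argmax_c [ ln pi_c − ½ ln|Σ_c| − ½ (x−μ_c)ᵀ Σ_c⁻¹ (x−μ_c) ]`
   * *Mahalanobis distance*: `argmin_c (x−μ_c)ᵀ Σ_pooled⁻¹ (x−μ_c)`
   * *parallelepiped*: box test `|x_b − μ_cb| ≤ k·σ_cb` in every band,
     unmatched pixels left unclassified.
   The lint class becomes a boll mask applied to the reflectance.
2. **Accuracy assessment** — confusion matrix on held-out labeled pixels;
   overall accuracy `OA = Σ_i A_ii / N` and the Kappa coefficient
   `κ = (p₀ − p_e)/(1 − p_e)`; unclassified predictions count as errors.
3. **Boll-scale features** — mean masked reflectance per sampling-point
   polygon and 15 vegetation indices (NDVI, SAVI/OSAVI and red-edge
   variants, RDVI/RERDVI, EVI, NLI/NLVI, TVI, RTVI, MSR, DVI/REDVI), with
   soil-adjustment constants L = 0.5, Y = 0.16.
4. **Feature selection** — |Pearson r| with SBW fused (equal weights, after
   sum-to-one normalization) with mean |SHAP| importance from an XGBoost
   regression; features selected to 60 % cumulative fused contribution.
5. **SBW regression** — ridge (closed form, α grid), random forest and a
   one-hidden-layer ReLU network, each tuned by exhaustive grid search with
   five-fold cross-validation on a year × variety × density stratified 7:3
   calibration/validation split; scored by `R²` and `RMSE` (g).
6. **SBW mapping** — per-pixel predictions inside the boll mask, aggregated
   to plot means, with relative-error and masked-background diagnostics.

Because no UAV imagery is distributed with the underlying field trial, the
package ships a seeded synthetic scene generator (`generate_scene()`)
emulating a two-year, five-density (D1–D5), four-variety (V1–V3 + CK check)
trial of 48 plots × 3 sampling points per year. Each plot carries a latent
boll quality that shifts the lint red-edge/NIR reflectance and sets SBW
through a linear link with Gaussian noise, so the spectra→SBW relation is
recoverable by construction and every pipeline stage is testable end to end.

## Worked example

```r
library(cottonsbw)
man <- run_pipeline(default_run_config(profile = "fast", seed = 1))
```

which logs, stage by stage:

```
[classify] year 2023: maximum_likelihood OA 100.00%, mahalanobis OA 100.00%, parallelepiped OA 80.47%
[classify] year 2024: maximum_likelihood OA 100.00%, mahalanobis OA 100.00%, parallelepiped OA 77.70%
[features] 288 sampling-point records, 15 indices
[select] 5 features at 60% cumulative contribution: NLVI, DVI, NLI, TVI, NDVI
[train] ridge: calibration R2 0.804 | validation R2 0.775, RMSE 0.258 g
[train] random_forest: calibration R2 0.844 | validation R2 0.739, RMSE 0.278 g
[train] neural_net: calibration R2 0.828 | validation R2 0.771, RMSE 0.261 g
[map] masked background 92.15%; 100% of plots within 15% relative error
```

Reading the output: on the default well-separated scene the Gaussian
classifiers are essentially perfect while the box classifier loses ~20
points of overall accuracy to unclassified boundary pixels; five indices
carry 60 % of the fused Pearson+SHAP contribution; the best model explains
~78 % of validation SBW variance with a 0.26 g error, close to the
generator's noise floor (σ_ε = 0.215 g); and pixel-to-plot aggregation keeps
every plot's relative error under 15 %. The returned manifest holds the same
numbers programmatically (`man$accuracy`, `man$ranking`, `man$models`,
`man$plot_summary`, `man$predictions`), and `out_dir` in the configuration
writes GeoTIFF/GeoJSON/CSV artifacts readable by the package's own readers.

Individual stages are plain functions — `generate_scene()`,
`fit_class_statistics()`, `classify_maximum_likelihood()`,
`extract_boll_mask()`, `zonal_mean_reflectance()`,
`compute_vegetation_indices()`, `fuse_and_select()`, `split_dataset()`,
`train_sbw_model()`, `predict_pixel_sbw()`, `aggregate_to_plot()` — and a
thin command-line wrapper with `simulate` / `classify` / `features` /
`select` / `train` / `map` / `run` subcommands lives at
`inst/cli/sbw_pipeline.R`.

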