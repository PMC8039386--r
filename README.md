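# gastrolayer

Quantitative analysis of the five-layer structure of the gastric wall in
oral contrast-enhanced ultrasound (OCUS), and a screening statistic built on
it.

In OCUS the contrast-filled stomach forms an acoustic window through which
the wall images as five alternating echogenic bands (mucosa, muscularis
mucosa, submucosa, muscularis propria, serosa). Diseases of the stomach
change the *relative thickness* of these bands, so the vector of layer
fractions `x = (x1, …, x5)`, `Σ xᵢ = 1`, is a compact screening feature.
The package is aimed at medical-image-analysis researchers who want a fully
testable implementation of that measurement chain:

* **`generate_phantom()` / `generate_cohort()`** — synthetic layered-wall
  speckle phantoms with exactly known geometry (unit-mean gamma speckle,
  known band thicknesses, optional curvature, three annotation styles via
  `make_labels()`), standing in for clinical images that cannot be shipped;
* **`build_unet()` / `train_detector()` / `predict_mask()`** — a compact
  encoder–decoder segmentation network (3×3 convolutions + ReLU, 2×2 max
  pooling with channel doubling, transposed-convolution upsampling with skip
  concatenation, per-pixel softmax), implemented in vectorized R, plus
  `iou()` and `mask_to_roi()`;
* **`srad_filter()`** — speckle-reducing anisotropic diffusion
  `∂I/∂t = div[c(q) ∇I]`, where the instantaneous coefficient of variation
  `q` (from `icov()`) drives the diffusivity `c` (reciprocal or exponential
  form) calibrated by the speckle scale `q0` of a homogeneous window;
* **`stratify_wall()` / `aggregate_columns()`** — Sobel gradient peaks
  along sampled columns locate the four inter-layer boundaries; differencing
  boundary rows gives `x`;
* **`fit_screening_model()` / `evaluate_pipeline()`** — the distance
  statistic `d = sqrt(Σᵢ₌₁⁴ (xᵢ − sᵢ)²)` against the normal-wall standard
  `s`, a threshold fitted on a stratified 70/30 split ("abnormal iff
  d ≥ threshold"), and the metric suite ACC / SENS / SPEC / PPV / NPV /
  MCC / F1 / AUC.

Results are tibbles; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(gastrolayer)

# a speckled phantom with known layering (4-look speckle, 120 px wall)
truth <- generate_phantom(phantom_spec(height = 220, width = 128,
                                       wall_top_row = 60, wall_thickness = 120,
                                       speckle_looks = 4, seed = 7))

# ROI crop -> SRAD (100 iterations) -> column-wise Sobel stratification
st <- stratify_wall(truth$image, truth$wall_mask, pipeline_config())
round(rbind(truth = truth$proportions, recovered = st$x), 3)
#>            [,1]  [,2]  [,3]  [,4]  [,5]
#> truth     0.275 0.133 0.150 0.150 0.292
#> recovered 0.275 0.127 0.154 0.144 0.300

# distance to the published normal-wall standard: small, i.e. "normal"
s <- c(0.278, 0.133, 0.154, 0.154, 0.280)
wall_distance(st$x, s)
#> [1] 0.01175569
```

Every recovered layer fraction is within 0.01 of the ground truth, and the
wall's distance to the normal standard is far below any plausible decision
threshold. A full screening experiment on a labeled cohort (28 normal, 12
with the mucosal fraction doubled):

```r
cohort <- generate_cohort(28, 12, abnormal_effect = list(layer = 1, factor = 2),
                          base_spec = phantom_spec(height = 200, width = 128,
                                                   wall_top_row = 50),
                          thickness_range = c(100, 120), seed = 42)
evaluate_pipeline(cohort, pipeline_config(seed = 42))
#> <pipeline_evaluation> 40 cases (0 excluded), threshold 0.0842
#> # A tibble: 1 × 15
#>     ACC  SENS  SPEC   PPV   NPV   MCC    F1   AUC    TP    TN    FP    FN ...
#> 1     1     1     1     1     1     1     1     1     4     8     0     0
```

The threshold is fitted on the 28-case training split; the 12-case test set
is classified perfectly because the simulated thickening (layer-1 fraction
0.278 → ~0.435) moves `d` an order of magnitude beyond the normal jitter.

See `vignettes/gastric-wall-stratification.Rmd` for the model, the numerical
choices and the phantom's limitations.

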