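---
title: "Quantifying gastric-wall layering in contrast-enhanced ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastric-wall layering in contrast-enhanced ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
set.seed(1)
```

## The problem

After a patient drinks an ultrasound contrast agent, the filled stomach forms
an acoustic window through which the gastric wall images as five alternating
echogenic bands: mucosa, muscularis mucosa, submucosa, muscularis propria and
serosa. Disease — gastritis, ulcers, tumors — changes the *relative
thickness* of these bands long before gross morphology changes, so the vector
of five layer-thickness fractions is a compact, interpretable screening
feature. `gastrolayer` implements the full measurement chain:

1. **Detection** — a compact U-net segments the wall region of interest.
2. **Speckle filtering** — speckle-reducing anisotropic diffusion (SRAD)
   smooths the multiplicative speckle inside each band while sharpening the
   inter-band edges.
3. **Stratification** — Sobel gradients sampled along image columns locate
   the four inter-layer boundaries; differencing the boundary rows yields
   the proportion vector $x = (x_1,\dots,x_5)$, $\sum_i x_i = 1$.
4. **Screening** — a wall is compared to the normal-wall standard
   $s$ through the distance statistic
   $d = \sqrt{\sum_{i=1}^{4}(x_i-s_i)^2}$ and flagged abnormal when
   $d \ge$ a threshold fitted on a training split.

Because clinical images cannot be redistributed, the package ships a
synthetic phantom generator with exactly known geometry; every stage is
developed and tested against that ground truth.

```{r pipeline}
library(gastrolayer)

truth <- generate_phantom(phantom_spec(height = 220, width = 128,
                                       wall_top_row = 60, wall_thickness = 120,
                                       speckle_looks = 4, seed = 7))
st <- stratify_wall(truth$image, truth$wall_mask, pipeline_config())
rbind(truth = round(truth$proportions, 3), recovered = round(st$x, 3))
```

## The phantom: what it emulates, and what it does not

A phantom is a piecewise-constant template — five horizontal bands of
alternating bright/dark echogenicity over a darker lumen, optionally bowed by
a half-sine vertical offset — multiplied by i.i.d. unit-mean gamma noise with
variance $1/L$, where $L$ is the number of looks. This is the standard
fully-developed-speckle model and exactly the noise family SRAD is designed
for; `speckle_looks = 4` is the package default, a realistic value for
compounded B-mode imaging. Integer band thicknesses are the proportions
times the wall thickness, rounded half-up for layers 1–4 with the remainder
assigned to the deepest layer, so ground-truth boundary rows reconstruct the
quantized proportions exactly.

What the phantom deliberately does **not** model: a point-spread function,
attenuation or time-gain compensation, refraction and shadowing artifacts,
anatomical texture within layers, or operator-dependent orientation. Tests
passing on phantoms therefore demonstrate that the algorithms are correct
under their stated assumptions (layered structure crossing the image rows,
multiplicative speckle, positive intensities) — not that the pipeline meets
any particular accuracy on clinical data.

Cohorts for screening experiments jitter the normal template on the simplex
(multiplicative log-normal, $\sigma = 0.05$, renormalized) and derive the
abnormal template by scaling one layer's fraction — by default doubling the
mucosal fraction, emulating mucosal thickening — and renormalizing. Setting
the factor to 1 yields a null cohort with no class signal, used to check that
the screening model does not hallucinate separation.

## SRAD

Given a strictly positive image $I$, SRAD evolves
$\partial I/\partial t = \mathrm{div}\!\left[c(q)\,\nabla I\right]$ with
zero-flux boundaries. The instantaneous coefficient of variation

$$q = \sqrt{\frac{\tfrac12(|\nabla I|/I)^2 - \tfrac1{16}(\nabla^2 I/I)^2}
{\left[1 + \tfrac14(\nabla^2 I/I)\right]^2}}$$

is large at edges and fluctuates around the speckle scale $q_0$ — the
coefficient of variation of a homogeneous region — inside uniform speckle.
Both published forms of the diffusivity are implemented:
reciprocal $c = 1/(1+r)$ and exponential $c = e^{-r}$ with
$r = (q^2-q_0^2)/[q_0^2(1+q_0^2)]$; both equal 1 at $q = q_0$ and vanish as
$q \to \infty$. The reciprocal form is the default.

Numerical choices, all of which matter for reproducibility:

* **Discretization.** Explicit 4-neighbor scheme; gradient and Laplacian by
  central differences with replicated (Neumann) borders. The default
  time step is $\Delta t = 0.05$ with 100 iterations; $\Delta t \le 0.25$ is
  the stability bound of the stencil and is enforced.
* **Conservative flux form.** The divergence uses arithmetic-mean edge
  diffusivities, $\sum_{nb} \tfrac12(c_p + c_{nb})(I_{nb} - I_p)$, which
  preserves the global intensity sum to floating precision and makes the
  zero-flux boundary exact.
* **Clamping.** The $q^2$ numerator can go negative in strong deflections
  and both $c$ forms exceed 1 where $q < q_0$; the numerator is clamped at 0
  and $c$ clipped to $[0,1]$ by default (switchable via `clamp_c`).
* **Positivity.** The update is floored at $10^{-12}$ times the image mean,
  keeping intensities strictly positive without breaking the scale
  invariance $\mathrm{SRAD}(kI) = k\,\mathrm{SRAD}(I)$.
* **$q_0$ per iteration.** The speckle scale is recomputed from the
  homogeneous window at every iteration, so it decays as speckle is removed;
  the window is user-selected (in the automated pipeline: the lumen rows
  above the wall inside the ROI crop). $q_0 = 0$ (noise-free window) is
  degenerate and yields $c \equiv 1$, i.e. plain isotropic diffusion.

## Stratification

Layers are assumed to stratify along ROI rows — a column crosses all five
layers — so real images must be cropped/oriented accordingly; this is a
documented requirement, not an inference. For each sampled column the Sobel
gradient magnitude is smoothed with a 1-D Gaussian ($\sigma = 1$ row) and
local maxima are picked, with three tie/noise rules:

* plateaus (exact ties, common in noise-free steps) count once, at the
  rounded-up center, which maps a two-pixel step response exactly onto the
  "first row of the next layer" boundary convention;
* peaks closer than `min_separation` (default 3 rows) are merged, keeping
  the larger;
* peaks within `min_separation` of the wall's outer edges are discarded —
  those responses belong to the outer wall boundary, not to interior layers.

The wall extent is read from the mask when one is available (preferred) and
from the outermost gradient peaks otherwise. If fewer than four interior
peaks survive, the column is reported "cannot stratify" with the count found;
an ROI is unstratifiable when fewer than half the sampled columns succeed.
Nine columns evenly spaced across the middle 80% of the ROI width are
sampled by default; per-column proportion vectors are averaged
component-wise and renormalized (averaging before renormalizing is a
documented choice — pixel quantization leaves $\sim 10^{-3}$ drift in the
mean). Recovered proportions are invariant to uniform intensity scaling, and
sub-pixel boundary localization is out of scope.

## Screening

The standard vector is the component-wise mean of reference proportion
vectors, **not** renormalized — the published normal standard
$s = (0.278, 0.133, 0.154, 0.154, 0.280)$ sums to 0.999 and is reproduced
as printed. By default $s$ is estimated from training-set normals only (a
"standard" wall should be normal); `use_all_for_s = TRUE` averages over all
training records for comparison.

The distance statistic sums **four** squared differences, exactly as the
formula is printed; the fifth coordinate is deliberately excluded, and the
package does not "correct" this (a flag `include_fifth` exists, default
off). The omission is tested explicitly: two vectors differing only in the
fifth component have $d = 0$. Note the five proportions sum to 1, so the
fifth coordinate is jointly — though not individually — redundant.

Threshold fitting enumerates midpoints between consecutive distinct training
$d$ values (plus sentinels) and maximizes training accuracy under the fixed
convention *abnormal iff $d \ge$ threshold*; ties go to the smaller
threshold and boundary cases to "abnormal", both favoring sensitivity, which
is the natural asymmetry for a screening tool. The cohort split is
stratified by label with largest-remainder allocation, so a 70/30 request on
10 records gives exactly 7/3 while keeping both classes on both sides. AUC
is computed as the Mann–Whitney probability with half credit for ties,
equivalent to the trapezoidal area under the empirical ROC of the
thresholded-$d$ classifier family. Metrics with zero denominators are
reported `NA`, never 0.

## Problem sizes and what the checks compute

The test suite and the acceptance script run entirely on phantoms at desk
scale, chosen to exercise each property without waste: stratification
recovery on 20–50 speckled walls of 100–200 px (100 SRAD iterations);
screening on cohorts of 40 (28 normal / 12 abnormal, test sets of 12), with
the null-effect AUC averaged over 5 independent cohorts because a single
12-case test AUC has sampling noise of roughly ±0.1; detector training on
20 phantoms of 256×256 resized to a 64×64 input, depth-2, 8-channel
network, ≤ 30 epochs. The full-resolution, depth-4 configuration of the
published architecture (ten 3×3 convolutions and four poolings in the
contracting path, channel counts 16–256) is available through
`unet_config(input_size = c(256, 256), depth = 4, base_channels = 16)`; the
compact settings are a budget choice, not an architectural one.

## Known limitations

* The U-net is trained with plain per-image Adam steps and no augmentation;
  optimizer, epochs and input size are config-exposed because the published
  description specifies none of them.
* Phantom realism is deliberately limited (see above); absolute IoU or AUC
  values on phantoms say nothing quantitative about clinical images.
* The screening model is binary; three-way separation (normal / benign /
  cancer) is applied pairwise by relabeling, not modeled jointly.
* Between-group p-values are not part of the screening report; a rank-sum
  utility (`d_rank_test()`) is provided for exploratory comparison only.
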