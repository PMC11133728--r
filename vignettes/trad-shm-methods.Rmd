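---
title: "Models and methods behind tradshm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tradshm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices in `tradshm`:
what each model assumes, which parameters matter, what the synthetic data
does and does not emulate, and where the design was genuinely open.

## The bioassay in brief

Stamen hairs of *Tradescantia* clone 4430 are chains of single cells that
are blue in the unstressed state and turn pink under mutagenic or
physiological stress. The assay statistic is the number of pink cells per
1000 stamen hairs scored. Two exposure designs are covered: potted plants on
soil spiked with diesel oil at 0, 100, 1000, 10000 and 100000 mg/kg
(the top dose kills the plants, so it contributes no observations), and
plants exposed outdoors to airborne particulate matter quantified by daily
PM2.5/PM10 series.

## Synthetic single-cell images

`generate_cell_image()` renders one cell per specification:

* **Color.** Cell pixels are drawn i.i.d. per channel from a Gaussian with
  the class mean and SD, clipped to [0, 255] and rounded to 8 bits. The
  default class models are the published per-class pixel statistics of the
  real dataset: blue (97.6, 91.7, 122.0) ± (25.0, 31.8, 45.7), pink
  (143.9, 97.1, 140.2) ± (33.6, 34.1, 39.4). A per-cell
  `minority_fraction` of pixels is drawn from the *other* class's model,
  emulating the pinkish pixels inside blue cells (and vice versa) that make
  the classification non-trivial. The fraction is capped below 0.5 so the
  label remains the majority color; the default range [0.05, 0.25] is a
  modeling choice — the source images show visible cross-class pixels but
  no measured fraction.
* **Shape.** Filled ellipses (round/oval), rounded rectangles
  (rectangular) and high-aspect capsules (elongated), with aspect ratios
  1 / 0.62 / 0.7 / 0.28. Only the shape vocabulary is taken from the real
  data; the geometry is idealized.
* **Size.** Bounding-box sides are drawn log-uniformly over [13, 256] px,
  matching the published size bounds and giving many small and few large
  cells, as in microscopy crops of tapering hairs.
* **Vacuoles.** 0–2 interior ellipses whose pixels are pulled halfway
  toward white, emulating the brighter vacuole regions.
* **Background.** Pure white (255, 255, 255), so background exclusion is
  exactly testable.

What the generator does **not** emulate: optics (focus, illumination
gradients, chromatic noise correlated across channels), spatial texture
(real pigment varies smoothly, not i.i.d.), cell-wall edges, or touching
cells. Tests passing on this data therefore demonstrate correctness of the
pipeline and learnability of the color signal — not performance on real
micrographs.

The default dataset composition mirrors the real one: 102 images per class
(204 total), stratified splits of 164/40, and 84/22 for a 106-image subset.

## The interval baseline

A pixel is pink iff all three channels lie within pink mean ± half-width,
and blue analogously; defaults are the published intervals
(133.83, 75.84, 182.24) ± 27 and (70.99, 75.87, 163.05) ± 27. The
conjunctive ("all channels") reading makes the two default classes mutually
exclusive because their red intervals are disjoint — the package asserts
this. The cell label is the larger of the two pixel counts over
non-background pixels; exact ties (including 0–0) default to blue, the
unstressed wild-type state, and the tie rule is an argument.
`calibrate_profile()` re-estimates interval centers as per-class means over
cell pixels of sampled images and the half-width as the pooled SD, with the
published fixed value available via `half_width = 27`.

Background masking uses a near-white threshold (all channels ≥ 250 by
default) rather than exact white, so anti-aliased crop borders are excluded
on real PNG crops.

## Architectures and the training engine

No deep-learning framework is involved: the package carries a compact CNN
engine (Rcpp + BLAS). Convolutions are im2col patch matrices multiplied by
flattened kernels; patch buffers and conv gemms run in single precision
(they dominate memory traffic), while parameters, gradients and everything
else stay double. Maximum pooling stores argmax indices for its backward
pass. Correctness is established by finite-difference gradient checks for
every layer type in the test suite.

* **TinyVGG**: two blocks of (conv 3×3 s1 p1 → ReLU → conv → ReLU →
  2×2 max-pool), 10 channels, then flatten → linear; input 64×64, so the
  flattened width is 10·16·16.
* **VGG16 (batch-norm variant)**: the canonical 13-conv feature stack in
  five blocks (2,2,3,3,3 at widths 64–512), conv → BN → ReLU, 2×2 pooling
  between blocks; input 227×227 leaves 7×7 maps. The classifier head
  (dropout 0.5 → linear → ReLU → linear) has no published width; the
  default is 256 — the canonical 4096 would put ~100 M parameters behind a
  ~100-image task — and both width and dropout are arguments.
* **ResNet34**: 7×7 s2 stem with BN/ReLU and 3×3 s2 max-pool, stages of
  basic blocks [3,4,6,3] at widths 64/128/256/512 with 1×1 projection
  shortcuts on downsampling, global average pooling, final linear layer:
  33 convolutions + 1 linear = 34 weighted layers. A basic block with zero
  conv weights is exactly the identity on non-negative input, which the
  tests assert.

Weight initialization is He-uniform (fan-in) under a fixed seed; final
biases start at zero. Optimizer defaults per architecture follow the
reference setup (Adam 0.001 / SGD 0.005 / SGD 0.01, batch 32, 20 epochs,
cross-entropy loss); SGD momentum defaults to 0 because no value is
published.

### Batch normalization at desk scale

Two related choices deserve emphasis. Running BN statistics default to a
*cumulative* moving average (the torch `momentum = NULL` convention) rather
than an exponential one. More importantly, `train_model()` re-estimates the
running statistics over the training images with the *current* weights
before every evaluation (a precise re-estimation pass, off via
`bn_recalibrate = FALSE`). With only a handful of optimizer steps per epoch,
exponential averages lag the weights by many epochs: a network that
perfectly fits its training batches can still score at chance in evaluation
mode for several epochs. The re-estimation pass costs one extra forward
sweep per epoch and makes evaluation reflect the weights actually being
scored.

### Problem sizes

The package trains the full-resolution architectures on one CPU, which sets
the practical scale of its self-checks: the test suite trains all three
architectures on a 14-image zero-contamination dataset (10 train / 4 test,
batch 4) with early stopping once training accuracy reaches 0.90 within the
20-epoch budget. On such color-separable data all three reach that level in
a few epochs (the batch-normalized ones typically in 3). Mini-batches of 4
rather than 32 keep backpropagation caches of the 227×227 VGG16 near 1 GB;
batch size is a configuration field, and at 10 training images either choice
performs the same number of gradient updates per epoch ± 1.

## Exposure statistics

* **Saturating dose-response.** y = m·x/(h+x) + b: m is the saturation
  level (response units per 1000 hairs), h the half-saturation dose
  (mg/kg), b a small baseline. Fitting is bounded (m, h ≥ 0)
  Levenberg–Marquardt least squares. Starting values profile h over a
  60-point logarithmic grid spanning [min positive dose / 10, max dose ×
  10]; given h the model is linear in (m, b), so each grid point is a
  closed-form fit, and the grid minimum seeds the nonlinear optimizer.
  This avoids the degenerate local optimum at h → 0 (a step function
  through the dose means) that plain LM falls into from poor starts.
  Standard errors come from the final Jacobian cross-product; responses
  aggregate to per-dose medians by default (`aggregate = "none"` fits all
  replicates); doses whose responses are all missing — the lethal
  100000 mg/kg pots — are dropped and reported.
* **BSW averaging.** The exposure proxy is the mean of daily PM values over
  a window of `window_days` consecutive calendar days ending `lag_days`
  before the sampling date, inclusive (defaults 6 and 2). Only the window
  length and lag are published; the inclusive-end day convention is this
  package's, and both are parameters. Missing days inside the window are an
  error that lists the dates.
* **Origin regression.** The PM relations are published as intercept-free
  lines, so the slope is the least-squares estimate through the origin,
  Σxy/Σx², with the ordinary Pearson correlation reported alongside.

Simulated experiment defaults are the published study conditions: doses
{0, 100, 1000, 10000} mg/kg with the fitted curve (4.78, 125.12, 0.03),
5 replicates per dose and response noise SD 0.2 (a plausible between-sample
spread for median appearance rates of a few units); exposure series of 50
points with noise SD 5 on the published slopes 7.00 (PM10, 5–40 µg/m³) and
12.82 (PM2.5, 2–20 µg/m³).

## Seeds and reproducibility

Every stochastic operation takes an integer seed and runs under a local RNG
state. `run_pipeline()` and `compare_architectures()` derive per-stage seeds
from one master seed via a fixed string hash (`derive_seed()`), so a single
integer reproduces a whole run bit-for-bit; pipeline CSV outputs are
byte-identical across reruns, which the tests assert.

## Known limitations

* Synthetic colors are i.i.d. Gaussian per channel; real pigment is
  spatially correlated, so real-data accuracy will differ from synthetic
  accuracy in either direction.
* The engine is CPU-only and eager; it is built for correctness and
  reproducibility at desk scale, not for large datasets.
* Training wall-clock times are reported in comparison tables for
  information only and are never asserted.
* The interval baseline's conjunctive channel rule is one reading of the
  published description ("falls into these intervals"); the package fixes
  it and exposes the profile so a disjunctive variant can be studied by
  sensitivity analysis.
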