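---
title: "Methods: rosette segmentation, growth forecasting and fresh-weight chaining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rosette segmentation, growth forecasting and fresh-weight chaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rosettecast` implements a complete top-view rosette phenotyping analysis:
preprocessing of marked tray images, semantic-segmentation training and
evaluation, shape-feature extraction, stage-windowed direct multi-horizon
forecasting of projected area (PA), allometric fresh-weight (FW) estimation
chained onto the forecasts, and the statistical validation protocol. This
vignette documents the models, the tunable parameters, the synthetic-data
generator that stands in for non-shareable HTPP imagery, and the numerical
and design choices a maintainer should know about.

## The time model

Captures are hourly and daylight-only: `steps_per_day = 12` per day starting
at `first_hour = 8`, over DAS 10–23, `total_steps = 165`. Decimal DAS is
`day + hour/24`, rounded to two decimals for display (step 154 → 22.71).
Nights are simply absent from the grid, so one step is one measured hour and
12 steps equal one day; forecast horizons count measured steps.

Two internal inconsistencies of this grid are resolved as follows. First,
14 days × 12 steps would give 168 steps, not 165; the six training windows
(`table1_windows()`) are therefore stored as verbatim step constants of the
study design — T1 (60, 140, 141, 165), T2 (72, …), T3 (84, …), T4 (96, …),
T5 (72, 127, 128, 165), T6 (84, 127, 128, 165) — and the canonical grid
formula is used only for synthetic data, where it is self-consistent.
Second, the final step 165 falls at 16:00 (23.67) under the formula; the
validation checkpoint defaults to that last measured step, together with the
22.71 step, via `checkpoint_steps = c(154, 165)`.

## The synthetic-data generator

The generator defines the study conditions every test runs under. It
emulates three things the real platform produced.

**Growth trajectories** (`simulate_growth_curves`). Per-plant logistic
growth `PA(t) = K / (1 + exp(−r (t − t0)))` in decimal DAS, evaluated on the
daylight grid and multiplied by `(1 + ε)`, `ε ~ N(0, noise_sd)`. Rosette
growth to a pre-flowering plateau is near-linear in the mid-phase and
saturates before flowering, which the logistic reproduces; its increments
depend only on the current state, so the generator is short-memory by
construction (well within the 48-step lookback). Defaults: `n_plants = 110`
(the replicate-experiment population size), `K ~ N(10, 1.5²)` arbitrary
"area units" (the platform's area unit is not standardized, so the scale is
arbitrary and documented as such), `r ~ N(1.1, 0.12²)` per day,
`t0 ~ N(17, 0.8²)` DAS (so the plateau is approached just before the
T1–T4 training end at 21 DAS but not yet at the T5/T6 end of 20 DAS — the
property the window comparison probes), multiplicative noise 4%. A `linear`
law (constant per-step increment) provides the exact-recovery regime for
the OLS learner. Hull area is PA divided by a per-plant true compactness
drawn uniformly on (0.6, 1]; the perimeter column scales as the boundary of
the equivalent disc inflated by non-compactness. All generators restore the
caller's RNG state and are bit-reproducible given their seed.

**Tray images** (`render_rosette`, `compose_tray`, `soil_texture`). A
rosette is a union of rotated ellipses at the 137.5° phyllotaxis angle whose
scale is bisected until the rasterized mask hits the target PA within 5%;
leaves are painted in green hues over multi-octave value-noise soil in brown
hues (optional moss-green speckles stress-test refinement). Trays hold a
rows × cols grid of cells with four anti-aliased red disc markers inset in
the margin, then the whole tray is warped by a perspective homography onto a
padded canvas (the padding models the camera seeing the whole tray; without
it a strong warp can clip a marker and bias its centroid). Ground truth —
per-cell masks and marker coordinates before and after warping — is retained
for evaluation. What the renderer does *not* emulate: leaf venation,
shadows, specular highlights, overlapping neighbours, lens distortion.
Passing tests therefore demonstrate correctness of the geometry and the
learning machinery, not segmentation accuracy on real soil/plant imagery.

**Fresh weight** (`simulate_fresh_weight`). Destructive harvests at
14/17/20 DAS (and optionally the final day): randomly chosen plants get
`FW = slope·PA_true + intercept + N(0, noise_sd)` (defaults 0.8, 0.5, 0.25
FW units; a power-law form is available via `exponent`) computed from the
*noiseless* PA, and all their later records are dropped. The linear form
matches the strong linear PA–FW relation reported for rosettes; the
generator's allometry is stage-invariant, which is exactly the assumption
the cross-stage chain test verifies.

## Preprocessing

Marker detection is HSV-range thresholding (defaults: hue ≥ 0.95 or ≤ 0.04,
saturation ≥ 0.55, value ≥ 0.25) followed by 4-connected component
labelling; the four largest components are accepted (fewer is an error
naming the count; more are logged and trimmed) and their red-excess-weighted
centroids are ordered TL, TR, BR, BL by angle around their mean. The hue
window is deliberately tight: warped soil texture can reach hue ≈ 0.078, and
a loose threshold lets soil pixels merge into marker components and bias
centroids by over a pixel.

Rectification fits the 8-parameter homography mapping the detected corners
to their nominal positions and resamples bilinearly. One refinement pass
re-detects the markers in the rectified image — where they are again nearly
circular, so their centroids are unbiased — and composes the residual
correction. This matters because a projective warp moves a disc's centroid
away from the warped disc center; with refinement the composite residual
distortion is well under 0.1 px and per-cell mask IoU after
rectification + cropping exceeds 0.999 for corner perturbations up to 3% of
the tray diagonal (the stated perspective strength).

Cropping uses 1-based, inclusive, exactly `cell_px`-sized intervals in
row-major order; `scale_and_pad` scales the larger side to the network size
(512 default) and zero-pads symmetrically, recording scale and padding so
mask coordinates map back exactly (`map_points`/`unmap_points`).

## Segmentation: metrics, losses, the trainable harness, refinement

Hard metrics (IoU, precision, recall, Fβ) are computed on thresholded masks
from pixel confusion counts; the losses are soft: the dice loss replaces
indicators with probabilities in the Fβ formula, and the focal loss is the
mean of `−α_t (1 − p_t)^γ log p_t` with α = 0.25, γ = 2 and probabilities
clipped at 1e-7. Conventions worth stating: `α_t` is α on foreground and
1 − α on background, with `α = 1` reserved to mean "no class weighting" (so
γ = 0, α = 1 is exactly mean cross-entropy); empty-vs-empty comparisons
score 1 on all metrics (predicting no plant where there is none is correct —
this also keeps best-epoch selection sane when a validation cell is empty);
undefined precision/recall with a nonempty counterpart are 0, with a
message. The combined training loss is the exact sum dice + focal.

The default trainable segmenter (`pyramid_logistic`) is a compact
encoder–decoder: a fixed multi-scale encoder (each RGB channel at Gaussian
scales σ = 0, 2, 4 → 9 per-pixel features, standardized) and a learned
pixel-wise logistic decoder trained full-batch with Adam (lr 0.15, 5 steps
per logged epoch) on the combined loss. It trains in seconds on a CPU and
separates green foliage from soil essentially perfectly on synthetic crops;
it is registered behind a learner registry so heavier encoder–decoder
architectures can implement the same contract. Validation IoU/F1 are logged
every epoch on a held-out 10% split and the best-validation-F1 weights are
returned, ties resolving to the later epoch (better-calibrated under a
saturating F1). `epochs = 0` returns the untrained decoder (p = 0.5
everywhere) with an empty log. Training aborts on non-finite loss or
gradient.

Mask refinement is a deterministic morphological stand-in with a pluggable
contract (probability map or mask in, mask out): threshold at 0.5, drop
4-connected components below `min_area` (9 px default), fill interior holes
up to `max_hole_area` (25 px). It is idempotent. A dense-CRF refiner could
be substituted behind the same interface; no CRF parameters are published
for this pipeline, and the deterministic refiner keeps tests exact.

## Shape features

Projected area is the foreground pixel count times an optional area scale
(pixels² by default; the area unit of the study is unknown, so none is
asserted). The convex hull is taken over the *corners* of boundary pixels,
not their centers: the hull polygon then always encloses the rasterized
footprint, guaranteeing `hull ≥ PA` and compactness (= PA/hull, i.e.
solidity) in (0, 1] for every mask — with pixel centers a disc's hull would
be *smaller* than its pixel count and solidity would exceed 1. Perimeter is
the exposed-edge count of the largest 4-connected component (a filled s × s
square has perimeter 4s); raster perimeter conventions differ, so this one
is stated and tested. The absolute growth rate is the backward finite
difference of PA over a configurable window in steps.

## Forecasting

One direct model per (plant, horizon): a design row at base step `t` holds
the most recent `lookback` values of each dynamic feature (PA, hull area,
compactness by default; the perimeter is exported in the feature table and
can be added) plus calendar features of `t`, and its target is `pa(t + h)`.
The defaults follow the platform conventions: horizons {1, 6, 12, 24, 36,
42, 48} measured hours, lookback 48 (the "48-hour period" read as the
feature memory), per-plant models rather than pooled ones.

Numerical and design choices:

* **Lookback capping.** A 48-step lookback cannot fit every window (T4
  trains on 45 steps). The effective lookback per window and horizon is
  `min(lookback, train_len − h − min_rows + 1)`, preserving at least
  `min_rows = 10` training rows. `cap_lookback = FALSE` restores a strict
  configuration error instead.
* **Impossible horizons.** When `h` exceeds the training window length no
  (base, target) pair fits inside it (T4 and T6 at h = 48); those models
  fall back to persistence of the last training observation, with a
  warning. Designs with under 5 rows or a constant target fall back to the
  target mean.
* **Learners.** `gbt` is xgboost (max_depth 3, eta 0.3, 60 rounds, single
  thread — deterministic; boosters are stored as serialized bytes, which
  survives saving and avoids accumulating hundreds of live external
  handles). `linear` is ordinary least squares solved by SVD pseudoinverse:
  exact on consistent systems, bounded coefficients on underdetermined
  ones. The linear learner omits calendar features by default: day and hour
  encodings are step functions and periodic ramps that do not extrapolate
  linearly, whereas lagged features make the OLS baseline provably exact on
  noiseless constant-increment growth. Tree learners cannot extrapolate
  beyond their training range at all; recovery tests therefore use
  generators whose plateau is reached inside the training window, and this
  limit is inherent to the method, not a bug.
* **Leakage discipline.** A design row at `t` references no step after `t`
  except through its target. Predictions for test step `s` at horizon `h`
  are issued from base `s − h`, which must lie inside the observed period —
  by default ending at the training end, the scenario where measurement
  stops when training data ends. Under that default, 23-DAS predictions
  from the T5/T6 windows exist only at horizons ≥ 42 h, and horizon 1
  reaches only the first test step. Passing `obs_end` extends the cutoff
  for rolling forecasts. Corrupting all post-cutoff observations provably
  leaves predictions unchanged (tested).
* **Scoring.** MAE and RMSE per (plant, horizon) over the test window;
  global MAE/RMSE are their unweighted means. RMSE ≥ MAE always, with
  equality iff all absolute errors are equal.

`compare_windows` runs all six windows with a shared seed and extracts
checkpoint predictions; `checkpoint_error` compares windows at a checkpoint
over the horizons valid for every window present (at step 165 that is
{42, 48}).

## Fresh-weight chain and validation

`fit_fw_model` fits FW ~ PA by OLS on harvests inside a DAS range (14–20 by
default) and reports the Spearman R of the pairs — Spearman, not Pearson, is
used wherever a correlation is reported. `estimate_fw` applies the line and
clips negatives at zero (flagged). `score_chain` joins checkpoint *predicted*
PA (averaged over the valid horizons) with held-out harvest FW and reports
Spearman R and MAE in FW units. The chain design mirrors the study layout:
the allometry is fitted on early harvests of one experiment and evaluated on
30 final-day harvest plants of a replicate experiment.

Validation delegates the standard machinery to `stats`: `aov` for the
one-way ANOVA, `TukeyHSD` for simultaneous intervals at 95% family
confidence, `t.test` for observed-vs-predicted comparisons (paired, since
the same plants are observed and predicted; a two-sample variant is
available), significance flagged at α = 0.01. Degenerate cases have stated
conventions: identical groups give F = 0, p = 1; zero-variance paired
differences give p = 1 when the difference is 0 and p = 0 for an exact
nonzero shift. The test-suite oracles recompute ANOVA from raw sums of
squares and Tukey p-values from the studentized range distribution,
independently of the model-fitting route.

## The pipeline and problem sizes

`run_pipeline` executes simulate → harvest → imaging self-check → forecast →
FW chain → validation, writing CSVs and a checksum manifest; one root seed
derives all stage seeds, and a rerun with the same configuration and a
deterministic learner is byte-identical. The imaging stage renders small
trays at three grid steps, trains the segmenter on their ground truth,
re-detects, rectifies, segments, and verifies that extracted pixel areas
match the rendered truth — linking the imaging stages to the trajectory
scale without rendering all 165 steps.

Default problem sizes are chosen so the full test suite and the acceptance
script each run in about a minute on one CPU: populations of 24 plants for
window comparisons (110 for allometry fits, matching the replicate design),
100 64×64 crops for segmenter training, 20 random perspective warps for
rectification checks, trays of 2×4 96-px cells. These sizes are stated here
as the package's reduced-scale study conditions; all structural properties
(exactness limits, leakage, ordering of window difficulty) are
size-independent.

## Known limitations

* The renderer's rosettes are ellipse unions on procedural soil; real-image
  segmentation difficulty (moss, shadows, overlap) is out of scope, and the
  default segmenter is a pixel classifier, not a deep encoder–decoder.
* Tree-based forecasts cannot exceed the largest training target; forecasts
  into a still-accelerating phase are biased low. This drives the T5/T6
  degradation the validation stage measures, and matches the behaviour of
  boosted-tree forecasters generally.
* Recursive multi-step forecasting and neural sequence models are
  deliberately not implemented.
* Only projective (4-point) geometric correction is performed; radial lens
  distortion is not modelled.
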