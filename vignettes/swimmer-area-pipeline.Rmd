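---
title: "Estimating a swimmer's projected area from pool video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a swimmer's projected area from pool video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimarea)
```

## Why projected area

Active drag on a swimmer is commonly modelled with the steady-state
quadratic law `F_R = 1/2 · C_R · A · ρ · v²`, in which the projected
frontal area `A` is the reference area. `A` is not constant: it fluctuates
with every stroke cycle as arms, head and trunk change posture. A fixed
camera filming a tethered swimmer yields a stable scene in which `A` can
be segmented frame by frame, giving an area *time series* rather than a
single posture measurement. This package implements that segmentation and
the analyses applied to the series: between-camera regression, amplitude
spectra and dominant stroke-frequency extraction.

## The segmentation model

The swimmer in an underwater frame is a compact region whose colours
(skin, swimwear, cap, harness) differ from the bright bluish water, but
not uniformly: garments are dark, skin is mid-toned, and everything
carries the blue-green cast of the water column. The pipeline therefore
proceeds in two colour steps followed by shape cleanup:

1. **Garment unification.** The frame is converted to CIELAB and pixels
   strictly inside per-channel open intervals
   (`25.466 < L < 98.620`, `−46.336 < a < 8.860`, `−31.446 < b < 60.616`
   for the frontal camera) are repainted with a reference chest colour,
   `(27, 131, 135)` RGB. Under water, red light is strongly absorbed, so
   dark-red swimwear and a black cap appear as desaturated mid-dark tones
   that fall inside these intervals, while the water (strongly blue,
   `b < −31.4`) and white/yellow lane hardware fall outside. After this
   step the swimmer is one quasi-uniform colour mass.
2. **Water removal.** The lightness of the repainted frame, rescaled to
   `L* = L · 255 / 100`, is kept only inside the open interval
   `5 < L* < 160`. Bright water and lane ropes (`L* > 160`) and
   near-black pixels (`L* < 5`) drop out; the chest colour
   (`L* ≈ 127`) survives.
3. **Water-line filter.** Everything above the water-line row (`i = 97`
   in the frontal region of interest) is discarded. This removes the
   swimmer's mirrored reflection on the underside of the surface, which
   would otherwise survive both colour masks.
4. **Shape cleanup.** The retained region (background suppressed to
   black) is converted to grayscale (BT.601 luma), binarised with Otsu's
   threshold, components smaller than 3000 px are dropped
   (8-connectivity), internal holes are filled (4-connectivity
   background), and the surviving pixels are counted.

The area is reported in pixels. With a calibrated image scale (for
example ≈ 6.23 mm²/px) `pixels_to_m2()` converts to m²; because the
scale is constant for a fixed camera, pixel areas preserve all relative
structure (spectra, correlations) even without calibration.

## Conventions and numerical choices

* **CIELAB.** The published conversion equations do not fix an
  illuminant; we use the standard sRGB decoding with the D65 reference
  white `(X, Y, Z) = (0.95047, 1, 1.08883)` — the convention consumer
  cameras assume. `L` is kept natively on the 0–100 scale (so the garment
  thresholds apply verbatim) and `normalize_lightness()` is the explicit
  affine bridge to the 0–255 `L*` scale of the water interval. Grayscale
  uses the BT.601 weights `0.2989 R + 0.5870 G + 0.1140 B`, rounded half
  away from zero.
* **Strict bounds.** All colour intervals are open; boundary-equal values
  are excluded.
* **Row indexing.** Rows are 1-based as in R matrices (and in the
  original Matlab formulation): the water-line filter keeps rows
  `i ≥ 97`.
* **Binarisation.** Otsu's between-class-variance criterion over
  candidate thresholds 0–255, ties broken toward the lowest threshold;
  foreground is `value > T`. A constant image has no separable
  foreground and yields an all-zero mask plus a warning. If the
  binarised foreground covers more than half the region of interest the
  polarity is inverted (with a warning) — a guard against
  dark-swimmer/bright-water reversals.
* **Connectivity.** Foreground components use 8-connectivity and
  hole-filling uses 4-connected background — the standard complementary
  pair that avoids topological paradoxes. Both kernels are small C++
  routines; installed image toolboxes label with 4-connectivity only.
* **Degenerate frames.** A frame with no surviving blob reports area 0
  with a warning code rather than an error, so a 60 s run survives bad
  frames.
* **Lateral camera.** No lateral threshold values are published; the
  lateral configuration reuses the frontal constants and is meant to be
  customised per recording.

## Time-series analyses

* `linear_fit()` is ordinary least squares between frame-paired series
  (pairing by frame index assumes synchronized cameras); its R² equals
  the squared Pearson correlation. A constant response is reported as
  R² = 0 with a warning instead of an error, so batch runs survive
  degenerate trials.
* `compute_spectrum()` removes the mean, applies a rectangular window
  and zero-pads to `pad_factor` (default 8) times the record length.
  Padding interpolates the spectrum to a grid of
  `fs / (pad_factor · n)` Hz; five-significant-digit peak readings from a
  60 s record imply exactly this kind of interpolated readout. Amplitudes
  are scaled so a sinusoid of amplitude `A` peaks at ≈ `A`.
* `dominant_frequency()` searches at or above `min_hz` (default 0.1 Hz,
  excluding residual DC leakage) and breaks ties toward the lower
  frequency.
* `resistive_force()` and `net_force_acceleration()` are the closed-form
  drag model and Newtonian balance; the resistive force is passed as a
  signed quantity, so constant speed corresponds to `F_P = −F_R`
  exactly.

## The synthetic generator

Real pool footage from the original experiments is not distributable, so
validation uses a parametric scene generator with exact ground truth. A
scene contains: uniform water; a lane-rope band of alternating
yellow/white segments straddling the surface; a swimmer built from a
torso ellipse, head disc (upper part capped) and rotated limb
rectangles; optionally the swimmer's mirror image above the water line,
blended 30 % toward the water colour; and i.i.d. Gaussian pixel noise
(sd 3, clipped to [0, 255]). Ground truth counts silhouette pixels only —
never the reflection.

The default colours were chosen *once*, by their CIELAB coordinates, so
that the published constants are exercised rather than bypassed: skin
`(35,140,140)`, swimwear `(75,60,62)` and cap `(70,70,75)` lie strictly
inside the garment intervals (as underwater-desaturated garments do),
while water `(0,190,250)` fails the `b` bound and exceeds `L* = 160`, and
the lane colours fail the `b` or `L` bound and exceed `L* = 160`. The
default geometry yields ≈ 4900 px of silhouette in a 240 × 360 frame with
the water line at row 97, matching the shipped configuration verbatim.

`render_sequence()` modulates every silhouette size by
`1 + A·sin(2π f t + φ)` about fixed centres, so the ground-truth area
oscillates at the stroke frequency `f` (area scales with the square of
size; for moderate `A` the fundamental dominates). Phase `φ` emulates the
fact that frontal and lateral projections of one stroke peak at different
phases — which is why two cameras of the same swimmer can share a
frequency yet show near-zero R², as observed on real recordings.
`segment_synthetic_sequence()` is the streaming render-and-segment
counterpart that holds only one frame in memory, used for minute-long
runs.

What the generator does **not** emulate: articulated stroke kinematics
(limbs keep fixed angles), water optics (refraction, caustics, bubbles,
turbidity gradients), motion blur, occlusion by splashes, and
illumination drift. Passing tests on synthetic scenes therefore
demonstrate the correctness of the algorithmic chain and its constants on
scenes whose colours behave as the thresholds assume — not robustness to
every optical condition of a real pool, for which the thresholds would be
re-tuned per camera.

## Validation problem sizes

The test suite validates ground-truth recovery on 20 seeded scenes at
240 × 360 (relative area error ≤ 5 %; in practice the default scenes are
recovered exactly), frequency recovery on a 60 s, 30 Hz sequence
modulated at 0.476 Hz (within one padded bin, 30/(8·1800) ≈ 0.0021 Hz, on
both the ground-truth and the pipeline-estimated series), oracle
equivalence of the Otsu threshold (100 random 16 × 16 rasters against
exhaustive search), blob filtering (50 random 64 × 64 masks against a
brute-force flood-fill labeller) and R² (20 seeded datasets against the
squared Pearson correlation at 10⁻¹² tolerance), and byte-identical
outputs across repeated end-to-end runs.

## Known limitations

* Pixel areas are camera-relative; absolute m² requires a calibration
  the package deliberately leaves to the user (`pixel_scale_mm2`).
* The garment intervals, water interval and water-line row are
  per-camera constants; footage from a different pool, depth or lighting
  requires re-tuning them (the YAML config is the intended mechanism).
* The spectral peak location is limited by the padded bin width; padding
  interpolates but cannot add resolution beyond the 60 s record length.
* Frame ingestion covers PNG/TIFF images and directories of numbered
  frames; video containers should be exported to frames with standard
  tooling first.
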