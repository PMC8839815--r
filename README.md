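# swimarea

Automated per-frame estimation of a swimmer's projected surface area from
pool video, with the downstream time-series analyses used in active-drag
studies of tethered swimming.

## The problem

The hydrodynamic resistive force acting on a swimmer follows the
steady-state quadratic drag model

    F_R = 1/2 · C_R · A · ρ · v²

where `C_R` is a dimensionless resistive-force coefficient, `ρ` the water
density, `v` the swimming speed, and `A` the swimmer's projected (frontal)
surface area. `A` fluctuates within every stroke cycle, so estimating drag
over time requires measuring `A` frame by frame — by hand an impractically
slow task. This package implements an automated colour-segmentation
pipeline that extracts `A` (in pixels) from each frame of a fixed-camera
recording of a tethered swimmer, plus the analyses applied to the
resulting area signal: frontal-vs-lateral linear regression (R²),
single-sided amplitude spectra and dominant stroke-frequency extraction.

It is aimed at swimming-biomechanics researchers and sports scientists who
record tethered swimmers with fixed underwater cameras and need
reproducible area time series.

## The pipeline

For each frame (within a per-camera region of interest):

1. convert RGB → CIELAB (sRGB, D65 white);
2. mark pixels inside the garment intervals
   `25.466 < L < 98.620`, `−46.336 < a < 8.860`, `−31.446 < b < 60.616`
   (swimwear, cap and harness, desaturated by the underwater colour cast)
   and repaint them with the chest colour `(R,G,B) = (27,131,135)`;
3. keep only pixels with normalized lightness `5 < L* < 160` (removes
   water, lane ropes and bright background);
4. zero all rows above the water line (row `i = 97`), removing the
   swimmer's mirrored surface reflection;
5. convert the retained region to grayscale, binarise with Otsu's method,
   drop connected components smaller than 3000 px, fill internal holes,
   and count the remaining pixels.

All printed constants ship in `inst/extdata/frontal.yaml` (the lateral
camera reuses them until customised). A parametric synthetic pool-scene
generator — water, lane ropes, water line, attenuated mirror reflection and
a swimmer with known silhouette — provides exact ground truth for
validation.

## Worked example

```r
library(swimarea)

sc  <- render_scene(scene_spec(seed = 1))     # synthetic scene, known truth
res <- process_frame(sc$frame, frontal_config())
res
#> Frame 0: area 4893 px
sc$truth$area_pixels
#> [1] 4893                                    # exact recovery here

# 10 s sequence whose silhouette pulsates at the stroke frequency 0.476 Hz
run <- segment_synthetic_sequence(scene_spec(seed = 1), 300,
                                  osc_freq_hz = 0.476)
dominant_frequency(compute_spectrum(run$estimate, pad_factor = 8))
#> frequency_hz    magnitude
#>       0.4750     702.3271

# drag at 1.8 m/s with C_R = 0.3 and a 6.23 mm²/px image scale
A <- pixels_to_m2(res$area_pixels, pixel_scale_mm2 = 6.23)  # 0.030483 m²
resistive_force(drag_params(c_r = 0.3, rho = 1000), A, 1.8)
#> [1] 14.81495
```

The recovered peak (0.4750 Hz) sits within one padded DFT bin
(30 / (8 × 300) = 0.0125 Hz) of the true 0.476 Hz modulation; the peak
magnitude is the amplitude, in pixels, of the area oscillation.

A command-line front end with `segment`, `analyze`, `simulate` and
`overlay` subcommands is installed at
`system.file("scripts", "swimarea-cli.R", package = "swimarea")`.

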