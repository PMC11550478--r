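# lumenflow

Quantification of junctional-protein segregation, mobility and flow during
de novo vascular lumen formation.

When two endothelial tip cells meet, they deposit adherens-junction proteins
(VE-cadherin/Cdh5) at the contact site; the initial contact patch then opens
into a junctional ring enclosing a nascent apical compartment that becomes
the luminal surface. Studying this process in fluorescence time-lapse data
raises a recurring set of measurement problems: how colocalized are two
markers as the patch remodels into a ring; how cleanly is junctional
material cleared from the apical compartment; how mobile is the junctional
pool; and in which direction does junctional material flow — outward with
ring expansion, or inward, detaching toward the compartment center?

`lumenflow` implements that measurement toolkit for R, for anyone analysing
two-channel time-lapse stacks of junctional rings (vascular anastomosis,
epithelial de novo lumen formation, or comparable systems):

* **Segmentation** — Otsu automatic thresholding (maximizing between-class
  variance sigma_b^2(t) = w0 w1 (mu0 - mu1)^2 over a 256-bin histogram),
  polygon-ROI rasterization, and partition of a compartment ROI into a
  fixed-width peripheral **boundary band** (0.5 µm by default, carved by
  exact Euclidean distance transform) versus the enclosed **apical**
  interior.
* **Scalar statistics** — Dice–Sørensen coefficient
  `2|A∩B| / (|A| + |B|)` on thresholded masks; boundary-to-apical (B/A)
  intensity ratio (mean band intensity / mean apical intensity);
  coefficient of variation; whole-cell mean normalization; line-intensity
  profiles with bilinear interpolation.
* **Photoconversion pulse-chase** — half-ring recovery curves (ratio of
  mean intensities between converted and unconverted halves per frame),
  linear-interpolated time-to-fraction (e.g. time to 90 % recovery),
  trapezoidal AUC, and pooled two-sample t comparison of AUC groups.
* **PIV** — window-correlation particle image velocimetry (normalized,
  mean-subtracted, zero-padded linear cross-correlation with three-point
  Gaussian sub-pixel refinement and peak-ratio validation), radial/
  tangential decomposition about the compartment center (positive radial =
  outward), 360-s accumulated radial-displacement heat maps, binned mean
  radial velocity series, and 2× arrow maps.
* **Synthetic scenes** — a generator producing two-channel stacks with a
  junctional ring, advected punctate particles (outward expansion, inward
  bursts, rotation, translation), photoconversion with memoryless turnover,
  erf-integrated Gaussian PSF rendering and Poisson + Gaussian noise —
  together with exact ground truth, so every statistic above is validated
  by parameter recovery rather than by eye.

Everything user-facing takes or returns tidy tibbles and composes with the
pipe; result objects have `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Generate a synthetic mutant-like scene — a junctional ring whose particles
undergo two scheduled episodes of inward-directed detachment — and measure
the flow the way a real stack would be measured:

```r
library(lumenflow)

scene <- generate_scene(scene_preset("rasip1_like"))
scene$stack
#> <image_stack> 21 x 2 x 256 x 256 (T x C x Y x X)
#>   pixel size: 0.1 um/px; frame interval: 36 s
#>   channels: green, magenta

series <- piv_series(scene$stack, channel = 1,
                     center = scene$truth$center_px,
                     min_mean_intensity = 0.5)
binned <- mean_radial_series(series, interval_s = 120)
binned
#>   t_start_s t_mid_s mean_radial_um_s n_valid
#> 1         0      60          0.00173     235
#> 2       120     180         -0.00393     127
#> 3       240     300          0.00166     179
#> 4       360     420          0.00180     237
#> 5       480     540         -0.00442     104
#> 6       600     660          0.00151     117

detect_inward_episodes(binned, threshold_um_s = 0.001)
#>   t_start_s t_mid_s mean_radial_um_s n_valid
#> 1       120     180         -0.00393     127
#> 2       480     540         -0.00442     104
```

The two negative bins are the two scheduled inward-burst episodes of the
preset (and only those): sustained outward ring expansion reads as positive
mean radial velocity, pulsatile detachment toward the compartment center as
negative bins. `plot_radial_series(binned)`, `plot_radial_heatmap(
heatmap_accumulate(series))` and `autoplot(series[series$pair == 1, ])`
render the corresponding bar series, diverging-colour heat map and arrow
map.

Scalar statistics on a wild-type-like ring frame:

```r
wt   <- generate_scene(scene_preset("wildtype_ring"))
img  <- stack_frame(wt$stack, frame = 1, channel = "green")
ring <- wt$truth$ring_roi

part <- partition_compartment(ring, c(256, 256),
                              pixel_size_um = 0.1, band_width_um = 0.5)
boundary_apical_ratio(img, part)
#> [1] 18.18521
```

A B/A ratio of ~18 says the junctional marker is almost entirely confined
to the 0.5-µm boundary band — a cleanly cleared apical compartment (the
preset places 85 % of its particles in the band; the uncovered apical area
pushes the ratio of means well above the intensity split).

Photoconversion recovery on the conversion preset (exchange rate
`log(10)/200` per second, so 90 % recovery is expected at 200 s):

```r
conv <- generate_scene(scene_preset("conversion_test"))
k    <- conv$truth$conversion_frame
unconverted <- roi_polygon(c(127.5, 255.5, 255.5, 127.5),
                           c(-0.5, -0.5, 255.5, 255.5))
curve <- halfring_recovery(conv$stack, conv$truth$conversion_roi,
                           unconverted, channel = 1, frames = k:33)
glance(curve)
#> # A tibble: 1 × 5
#>   n_frames t_reach_s fraction   auc final_ratio
#>      <int>     <dbl>    <dbl> <dbl>       <dbl>
#> 1       31      201.      0.9  512.       0.998
```

The measured time to 90 % recovery (201 s) recovers the simulated turnover
half-life; a zero-exchange control never recovers.

## Config-driven runs

Whole analyses are reproducible bundles driven by one YAML file
(`run_pipeline()` in R, or the thin CLI at `inst/cli/lumenflow.R` with
verbs `generate`, `quantify`, `piv`, `recovery`, `run-all`, `validate`).
Each bundle contains tidy CSVs, PNG heat maps, a log of every parameter
used, a verbatim config echo and a checksum manifest; identical configs
produce byte-identical bundles.

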