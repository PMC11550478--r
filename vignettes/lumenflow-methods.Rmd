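---
title: "Methods: quantifying junctional segregation, mobility and flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying junctional segregation, mobility and flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lumenflow` packages the image-quantification procedures needed to follow a
junctional contact patch as it opens into a ring enclosing a nascent apical
compartment: colocalization of marker pairs, clearance of junctional
material from the apical interior, turnover of the junctional pool, and the
direction of junctional flow. This vignette explains what each procedure
computes, the assumptions behind it, the parameters that matter, and the
numerical choices made where the design was genuinely open. It states no
measured result: every number the package claims to produce is computed by
the test suite or by `scripts/acceptance.R` at run time.

## Conventions

All modules share one coordinate convention: pixel coordinates are 0-based
with pixel centers at integer `(x, y)`; `x` indexes columns, `y` rows, `y`
increasing downward (raster convention). Image stacks are `T × C × Y × X`
arrays (a `Z` axis, when present, sits between `C` and `Y` until flattened)
calibrated by an isotropic in-plane pixel size (µm) and a frame interval
(s). Whether quantification runs on maximum or sum Z-projections changes
results, so the projection is always an explicit argument — a required
config field in pipeline runs, never a hidden default.

## Segmentation

**Otsu threshold.** `otsu_threshold()` maximizes the between-class variance
`w0·w1·(µ0 − µ1)²` over the interior edges of a 256-bin histogram spanning
the `[min, max]` of the analysed region (the 8-bit convention of
`graythresh`-style implementations; the bin count is an argument). Class
statistics come from per-bin sums of the actual pixel values, so the result
is exactly the argmax over all candidate edges; ties resolve to the lowest
threshold, and a constant region raises an error rather than returning an
arbitrary value. Thresholding is meant to be applied *locally* — to the
region around the structure, per channel — which is why the function takes
any vector or sub-image rather than insisting on whole frames.

**ROI rasterization.** ROIs are simple polygons (plain-text `x y` vertex
files standing in for hand-drawn freehand selections). A pixel belongs to a
polygon iff its center lies inside under the even-odd rule, implemented as
a strict upward-crossing test. The rule is half-open: centers on the
left/bottom boundary of an axis-aligned rectangle are inside, right/top
outside, so integer-cornered rectangles rasterize to exactly
`(x1−x0)·(y1−y0)` pixels and abutting polygons tile without double counting.
Any fixed deterministic tie-break would do; this one is stated so results
are portable.

**Boundary band vs apical interior.** The junctional boundary band is the
set of compartment pixels within a fixed metric width (default 0.5 µm) of
the ROI perimeter; everything deeper is apical. Because the width is
metric, not a pixel count, the band is carved with the exact Euclidean
distance transform of the rasterized ROI rather than by structuring-element
erosion — sub-pixel widths and anisotropic pixel sizes then behave
sensibly. One numerical subtlety: the distance transform measures distance
to the nearest *outside pixel center*, which exceeds the distance to the
polygon perimeter by half a pixel on average, so the band threshold is
`band_width/pixel_size + 0.5` pixels. With that correction a 100 × 100 px
square at 0.1 µm/px with a 0.5 µm band leaves exactly the inner 90 × 90
apical core, and a disk's band-area fraction matches the annulus closed
form `1 − (1 − w/R)²` to within rasterization error. A band wider than the
ROI inradius would leave no apical pixels and is an error.

## Scalar statistics

* **Dice–Sørensen**: `2|A∩B|/(|A|+|B|)` on thresholded masks; 1 means full
  colocalization (contact patch), 0 full segregation (mature ring). Two
  empty masks are an error (0/0), not a silent 0.
* **B/A ratio**: mean band intensity / mean apical intensity. Ratios of
  means make the statistic invariant to multiplicative gain but *not* to
  additive offsets — the package applies no background subtraction anywhere
  (none is part of the measurement definition); any subtraction must be an
  explicit upstream step, and the tests include an offset-sensitivity
  check.
* **CV**: sample standard deviation over mean within a mask; the
  heterogeneity readout for apical cargo (smooth vs clustered).
* **Whole-cell normalization** divides by the mean over a cell mask so
  regional means read as fold-of-cell-mean; B/A is invariant under it.
* **Line profiles** sample along a polyline at 1-px arclength steps with
  bilinear interpolation, averaging over an odd perpendicular width.

## Photoconversion recovery

Half-ring pulse-chase experiments are quantified as per-frame ratios of
*spatial means* between the converted and unconverted half-ring ROIs —
means, not sums, because hand-drawn halves differ in area. The recovery
curve for the unconverted-colour channel rises from ~0 toward 1 as new
protein incorporates into the converted half; the per-frame ratio form
makes the reference the *same-frame* unconverted half (the alternative,
normalizing to a fixed final frame, is a caller-side one-liner on the tidy
curve). `time_to_fraction()` reports the first crossing of a level
(default 0.9) with linear interpolation between frames — the data are
sampled at tens of seconds, so sub-frame precision beyond linear
interpolation is not warranted; a curve that never crosses returns `NA` (a
legitimate outcome for a zero-turnover control), not an error. Curves are
summarised by trapezoidal AUC from the first post-conversion frame
(conversion time is explicit input, never inferred), and groups of AUCs are
compared with the classical pooled-variance two-sided unpaired t test
(`stats::t.test(var.equal = TRUE)`; Welch's form behind a flag).

## Particle image velocimetry

`piv_pair()` correlates square interrogation windows (default 32 px, 16 px
overlap) between consecutive frames. Windows are mean-subtracted and
normalized, then cross-correlated by zero-padded FFT, and the correlation
plane is divided by the per-lag overlap area. That last step matters: the
raw linear correlation of a `w × w` window carries a triangular envelope
`(w−|k|)/w` per axis that systematically drags peaks toward zero lag — for
smooth particles the bias reaches tens of percent of the displacement —
and dividing by the overlap area removes it exactly for content within the
window. The integer peak is refined per axis by a three-point Gaussian fit
`δ = (ln c₋ − ln c₊) / (2 ln c₋ − 4 ln c₀ + 2 ln c₊)` (particle images are
near-Gaussian, so their correlation peak is too), falling back to a
parabolic fit when a neighbour is non-positive.

A window is *invalid* — reported as `NA`, never a fabricated vector — when
its variance is ~0, its mean intensity falls below a floor (avoids
noise-locking on empty regions), its first-to-second peak ratio falls below
1.2, or the displacement leaves the `±window/2` search bound. The second
peak is taken outside the 5 × 5 neighbourhood of the first: with realistic
particle widths (σ ≈ 1.5–2 px) the correlation peak has shoulders two
lags wide, and a 3 × 3 exclusion would misread the shoulder as a competing
peak and reject well-matched windows. Defaults (window 32, overlap 16,
`gauss3`, peak ratio 1.2) are community norms and are all exposed in the
config. The wording "auto-correlation" sometimes attached to this family of
scripts is implemented here as frame-pair *cross*-correlation: single-frame
autocorrelation is symmetric and cannot yield a displacement sign, hence no
directed arrow maps.

**Radial decomposition.** About the compartment center (by convention the
centroid of the apical mask), each valid vector splits into a signed radial
component (positive = outward, away from the center — ring expansion) and a
tangential component; `radial² + tangential²` reconstructs the speed to
numerical precision. Per-pair fields are aggregated two ways, because both
are useful and they answer slightly different questions: the summed radial
*displacement* per grid position over a span (e.g. ten 36-s pairs → 360 s),
rendered as a diverging heat map centred at zero, and the *mean radial
velocity* over non-overlapping time bins (default 120 s). Invalid windows
contribute zero to sums and are counted, so the average form divides by the
number of valid contributions only. Arrow maps draw vectors at twice their
true length for visibility (display only; data unchanged).

## The synthetic generator

`generate_scene()` renders what the quantification stages assume the
microscope produces: a two-channel scene with a bright elliptical
junctional band and interior signal, built from point particles convolved
with an isotropic Gaussian PSF proxy. Rendering integrates the Gaussian
over each pixel (erf-based), so sub-pixel positions are faithfully encoded
— a prerequisite for testing sub-pixel PIV. Noise is Poisson
(variance = gain × mean) plus additive Gaussian. Flow fields are analytic
(static, uniform translation, radial outward, scheduled inward bursts in
angular sectors, rigid rotation); particles advect by forward Euler per
frame, and the exact per-pair displacement function ships in the returned
ground truth, together with trajectories, masks and the parameter echo.
Scenes are bit-reproducible: one RNG stream per scene seed, with per-frame
noise substreams derived deterministically from it.

Photoconversion switches the label of every particle inside the conversion
ROI at the pulse, then lets each converted particle revert independently
with probability `1 − exp(−r·Δt)` per frame — memoryless turnover by new
unconverted protein — so the expected recovered fraction follows
`1 − exp(−r·(t − t_c))` and the measured time-to-90 % inverts to
`ln(10)/r`. Conversion scenes place equal particle counts in the two
halves (stratified placement) so the half-to-half ratio has asymptote 1 by
construction rather than by luck of sampling.

**Study conditions.** The presets fix the conditions under which the
package validates itself; they were chosen once, against the generator's
own ground truth, and the test suite was then frozen:

* Defaults: 256 × 256 px at 0.1 µm/px (high-zoom confocal of a 5–20 µm
  compartment), 36-s frame interval, PSF σ = 0.15 µm (typical lateral
  confocal PSF), ring radius 8 µm with a 0.5 µm placement band.
* `wildtype_ring`: sustained 0.005 µm/s outward expansion, 21 frames
  (20 pairs = 720 s → six 2-minute bins), 700 particles/channel, 85 % in
  the band, Poisson gain 1 + Gaussian σ 2.
* `rasip1_like`: 0.002 µm/s outward baseline with two 3-pair inward
  episodes at 0.02 µm/s (7.2 px/pair, safely inside the ±16 px search
  bound), each confined to a pair of opposing 90° sectors, the second
  episode in the orthogonal sectors so it acts on an undepleted stretch of
  band; 1000 particles for reliable correlation texture. Episodes are
  declared at bins whose mean radial velocity drops below −0.001 µm/s.
* `translation_test` / `subpixel_test`: 1500 particles uniformly over the
  frame — a content-rich field, so interior windows carry enough texture
  for the integer peak to be exact and the sub-pixel fit unbiased;
  noiseless by design (they isolate the correlator, not the noise model).
* `rotation_test`: rigid rotation sampled on a uniform particle field;
  with ring-only texture the intensity centroid of a window sits off the
  window center and a small fraction of tangential speed leaks into the
  radial readout, so the zero-radial oracle uses full-field texture.
* `conversion_test`: static ring, 4000 particles all in the band,
  conversion of the left half at t = 40 s with exchange rate
  `ln(10)/200 s⁻¹` (so 90 % recovery is expected at 200 s), 20-s frames.
* `ba_test`: single-frame disk whose band width is computed at run time as
  the median depth of the distance transform — the width at which the
  *discrete* band and interior masks have equal pixel counts, which is the
  stated condition of the recovery check (the continuous closed form
  `w = R(1 − 1/√2)` leaves a few-percent count imbalance after
  rasterization). Small PSF (σ = 0.05 µm) keeps cross-boundary leakage of
  particle intensity small; the residual leakage is the dominant remaining
  bias in B/A recovery and grows with the allocation fraction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optical sectioning and axial blur (scenes are
2-D; a measured 3-D PSF is out of scope), scattering and depth-dependent
attenuation, bleaching, stage drift, sub-cellular structure beyond a
ring-plus-puncta geometry, biological heterogeneity between cells, and any
mechanics (flows are kinematic prescriptions, not actomyosin models).
Parameter-recovery results certify the *estimators*, not the biology.

## Pipeline and reproducibility

`run_pipeline()` drives everything from one YAML config: validation reports
every violated field before any computation; outputs are tidy CSVs (one
statistic per row with `statistic, value, cell_id, condition,
timepoint_s`), PNG heat maps, a log recording every parameter actually
used (including defaults), a verbatim config echo, and a manifest with one
checksum per file (SHA-256 when the `digest` package is present, MD5
otherwise, with the algorithm named in the manifest). Runs are
deterministic given config + seed; a non-empty output directory is refused
unless `overwrite: true`. The CLI (`inst/cli/lumenflow.R`) is a thin
wrapper with exit codes 0 (success), 2 (validation failure), 1 (runtime
failure).

Problem sizes throughout the tests and the acceptance script — 256² scenes,
≤ 21 frames, ≤ 20 seeds per condition — were chosen as the smallest sizes
at which the statistical checks are stable, so the whole validation runs on
a laptop in minutes.

## Known limitations

* Single-pass PIV: no iterative window deformation or multi-resolution
  passes; displacements should stay within about a quarter window for
  reliable peaks.
* The correlation-envelope correction amplifies noise at extreme lags;
  the search bound (±window/2) keeps this region out of play.
* TIFF float data round-trips through 32-bit storage (integer data is
  bit-exact); calibration travels in a JSON sidecar or OME-XML, and plain
  multi-page TIFFs without either require an explicit axis specification —
  guessing axis order silently is a refusal, not a feature gap.
* Per-embryo nesting of cells is out of scope: statistics carry `cell_id`
  and `condition` so mixed-effects modelling can happen downstream.
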