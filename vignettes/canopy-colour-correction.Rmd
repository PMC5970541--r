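---
title: "Chart-anchored canopy colour correction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chart-anchored canopy colour correction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopycolor)
```

## The problem

Mean canopy colour is a cheap, automatically measurable phenotype: greenness
tracks chlorophyll and nitrogen status, and the red/green balance tracks
senescence. But a plot imaged on a bright day and again under cloud produces
different raw pixel values for the same plant. Without a correction, the
colour trait confounds biology with weather.

The remedy implemented here is to keep a 24-tile colour checker in every
frame. The checker's tiles have known reference colours, so the observed
tile values in each image expose exactly how that image's illumination
distorted colour — and a model fitted on the 24 (observed, reference) pairs
can then undo the distortion for the plant pixels.

## The correction model

Let $(L_i, a_i, b_i)$ be the observed CIELAB colour of tile $i$ and
$\hat L_i$ its reference lightness. The model for each output channel is a
polynomial in all three observed channels and their squares, with an
intercept and no cross terms; for the lightness channel:

$$
\hat L_i = \alpha_0 + \alpha_1 L_i + \alpha_2 a_i + \alpha_3 b_i
         + \alpha_4 L_i^2 + \alpha_5 a_i^2 + \alpha_6 b_i^2 ,
$$

with analogous coefficient vectors $\beta$ and $\gamma$ for $a^*$ and
$b^*$. All three channels share one design matrix, and each coefficient
vector is obtained by ordinary least squares over the 24 tiles. A linear
baseline (the first four terms) is retained for comparison, since simpler
chart pipelines use a linear scaling.

Fitting happens in CIELAB (device-independent, and the space in which this
family of corrections is known to work well); corrected values are converted
back to 8-bit sRGB for reporting. Two properties follow from the model
design and are enforced by tests:

* the identity map is inside the family (because of the intercept and
  linear terms), so on its own fitting tiles a fitted model can never be
  worse than not correcting;
* the linear model is nested in the quadratic one, so with a shared design
  the quadratic fit's $R^2$ is never below the linear fit's.

Fit quality is summarised two ways. The **chart error** is the mean
Euclidean distance between paired sRGB triplets,
$E = \frac{1}{24}\sum_i \|(\hat R_i,\hat G_i,\hat B_i) - (R_i,G_i,B_i)\|_2$,
computed before and after correction. The **degree comparison** reports
per-RGB-channel $R^2$ for both polynomial degrees, fitted per channel
directly on the sRGB tile values. The latter choice is deliberate: $R^2$
nesting only holds in the space where the two degrees are fitted on a
common design, so converting Lab-fitted values into RGB first would allow
the quadratic degree to appear (slightly) worse than the linear one — an
artefact, not a property of the data.

### Numerical notes

The squared Lab terms span $[0, 10^4]$ while the linear terms span tens, so
design columns are centred and scaled internally before a QR solve and the
coefficients mapped back; the contract (coefficients for the raw
polynomial) is unchanged. A rank-deficient tile set (e.g. all tiles
identical) is a hard error naming the deficiency. Explicit normal equations
are used only as an independent oracle in the tests, where the two routes
agree to $10^{-11}$.

## Chart handling

Detection is normalized cross-correlation of a grayscale rendering of the
canonical chart against the image, over a small scale pyramid (±20%) and
the four quarter-turn rotations. Grayscale matching cannot distinguish a
half-turn, so after localisation both tile orderings are scored by
correlating extracted tile lightness against the template's pattern — the
achromatic bottom row makes this unambiguous. Tile colours are read as a
10%-trimmed mean over the central 50% of each tile, which is robust to edge
bleed and specular outliers; a tile with under 9 sampled pixels is an
error.

The shipped reference table is the commonly published nominal CIELAB value
set of the classic 24-patch checker (pre-2014 edition); any user table with
the same layout can be substituted.

### Occlusion screening

A chart partly in shadow poisons the fit, but a *global* illumination
change is exactly what the model exists to absorb, so occlusion screening
must not confuse the two. A provisional linear model is fitted first; tiles
whose residual exceeds `tol` (default 12 Lab units) are flagged, and the
chart is declared occluded when more than `max_bad` tiles are flagged. The
default `max_bad` is 12 — half the chart — calibrated on the synthetic
distortion family: a clean chart under a strong nonlinear global distortion
leaves up to ~11 tiles above tolerance after a linear fit, while a
half-shadowed chart leaves 17 or more. Both knobs are exposed because real
deployments will want to recalibrate them against their own imagery.

## ROI and segmentation

The region of interest is the strip between the vehicle's two rails, which
keeps out-of-plot weeds and the chart itself out of canopy statistics.
Rails are found by a Hough-style vote: bright pixels (Otsu threshold on the
grayscale image) vote for near-vertical lines parameterized by tilt
(±15°) and x-offset; the two strongest peaks at least 20% of the image
width apart win, and each offset is refined to the local vote centroid. A
peak must be both near full image height and at least three times the
accumulator median — the latter rejects images whose bright pixels are
diffuse texture rather than rails. Pixels strictly between the lines form
the mask (boundary pixels excluded on both sides), applied as an
elementwise (Hadamard) product.

Plant/background segmentation is an SVM over CIELUV chromaticity $(u, v)$,
a plane in which green canopy separates cleanly from soil, rails and chart
tiles regardless of lightness. Training compresses each labelled image to
k-means cluster centres (k = 20, clustered in Luv on a 20,000-pixel
subsample with seeded multi-start initialisation); each centre takes the
majority ground-truth label of its member pixels. Because plant clusters
are a small minority of the centres, the SVM uses inverse class weights —
without them a cost-1 margin collapses onto the background class. The
kernel is linear by default ("best separating hyperplane"); a radial
kernel and fuller feature spaces (Luv, Lab) are available by configuration.
Pooled centres are sorted canonically before fitting, so training is
insensitive to image order.

## Traits and NDVI

Mean canopy colour is the per-channel arithmetic mean over plant pixels
(median available), computed raw and after applying the image's correction
model to the plant pixels. Across sessions, per-plot sample standard
deviations of each channel summarise stability; on the synthetic benchmark
with constant true canopy colour, every plot's corrected deviation must
fall below its raw one.

NDVI, $(\mathrm{NIR}-R)/(\mathrm{NIR}+R)$, is insensitive to overall
illumination because common scaling cancels in the ratio — which makes it a
natural external check on colour correction: a model mapping canopy colour
to NDVI should transfer across sessions only if the colour has been made
illumination-independent. The prediction model mirrors the correction
design — intercept, features, squared features, no cross terms — over mean
canopy colour expressed in any subset of RGB, HSV, Lab and Luv. Held-out
evaluation trains on all sessions but the last and tests on the last. The
solver here is a truncated SVD (relative tolerance $10^{-3}$ on the
standardized design) rather than plain QR: the combined feature set is
structurally collinear (Lab and Luv share the same lightness), and
near-degenerate directions fitted from tightly clustered corrected colours
explode on held-out data if kept.

## The synthetic scene generator

Scenes emulate the imaging geometry: textured soil, two bright
near-vertical rails bounding the ROI, a chart in the margin outside the
rails, elliptical canopy patches of known true colour, and additive sensor
noise (default σ = 2 sRGB units). Illumination distortions are per-channel
$v' = \mathrm{clip}(g_c\,(v/255)^{\gamma_c}\cdot 255 + o_c)$ with
$g_c \in [0.6, 1.4]$, $o_c \in [-15, 15]$, $\gamma_c \in [0.8, 1.25]$ drawn
uniformly — gamma makes the distortion curved in the working space, the
regime where the quadratic model is needed — and chart and canopy are
distorted identically (the shared-illuminant assumption the whole method
rests on). Shadows for occlusion tests darken a rectangle over the chart
only. Everything is seed-deterministic and every scene carries its ground
truth (tile centres, ROI and plant masks, true canopy colour).

Two deliberate limitations matter when reading test results. First, the
distortion family acts per sRGB channel, which the no-cross-term quadratic
in Lab cannot represent exactly; together with clipping of the brightest
tiles this leaves a residual chart error of roughly 5–7 sRGB units (from
~50 before correction). Passing benchmarks therefore demonstrate a large
error *reduction* (typically 7×), not error elimination; exact recovery is
verified separately under distortions inside the model family. Second, the
generator's canopies are uniform-colour ellipses — real canopies have
within-plot colour structure, specular leaves and soil shadowing that the
synthetic benchmark does not emulate, so the 99%+ synthetic segmentation
accuracy is an upper bound, not a field expectation.

For large benchmark designs a record-level path
(`simulate_color_records()`) pushes the true canopy colour and the 24 chart
tiles through the same distortion plus noise, fits the correction model on
the tiles exactly as the image pipeline would, and corrects a sample of
canopy pixels — exercising the fit/correct machinery per record without
rasterising thousands of scenes. NDVI measurements are generated from the
*true* canopy colour through a fixed quadratic link plus Gaussian noise
(σ = 0.02), chosen to span a realistic seasonal NDVI range (~0.05–0.45,
declining with senescence); tying NDVI to the truth rather than the
observation is what makes the corrected-versus-raw comparison meaningful.

## Benchmark sizes

The standard problem sizes used throughout the test-suite benchmarks are:
60 distorted scenes (240×320 px) for chart-error reduction and the degree
comparison; 20 plots × 16 sessions at record level for stability; 2
training + 20 test scenes for segmentation; and 10 seeds × 60 plots × 5
sessions for the NDVI comparison across all five feature-space choices.
`scripts/acceptance.R` re-runs the same designs end to end from a single
seed.

## Worked example

```{r example, eval = FALSE}
ref <- chart_reference()
scene <- render_scene(scene_spec(seed = 5))
img <- apply_illumination(scene$image, random_illumination())

grid <- detect_chart(img)
obs <- extract_tile_values(img, grid)
check_occlusion(obs, ref)              # FALSE: global change, not occlusion
fit <- fit_correction_model(obs, ref)
fit$diagnostics$chart_error_before     # ~40-60 sRGB units
fit$diagnostics$chart_error_after      # ~5-10

roi <- make_roi_mask(detect_rails(img), dim(img))
mean_canopy_color(img, scene$truth$plant_mask, model = fit)
```

## Known limitations

* The polynomial family is fixed (no cross terms, degree ≤ 2); distortions
  outside it are reduced, not removed.
* Chart detection assumes quarter-turn orientations and ±20% scale; oblique
  charts are out of scope.
* The occlusion rule is threshold-based and calibrated on synthetic
  shadows; field deployments should recalibrate `tol`/`max_bad`.
* Rail detection expects two bright, near-vertical, near-full-height
  structures; it is not a general line detector.
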