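---
title: "Measuring zooplankton body length from dark-field video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring zooplankton body length from dark-field video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoobooth)
```

## The measurement problem

A single free-swimming zooplankter (a *Daphnia*, a copepod, ...) is filmed
for about 30 s in a small cuvette, lit so that the animal appears bright on
a dark background. Each video frame yields at most one candidate length
measurement, but the animal rotates freely in three dimensions, so most
projected lengths *undershoot* the true body length: only when the long
axis lies in the image plane does the silhouette reach full length. The
per-video distribution of projected lengths is therefore asymmetric around
the truth, and neither the mean nor the median is a good estimator. The
package's central statistic is instead a **calibrated percentile** of that
distribution.

For a prolate spheroid with semi-axes $a \ge b$ whose long axis makes angle
$\theta$ with the image plane, the orthographic silhouette is an ellipse
with major axis

$$L(\theta) = 2\sqrt{a^2\cos^2\theta + b^2\sin^2\theta} \;\le\; 2a,$$

with equality exactly at $\theta = 0$. This projection law is what the
synthetic generator implements and what the pipeline's property tests
verify; it is the mechanism that makes a high percentile (not the maximum
of a noisy distribution, and not its centre) the right summary.

## The per-frame pipeline

Each frame passes through a fixed sequence:

1. **Crop** to the inner area of the cuvette (the crop rectangle is defined
   in raw-frame coordinates).
2. **Undistort** with the stored camera model: a 5-coefficient
   Brown-Conrady model (radial $k_1,k_2,k_3$, tangential $p_1,p_2$) read
   from the four plain-text files a one-off checkerboard calibration
   leaves in a `lenscalibration/` folder. Undistortion is inverse-mapped
   and bilinearly interpolated; pixels that map outside the source are set
   to 0, which is safe on a dark-field background. The remap is
   precomputed once per video.
3. **Grayscale** (luminance weights 0.299/0.587/0.114 for colour input).
4. **Sharpness**: the population variance of the 3x3 Laplacian response,
   a standard focus measure. Frames below the threshold (default 1.8) are
   later rejected by the species filter. The statistic is evaluated on the
   whole cropped frame by default; a bounding-box variant is available via
   `run_config(box_sharpness = TRUE)` for scenes where debris outside the
   animal dominates frame-level focus.
5. **Background subtraction** with a sample-based K-nearest-neighbour
   model: each pixel keeps 10 intensity samples; a pixel is background
   when at least 3 samples lie within a squared-intensity radius of 400
   (20 grey levels) of the current value, ties counting as matches.
   Samples refresh stochastically at rate 1/500 per pixel per frame from
   the model's own seeded RNG stream, so a stationary object is eventually
   absorbed and all results are reproducible.
6. **Erosion then dilation** (3x3 rectangle, 3 iterations each by
   default): erosion removes drifting particles and thin appendages (the
   *Daphnia* spine and antennae would otherwise inflate the length), and
   the matching dilation restores the main body. Outside-image pixels
   count as background for both operators, and $k$ iterations of a
   radius-$r$ rectangle are applied as one radius-$kr$ window via an
   integral image, which is exactly equivalent and much faster.
7. **Contours**: external boundaries of 8-connected components
   (Moore-neighbour tracing), in deterministic top-left scan order.
8. **Largest object** by enclosed (shoelace) contour area, ties to scan
   order.
9. **Ellipse fit**: direct least-squares conic fit (Halir-Flusser
   formulation of Fitzgibbon's method) to *subpixel* boundary points -
   the midpoints between boundary pixel centres and their 4-adjacent
   background neighbours, i.e. the 0.5-level crossings of the binary
   mask. Fitting pixel centres instead would shrink every axis by about
   half a pixel per side; with the subpixel boundary, rasterized ellipses
   with axes down to ~30 px are recovered within 2 %. Below ~20 px
   diameter, quantization limits any contour-based estimate to roughly
   0.3 px.
10. **Species filter**, five criteria in fixed order so the reject reason
    is deterministic: (i) contour area within the species window, (ii)
    length-to-width ratio of the fitted ellipse, (iii) mean brightness
    inside the object (measured on the undistorted grayscale frame before
    background subtraction - the mask only locates the object), (iv)
    sharpness, (v) distance from the ellipse centre to the nearest crop
    edge (>= 10 px by default). The shipped species table covers six
    taxa; the *Daphnia* row (area 1500-4000 px, ratio 1.2-1.7,
    brightness >= 30, percentile 93) is the default profile.
11. **Millimetre conversion** with the fixed instrument scale factor.

Accepted frames produce rows of `*.detailedsizedata.csv`; the calibrated
percentile of each video's accepted lengths, plus the supporting frame
count, becomes the row in `*.sizedata.csv`.

### Two-pass background priming

A streaming background subtractor must warm up on the first frames, which
necessarily contain the animal; at the model's slow refresh rate the
animal's starting silhouette would linger in the sample store as a ghost
for hundreds of frames. Because this package processes recorded clips (not
a live stream), `process_video()` primes the model from the whole clip
before segmenting: the per-pixel **minimum** over up to 15 frames spread
evenly across the video. On a dark-field scene the animal and all debris
are strictly brighter than the background, so the temporal minimum is a
robust estimate of the true background wherever the animal moves at all.
Streaming behaviour (warmup, stochastic refresh) remains available through
`background_model()`/`bg_subtract()` and is what the absorption and
static-scene tests exercise. Priming can be disabled with
`run_config(prime_background = FALSE)`.

## Percentile calibration

For each individual in a calibration set we have a manual length
$m_i$ and the video's accepted lengths $X_i$. For every integer percentile
$p \in [50, 100]$ the objective is

$$J(p) = \sum_i \left| m_i - Q_p(X_i) \right|,$$

and the optimal percentile is the exhaustive-scan argmin, ties broken
towards the lower percentile so results are deterministic. $Q_p$ uses
linear interpolation between order statistics (the classical type-7
definition; a nearest-rank mode is available for sensitivity checks).
Integer percentiles suffice: with a few hundred frames per video a finer
grid changes nothing. The calibration is per-taxon and should be repeated
whenever the optical geometry changes (container volume, lens, working
distance). The shipped table carries the species defaults; for *Daphnia*
that is the 93rd percentile.

## What the synthetic generator emulates

`scene_config()`/`render_video()` draw a bright prolate spheroid on a dark
background. Per frame: the long-axis direction performs a seeded random
walk on the unit sphere; the centre swims with a directed speed (default
6 px/frame) whose heading random-walks and bounces off the crop walls,
plus a small jitter; the silhouette ellipse follows the projection law
above; an optional thin spine extends from the posterior tip; drifting
bright particles, Gaussian blur (default sd 0.8 px), Gaussian pixel noise
(sd 2 levels) and an optional forward lens distortion complete the frame.
Every frame's tilt, projected axes, centre and true length are recorded in
a ground-truth table, and everything is bit-reproducible under the
configured seed.

Directed swimming is not behavioural decoration: the adaptive background
model can only learn the true background at pixels the animal vacates, so
scenes must give the animal a swimming range larger than its own body.
`make_calibration_cohort()` therefore sizes each scene to its animal
(margin plus a swimming range of 1.2-1.6 body lengths per axis), the same
way the instrument
pairs macro and half-micro cuvettes with adult and juvenile animals.

Deliberate simplifications, and what they mean for the tests: projection
is orthographic (the cuvette is shallow relative to the optical path, so
perspective scaling is ignored); defocus is a global Gaussian blur, not a
depth-dependent model; the body is a true spheroid with uniform
brightness, so segmentation faces none of the transparency gradients that
make real *Diaphanosoma* heads disappear. Passing tests therefore
demonstrate that the measurement chain and the percentile statistic are
correct and well-calibrated on geometrically faithful scenes - not that
the filter thresholds are optimal for any particular real species.

## Numerical choices and degenerate inputs

* Quantile definition: type-7 linear interpolation; $p = 100$ is the
  maximum. Empty distributions produce a flagged summary row with a
  missing length rather than an error.
* Ellipse fits need >= 5 boundary points and a genuinely elliptic
  solution; degenerate contours (collinear, too small) reject the frame
  and are counted, not propagated.
* Exact ties at the background-match radius count as background; ties in
  the largest-object choice and in the percentile argmin resolve to scan
  order and to the lower percentile respectively - every tie-break is
  deterministic.
* The background model, the renderer and the cohort builder each own a
  seeded RNG stream and restore the caller's RNG state, so batch runs are
  reproducible end to end.
* Measurement-accepted frames below `min_support` (default 10, roughly
  3 s of usable footage at 26 fps) flag the summary row as low-support
  but still report it.

## Problem sizes used by the shipped checks

The packaged acceptance checks run entirely on synthetic scenes:
calibration on 8 individuals (200 frames each) and assessment on 20
individuals (300 frames each), true lengths 0.8-4.0 mm at 0.02 mm/px,
scene frames sized to the animal as described above; percentile-oracle
comparisons on 1000
random multisets; morphology against the exhaustive set definition on 500
random masks up to 12x12. These sizes were chosen so the whole suite runs
comfortably on a laptop-class single core while leaving the statistics
stable across seeds.

## Known limitations

* No multi-animal tracking: one individual per clip is a design
  assumption, as on the instrument.
* The species filter windows are pass-through configuration; only the
  *Daphnia*-style geometry is exercised by the synthetic assessment.
* Compressed video (h264/MP4) is not decoded directly; clips are
  converted once to lossless multi-page TIFF stacks or PNG frame
  directories (e.g. with ffmpeg) and analysed from there.
* Brightness criterion and dark-field priming assume bright-on-dark
  scenes; bright-field footage would need an inverted background
  estimator.
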