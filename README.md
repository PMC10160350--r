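# zoobooth

Video-based body-length measurement of single free-swimming zooplankton.

## The problem

Repeated size measurements of live individual zooplankton (*Daphnia*,
copepods, other microcrustaceans) are valuable for growth and life-history
studies, but trapping an animal under a microscope for each measurement
risks damage and stress. An alternative is to film the animal for ~30 s in
a small cuvette under dark-field illumination and measure it from the
video. The catch: the animal rotates freely in three dimensions, so the
projected length in most frames *undershoots* the true body length. For a
prolate body with semi-axes a ≥ b tilted by θ out of the image plane, the
silhouette's major axis is

    L(θ) = 2·√(a²·cos²θ + b²·sin²θ)  ≤  2a,

with equality only when the animal swims parallel to the camera. The
per-video distribution of lengths is therefore skewed below the truth, and
neither mean nor median recovers it.

This package implements the full measurement chain and the statistic that
solves the projection problem:

* per-frame processing — cuvette crop, Brown–Conrady lens undistortion
  from a stored calibration, Laplacian-variance sharpness, adaptive
  K-nearest-neighbour background subtraction, binary erosion/dilation,
  contour finding, largest-object selection, direct least-squares ellipse
  fit;
* species-specific filtering — area, length/width ratio, brightness,
  sharpness and edge-distance windows (six taxa shipped, *Daphnia* as
  default);
* the **calibrated percentile**: for calibration individuals with manual
  lengths mᵢ and video length distributions Xᵢ, the integer percentile
  p ∈ [50, 100] minimising Σᵢ |mᵢ − Q_p(Xᵢ)| is found by exhaustive scan
  and then applied to every new video (93rd percentile for *Daphnia*);
* a ground-truthed synthetic scene generator (rotating spheroid, drifting
  particles, optional spine, blur, noise, lens distortion) so the whole
  pipeline can be tested and calibrated with no instrument and no animals.

Videos are read as lossless multi-page TIFF stacks or directories of PNG
frames; convert compressed recordings once (e.g. `ffmpeg -i in.mp4
out.tif`).

## Worked example

```r
library(zoobooth)

# a ground-truthed synthetic clip: 2.4 mm animal at 0.02 mm/px
cfg <- scene_config(width = 390L, height = 330L, frames = 150L,
                    a_px = 60, b_px = 42, appendage_length_px = 0, seed = 7)
v <- render_video(cfg)

profile <- species_profile("synthetic", min_area_px = 150,
                           max_area_px = 60000, min_lw_ratio = 1.2,
                           max_lw_ratio = 1.7, min_brightness = 30,
                           optimal_percentile = 100)
rc <- run_config(profile = profile, mm_per_px = 0.02, seed = 11)
res <- process_video(v$frames, rc, video_name = "demo")

res$summary
#>   video_name    species percentile_used length_mm n_frames low_support
#> 1       demo  synthetic             100  2.439347      116       FALSE
res$reject_counts[res$reject_counts > 0]
#> lw_ratio
#>       34
v$truth$true_length_mm[1]
#> [1] 2.4
```

116 of 150 frames pass the filter; the 34 rejects are frames where the
tilted silhouette's length/width ratio fell below 1.2 — exactly the
strongly foreshortened frames the filter exists to drop. The estimate
(here the distribution maximum, since this single-video demo skips
calibration) lands within 2 % of the true 2.4 mm.

For real data the entry points are `process_folder()` (batch a directory,
append `*.detailedsizedata.csv` and `*.sizedata.csv`, save the first 19
accepted frames as annotated PNGs for manual validation) and
`calibrate_from_files()` (re-derive the optimal percentile from a manual
measurement table whenever the optical set-up changes). A thin CLI wraps
the same functions: `inst/scripts/zoobooth.R measure|calibrate|sim`.

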