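#' Batch run configuration
#'
#' Collects everything a measurement run needs: the species profile, the
#' camera model and pixel scale, the cuvette crop, segmentation and
#' morphology settings, and output toggles.
#'
#' @param species species name looked up in `profiles` (default
#'   `"daphnia"`, which is also the fallback when the name is unknown).
#' @param profiles named list from [load_species_profiles()], or a single
#'   [species_profile()] passed as `profile`.
#' @param profile optional explicit [species_profile()] overriding
#'   `species`.
#' @param camera_model a [camera_model()]; `NULL` uses an identity model
#'   sized to the frames (no distortion correction).
#' @param mm_per_px pixel scale (mm/px) or a [scale_factor()].
#' @param crop_box cuvette inner area `(x, y, w, h)`, 0-based; `NULL`
#'   means the full frame.
#' @param suffix run label used in output filenames.
#' @param min_support accepted-frame count below which summaries are
#'   flagged (default 10).
#' @param seed seed for the background model's RNG stream.
#' @param se_size structuring-element side (odd, default 3).
#' @param erode_iter,dilate_iter morphology iterations (default 3 each;
#'   the erosion budget removes particles and thin appendages, the
#'   dilation restores the body).
#' @param bg named list of overrides for [background_model()] parameters.
#' @param prime_background fill the background sample store from frames
#'   spread over the whole clip before segmenting (default `TRUE`; see
#'   [bg_prime()]).
#' @param save_snapshots write the first 19 accepted frames as annotated
#'   PNGs (default `FALSE`).
#' @param snapshot_dir where snapshots go (default `out_dir`).
#' @param out_dir where the two result CSVs go (default `"."`).
#' @param include_width also report the width at the calibrated percentile
#'   in the summary (default `FALSE`).
#' @param box_sharpness evaluate criterion-iv sharpness on the object's
#'   bounding box instead of the whole frame (default `FALSE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(species = "daphnia", profiles = load_species_profiles(),
                       profile = NULL, camera_model = NULL, mm_per_px = 0.02,
                       crop_box = NULL, suffix = "zoobooth",
                       min_support = 10L, seed = 1L, se_size = 3L,
                       erode_iter = 3L, dilate_iter = 3L, bg = list(),
                       prime_background = TRUE, save_snapshots = FALSE,
                       snapshot_dir = NULL, out_dir = ".",
                       include_width = FALSE, box_sharpness = FALSE) {
  if (is.null(profile)) {
    profile <- profiles[[tolower(species)]]
    if (is.null(profile)) {
      profile <- profiles[["daphnia"]]
      if (is.null(profile)) profile <- default_species_profile()
    }
  }
  if (!inherits(mm_per_px, "scale_factor")) mm_per_px <- scale_factor(mm_per_px)
  structure(list(profile = profile, camera_model = camera_model,
                 scale = mm_per_px, crop_box = crop_box, suffix = suffix,
                 min_support = as.integer(min_support), seed = seed,
                 se_size = as.integer(se_size),
                 erode_iter = as.integer(erode_iter),
                 dilate_iter = as.integer(dilate_iter), bg = bg,
                 prime_background = isTRUE(prime_background),
                 save_snapshots = isTRUE(save_snapshots),
                 snapshot_dir = snapshot_dir, out_dir = out_dir,
                 include_width = isTRUE(include_width),
                 box_sharpness = isTRUE(box_sharpness)),
            class = "run_config")
}

.pipeline_stages <- c("crop", "undistort", "grayscale", "sharpness",
                      "background_subtraction", "erode", "dilate",
                      "find_contours", "select_largest", "fit_ellipse",
                      "species_filter", "mm_conversion")

#' Process one video into per-frame measurements and a summary
#'
#' Runs the full measurement pipeline on one clip, per frame and in fixed
#' order: crop to the cuvette, undistort, grayscale, frame sharpness,
#' adaptive background subtraction, erosion, dilation, contour finding,
#' largest-object selection, ellipse fit, species filtering, and pixel to
#' millimetre conversion. Accepted frames become detailed rows; the
#' calibrated percentile of the accepted lengths becomes the summary row.
#' Videos are processed independently - the background model is rebuilt
#' per clip.
#'
#' @param video a path readable by [read_video()], or a list of grayscale
#'   frames.
#' @param cfg a [run_config()].
#' @param video_name identifier; defaults to the filename stem.
#' @return List with `detailed` (data.frame, one row per accepted frame),
#'   `summary` (one-row data.frame), `reject_counts` (named integer
#'   vector), `snapshots` (paths, if saved) and attribute `stages`.
#' @export
process_video <- function(video, cfg = run_config(), video_name = NULL) {
  if (is.character(video)) {
    if (is.null(video_name)) video_name <- parse_filename(video)$name
    frames <- read_video(video)
  } else {
    frames <- video
    if (is.null(video_name)) video_name <- "video"
  }
  if (length(frames) == 0L) stop("empty video", call. = FALSE)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  cb <- cfg$crop_box
  if (is.null(cb)) cb <- c(0, 0, w, h)
  rows <- (cb[2] + 1):(cb[2] + cb[4])
  cols <- (cb[1] + 1):(cb[1] + cb[3])
  cam <- cfg$camera_model
  if (is.null(cam)) cam <- identity_camera_model(w, h)
  umap <- undistort_map(cam, cb[3], cb[4], origin = cb[1:2])
  bg_args <- utils::modifyList(
    list(width = cb[3], height = cb[4], seed = cfg$seed), cfg$bg)
  model <- do.call(background_model, bg_args)
  se_erode <- struct_el(cfg$se_size, iterations = cfg$erode_iter)
  se_dilate <- struct_el(cfg$se_size, iterations = cfg$dilate_iter)
  crop_local <- c(0, 0, cb[3], cb[4])

  full_crop <- cb[1] == 0 && cb[2] == 0 && cb[3] == w && cb[4] == h
  prep <- function(fr) {
    if (!full_crop) fr <- fr[rows, cols, drop = FALSE]
    undistort(fr, cam, map = umap)
  }
  if (cfg$prime_background) {
    picks <- unique(round(seq(1, length(frames), length.out = min(15L, length(frames)))))
    bg_prime(model, lapply(frames[picks], prep))
  }

  detailed <- list()
  widths_mm <- numeric(0)
  snap_frames <- list(); snap_fits <- list()
  reject_counts <- c(none_detected = 0L, degenerate = 0L, area = 0L,
                     lw_ratio = 0L, brightness = 0L, sharpness = 0L,
                     edge = 0L)
  for (f in seq_along(frames)) {
    gray <- prep(frames[[f]])
    sharp <- sharpness(gray)
    mask <- bg_subtract(model, gray)
    if (cfg$erode_iter > 0L) mask <- erode(mask, se_erode)
    if (cfg$dilate_iter > 0L) mask <- dilate(mask, se_dilate)
    contours <- find_contours(mask)
    largest <- select_largest(contours)
    if (is.null(largest)) {
      reject_counts["none_detected"] <- reject_counts["none_detected"] + 1L
      next
    }
    m <- measure_object(largest, gray, crop_local, frame_index = f - 1L,
                        frame_sharpness = sharp)
    if (is.null(m)) {
      reject_counts["degenerate"] <- reject_counts["degenerate"] + 1L
      next
    }
    if (cfg$box_sharpness) {
      m$sharpness <- box_sharpness(gray, attr(largest, "pixels"))
    }
    verdict <- apply_species_filter(m, cfg$profile)
    if (!verdict$accept) {
      reject_counts[verdict$reason] <- reject_counts[verdict$reason] + 1L
      next
    }
    detailed[[length(detailed) + 1L]] <- data.frame(
      video_name = video_name, frame_index = m$frame_index,
      length_px = m$major_axis_px, width_px = m$minor_axis_px,
      length_mm = px_to_mm(m$major_axis_px, cfg$scale),
      width_mm = px_to_mm(m$minor_axis_px, cfg$scale),
      area_px = m$area_px, brightness = m$brightness,
      sharpness = m$sharpness, center_x = m$center_x, center_y = m$center_y,
      stringsAsFactors = FALSE)
    widths_mm <- c(widths_mm, px_to_mm(m$minor_axis_px, cfg$scale))
    if (cfg$save_snapshots && length(snap_frames) < 19L) {
      sf <- gray
      attr(sf, "frame_index") <- m$frame_index
      snap_frames[[length(snap_frames) + 1L]] <- sf
      snap_fits[[length(snap_fits) + 1L]] <- m$fit
    }
  }
  detailed <- if (length(detailed) > 0L) {
    do.call(rbind, detailed)
  } else {
    empty_detailed()
  }
  dist <- size_distribution(video_name, detailed$length_mm)
  summary <- summarize_video(dist, cfg$profile, min_support = cfg$min_support,
                             include_width = if (cfg$include_width) widths_mm)
  out <- list(detailed = detailed, summary = summary,
              reject_counts = reject_counts)
  if (cfg$save_snapshots) {
    sdir <- if (is.null(cfg$snapshot_dir)) cfg$out_dir else cfg$snapshot_dir
    out$snapshots <- save_snapshots(snap_frames, snap_fits, sdir, video_name)
  }
  attr(out, "stages") <- .pipeline_stages
  out
}

# Criterion-iv variant: Laplacian variance restricted to the object's
# bounding box (config-selectable; whole-frame sharpness is the default).
box_sharpness <- function(gray, pixels) {
  h <- nrow(gray)
  ys <- ((pixels - 1L) %% h) + 1L
  xs <- ((pixels - 1L) %/% h) + 1L
  box <- gray[min(ys):max(ys), min(xs):max(xs), drop = FALSE]
  if (length(box) < 9L) return(0)
  sharpness(box)
}

#' Process every video in a folder
#'
#' Reproduces the batch workflow: videos are processed in sorted filename
#' order, each independently, and results are appended to one detailed
#' and one summary CSV per run (named from the run suffix). Unreadable
#' videos are logged and skipped.
#'
#' @param input folder containing `.tif`/`.tiff` frame stacks (or
#'   subdirectories of PNG frames).
#' @param cfg a [run_config()]; its `out_dir` and `suffix` control the
#'   output files.
#' @return Invisibly, a batch report data.frame (one row per video:
#'   accepted frames, length estimate, elapsed seconds) with attributes
#'   `detailed_path` and `summary_path`.
#' @export
process_folder <- function(input, cfg = run_config()) {
  stopifnot(dir.exists(input))
  vids <- sort(c(list.files(input, pattern = "\\.tiff?$", full.names = TRUE),
                 list.dirs(input, recursive = FALSE)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  detailed_path <- file.path(cfg$out_dir,
                             paste0(cfg$suffix, ".detailedsizedata.csv"))
  summary_path <- file.path(cfg$out_dir, paste0(cfg$suffix, ".sizedata.csv"))
  if (file.exists(detailed_path)) file.remove(detailed_path)
  if (file.exists(summary_path)) file.remove(summary_path)
  if (length(vids) == 0L) {
    warning("no videos found in ", input, call. = FALSE)
    write_detailed(empty_detailed(), detailed_path)
  }
  report <- list()
  for (v in vids) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(process_video(v, cfg), error = function(e) {
      message("skipping ", v, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    write_detailed(res$detailed, detailed_path, append = TRUE)
    write_summary(res$summary, summary_path, append = TRUE)
    dt <- proc.time()[["elapsed"]] - t0
    message(sprintf("%s: %d accepted frames, length %.3f mm (%.1f s)",
                    basename(v), res$summary$n_frames,
                    res$summary$length_mm, dt))
    report[[length(report) + 1L]] <- data.frame(
      video = basename(v), n_frames = res$summary$n_frames,
      length_mm = res$summary$length_mm, seconds = dt,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report) > 0L) do.call(rbind, report) else
    data.frame(video = character(0), n_frames = integer(0),
               length_mm = numeric(0), seconds = numeric(0))
  attr(report, "detailed_path") <- detailed_path
  attr(report, "summary_path") <- summary_path
  invisible(report)
}

#' Calibrate the optimal percentile from batch outputs
#'
#' Joins a manual-measurement table against a detailed per-frame CSV by
#' `video_name` and runs [find_optimal_percentile()].
#'
#' @param detailed a detailed data.frame or path to a
#'   `*.detailedsizedata.csv`.
#' @param manual data.frame with `video_name` and `manual_mm`, or a CSV
#'   path.
#' @return A `calibration_result` (see [find_optimal_percentile()]).
#' @export
calibrate_from_files <- function(detailed, manual) {
  if (is.character(detailed)) detailed <- read_sizedata(detailed)
  if (is.character(manual)) manual <- read_sizedata(manual)
  pairs <- list()
  for (i in seq_len(nrow(manual))) {
    lens <- detailed$length_mm[detailed$video_name == manual$video_name[i]]
    if (length(lens) > 0L) {
      pairs[[length(pairs) + 1L]] <-
        calibration_pair(manual$manual_mm[i], lens)
    }
  }
  if (length(pairs) == 0L) {
    stop("no videos in common between the manual table and the detailed data",
         call. = FALSE)
  }
  find_optimal_percentile(pairs)
}
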