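#' Percentile of a length distribution
#'
#' The estimator the whole method rests on: because the animal rotates
#' freely in three dimensions, most projected lengths undershoot the true
#' body length, so a high percentile of the per-video distribution - not
#' the mean or median - recovers it. Uses linear interpolation between
#' order statistics (with sorted values `v(1..n)` and `h = (n-1)p/100`,
#' the result is `v(floor(h)+1) + (h - floor(h)) * (v(floor(h)+2) -
#' v(floor(h)+1))`; `p = 100` gives the maximum). A nearest-rank mode is
#' available for sensitivity checks.
#'
#' @param values non-empty numeric vector.
#' @param p percentile in `[0, 100]`.
#' @param method `"linear"` (default) or `"nearest"` (inverse-CDF rank).
#' @return The percentile value.
#' @export
percentile <- function(values, p, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 100) {
    stop("p must be a single value in [0, 100]", call. = FALSE)
  }
  type <- if (method == "linear") 7L else 1L
  stats::quantile(values, probs = p / 100, type = type, names = FALSE)
}

#' Per-video length distribution
#'
#' All accepted per-frame length measurements of one video; the object the
#' percentile statistic acts on.
#'
#' @param video_name identifier of the clip.
#' @param lengths_mm numeric vector of accepted lengths (mm), possibly empty.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(video_name, lengths_mm) {
  lengths_mm <- as.numeric(lengths_mm)
  if (any(lengths_mm <= 0, na.rm = TRUE) || any(!is.finite(lengths_mm))) {
    stop("lengths must be finite and > 0", call. = FALSE)
  }
  structure(list(video_name = video_name, lengths_mm = lengths_mm,
                 n_frames = length(lengths_mm)),
            class = "size_distribution")
}

#' Summarise a video's length distribution into one estimate
#'
#' Applies the species' calibrated percentile to the distribution and
#' reports the number of supporting frames. Distributions with fewer than
#' `min_support` frames are flagged low-support but still reported; an
#' empty distribution yields a missing length.
#'
#' @param dist a [size_distribution()].
#' @param profile a [species_profile()] (supplies the percentile).
#' @param min_support flag threshold on the accepted-frame count
#'   (default 10, about 3 s of usable footage at typical frame rates).
#' @param include_width optional numeric vector of accepted widths (mm);
#'   when given, the width at the same percentile is added.
#' @return A one-row data.frame (a summary size row).
#' @export
summarize_video <- function(dist, profile, min_support = 10L,
                            include_width = NULL) {
  p <- profile$optimal_percentile
  if (dist$n_frames == 0L) {
    row <- data.frame(video_name = dist$video_name, species = profile$name,
                      percentile_used = p, length_mm = NA_real_,
                      n_frames = 0L, low_support = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    row <- data.frame(video_name = dist$video_name, species = profile$name,
                      percentile_used = p,
                      length_mm = percentile(dist$lengths_mm, p),
                      n_frames = dist$n_frames,
                      low_support = dist$n_frames < min_support,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(include_width) && length(include_width) > 0L) {
    row$width_mm <- percentile(include_width, p)
  }
  row
}

#' Pair a manual measurement with a video's length distribution
#'
#' @param manual_mm manually measured body length (mm), > 0.
#' @param lengths_mm the video's accepted per-frame lengths, or a
#'   [size_distribution()].
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(manual_mm, lengths_mm) {
  if (inherits(lengths_mm, "size_distribution")) {
    lengths_mm <- lengths_mm$lengths_mm
  }
  stopifnot(manual_mm > 0, length(lengths_mm) > 0)
  structure(list(manual_mm = manual_mm, lengths_mm = as.numeric(lengths_mm)),
            class = "calibration_pair")
}

#' Calibrate the optimal percentile against manual measurements
#'
#' For each integer percentile p in 50..100 the objective is the summed
#' absolute difference between each individual's manual length and the
#' p-th percentile of its video length distribution; the optimal
#' percentile is the exhaustive-scan argmin (ties broken towards the lower
#' percentile). This calibration is per-taxon and should be repeated
#' whenever the instrument geometry changes.
#'
#' @param pairs non-empty list of [calibration_pair()] objects.
#' @param method percentile definition passed to [percentile()].
#' @return An object of class `calibration_result`: `optimal_percentile`,
#'   `objective_by_percentile` (named vector over 50..100, mm) and
#'   `n_pairs`.
#' @export
find_optimal_percentile <- function(pairs, method = "linear") {
  if (length(pairs) == 0L) stop("need at least one calibration pair",
                                call. = FALSE)
  grid <- 50:100
  objective <- vapply(grid, function(p) {
    sum(vapply(pairs, function(pr) {
      abs(pr$manual_mm - percentile(pr$lengths_mm, p, method = method))
    }, numeric(1)))
  }, numeric(1))
  names(objective) <- grid
  structure(list(optimal_percentile = grid[which.min(objective)],
                 objective_by_percentile = objective,
                 n_pairs = length(pairs)),
            class = "calibration_result")
}

#' Agreement statistics between video estimates and manual measurements
#'
#' Reports Pearson's correlation, the linear-model R-squared (video
#' estimate regressed on the manual measurement) and, per size bin
#' (< 2 mm, 2-3 mm, > 3 mm), the mean absolute difference and the average
#' relative percentage difference (mean difference / mean size x 100).
#'
#' @param manual_mm manual lengths (mm).
#' @param estimate_mm video length estimates (mm), same length.
#' @param bin_edges_mm interior bin edges (default `c(2, 3)`).
#' @return A list with `pearson_r`, `r_squared`, `n` and a `bins`
#'   data.frame (`bin`, `n`, `mean_size_mm`, `mean_abs_diff_mm`,
#'   `relative_diff_pct`). With zero variance the correlation is `NA`.
#' @export
assess_estimates <- function(manual_mm, estimate_mm, bin_edges_mm = c(2, 3)) {
  stopifnot(length(manual_mm) == length(estimate_mm))
  if (length(manual_mm) < 3L) stop("need at least 3 pairs", call. = FALSE)
  r <- if (stats::sd(manual_mm) == 0 || stats::sd(estimate_mm) == 0) {
    NA_real_
  } else {
    stats::cor(manual_mm, estimate_mm)
  }
  r2 <- if (is.na(r)) NA_real_ else {
    summary(stats::lm(estimate_mm ~ manual_mm))$r.squared
  }
  edges <- c(-Inf, bin_edges_mm, Inf)
  labels <- c(sprintf("<%g", bin_edges_mm[1]),
              if (length(bin_edges_mm) > 1) {
                sprintf("%g-%g", bin_edges_mm[-length(bin_edges_mm)],
                        bin_edges_mm[-1])
              },
              sprintf(">%g", bin_edges_mm[length(bin_edges_mm)]))
  bin <- cut(manual_mm, edges, labels = labels)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- which(bin == b)
    if (length(i) == 0L) {
      data.frame(bin = b, n = 0L, mean_size_mm = NA_real_,
                 mean_abs_diff_mm = NA_real_, relative_diff_pct = NA_real_)
    } else {
      mad <- mean(abs(estimate_mm[i] - manual_mm[i]))
      msz <- mean(manual_mm[i])
      data.frame(bin = b, n = length(i), mean_size_mm = msz,
                 mean_abs_diff_mm = mad,
                 relative_diff_pct = mad / msz * 100)
    }
  }))
  list(pearson_r = r, r_squared = r2, n = length(manual_mm), bins = bins)
}
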