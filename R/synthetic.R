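#' Synthetic dark-field scene configuration
#'
#' Describes a ground-truthed emulation of the filming booth: a bright,
#' freely rotating prolate spheroid (the animal) drifting inside the
#' cuvette crop on a dark background, with drifting particle noise,
#' optional thin appendages (spine/antennae), Gaussian blur and pixel
#' noise, and optional forward lens distortion. The spheroid's
#' orthographic silhouette is an ellipse with semi-major axis
#' `sqrt(a^2 cos^2(theta) + b^2 sin^2(theta))`, where `theta` is the angle
#' between the long axis and the image plane - the reason projected
#' lengths undershoot the true length and a high percentile is the right
#' estimator.
#'
#' @param width,height frame size in pixels (default 1080 x 768).
#' @param crop_box cuvette inner area `(x, y, w, h)`, 0-based; default the
#'   full frame.
#' @param frames number of frames (default 780, i.e. 30 s at 26 fps).
#' @param a_px,b_px spheroid semi-axes in pixels, `a >= b > 0`.
#' @param body_intensity,body_texture_sd mean and texture s.d. of the body
#'   (8-bit levels).
#' @param background_intensity dark-field background level.
#' @param n_particles,particle_radius,particle_intensity drifting debris.
#' @param appendage,appendage_length_px,appendage_width_px thin bright
#'   appendage along the major axis (off by default).
#' @param swim_speed_px directed swimming speed (px/frame); the heading
#'   performs its own random walk and bounces off the crop walls. Free
#'   swimming matters for segmentation: the animal must vacate pixels so
#'   the adaptive background model sees the true background.
#' @param heading_sd heading random-walk step s.d. (radians/frame).
#' @param drift_sd additional centre jitter s.d. (px/frame).
#' @param angle_step_sd orientation random-walk step s.d. (radians/frame)
#'   of the long-axis unit vector on the sphere.
#' @param initial_axis optional 3-vector fixing the initial long-axis
#'   direction (x, y in the image plane, z along the optical axis);
#'   with `angle_step_sd = 0` this pins the orientation, which is how
#'   the projection law is validated.
#' @param blur_sd Gaussian blur s.d. in pixels (0 disables).
#' @param noise_sd additive Gaussian pixel noise s.d.
#' @param camera_model optional [camera_model()] used to forward-distort
#'   the rendered frames.
#' @param mm_per_px pixel scale used for the truth table (default 0.02).
#' @param seed RNG seed; rendering is fully deterministic given the seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 1080L, height = 768L, crop_box = NULL,
                         frames = 780L, a_px = 60, b_px = 42,
                         body_intensity = 170, body_texture_sd = 8,
                         background_intensity = 8,
                         n_particles = 12L, particle_radius = 1.5,
                         particle_intensity = 60,
                         appendage = FALSE, appendage_length_px = 30,
                         appendage_width_px = 2,
                         swim_speed_px = 6, heading_sd = 0.2,
                         drift_sd = 0.5, angle_step_sd = 0.08,
                         initial_axis = NULL,
                         blur_sd = 0.8, noise_sd = 2,
                         camera_model = NULL, mm_per_px = 0.02, seed = 1L) {
  if (is.null(crop_box)) crop_box <- c(0, 0, width, height)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              crop_box = crop_box, frames = as.integer(frames),
              a_px = a_px, b_px = b_px,
              body_intensity = body_intensity,
              body_texture_sd = body_texture_sd,
              background_intensity = background_intensity,
              n_particles = as.integer(n_particles),
              particle_radius = particle_radius,
              particle_intensity = particle_intensity,
              appendage = isTRUE(appendage),
              appendage_length_px = appendage_length_px,
              appendage_width_px = appendage_width_px,
              swim_speed_px = swim_speed_px, heading_sd = heading_sd,
              drift_sd = drift_sd, angle_step_sd = angle_step_sd,
              initial_axis = initial_axis,
              blur_sd = blur_sd, noise_sd = noise_sd,
              camera_model = camera_model, mm_per_px = mm_per_px,
              seed = seed)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (!(cfg$a_px >= cfg$b_px && cfg$b_px > 0)) {
    stop("spheroid semi-axes must satisfy a >= b > 0", call. = FALSE)
  }
  if (cfg$body_intensity <= cfg$background_intensity) {
    stop("body intensity must exceed the background", call. = FALSE)
  }
  cb <- cfg$crop_box
  if (cb[1] < 0 || cb[2] < 0 || cb[1] + cb[3] > cfg$width ||
      cb[2] + cb[4] > cfg$height) {
    stop("crop box must lie within the frame", call. = FALSE)
  }
  if (cfg$frames < 1L) stop("need at least one frame", call. = FALSE)
  invisible(cfg)
}

# Separable Gaussian blur with truncated-kernel renormalisation at the
# borders, implemented with shifted accumulation.
gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- max(1L, ceiling(3 * sd))
  g <- stats::dnorm(-r:r, sd = sd)
  conv1 <- function(n) {
    # sum of in-range kernel weights at each border-distance position
    vapply(seq_len(n), function(i) {
      k <- (-r:r)[i + (-r:r) >= 1 & i + (-r:r) <= n]
      sum(g[k + r + 1])
    }, numeric(1))
  }
  acc <- g[r + 1] * img
  for (d in seq_len(r)) {
    acc <- acc + g[r + 1 + d] * shift_mat(img, d, 0L) +
      g[r + 1 - d] * shift_mat(img, -d, 0L)
  }
  acc <- acc / conv1(h)        # divides each column by the row norms
  out <- g[r + 1] * acc
  for (d in seq_len(r)) {
    out <- out + g[r + 1 + d] * shift_mat(acc, 0L, d) +
      g[r + 1 - d] * shift_mat(acc, 0L, -d)
  }
  sweep(out, 2L, conv1(w), "/")
}

# Blur only a window of the frame: outside the window the image is
# constant (dark background), where a normalized Gaussian is a no-op, so
# blurring a padded patch and writing back the target region is exact.
blur_patch <- function(img, ys, xs, sd) {
  r <- max(1L, ceiling(3 * sd))
  py <- max(1L, min(ys) - r):min(nrow(img), max(ys) + r)
  px <- max(1L, min(xs) - r):min(ncol(img), max(xs) + r)
  blurred <- gaussian_blur(img[py, px, drop = FALSE], sd)
  img[ys, xs] <- blurred[ys - py[1] + 1L, xs - px[1] + 1L]
  img
}

# Forward-distort a clean frame: each distorted pixel samples the ideal
# frame at the numerically inverted distortion position.
distort_frame <- function(frame, model) {
  h <- nrow(frame); w <- ncol(frame)
  u <- rep(seq_len(w) - 1, each = h)
  v <- rep(seq_len(h) - 1, times = w)
  src <- undistort_points(cbind(u, v), model)
  bilinear_sample(frame, src[, 1], src[, 2])
}

bilinear_sample <- function(frame, xs, ys) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  v <- as.numeric(frame)
  gather <- function(xq, yq) {
    ok <- xq >= 0 & xq <= w - 1 & yq >= 0 & yq <= h - 1
    val <- numeric(length(xq))
    val[ok] <- v[yq[ok] + 1 + xq[ok] * h]
    val
  }
  out <- gather(x0, y0) * (1 - fx) * (1 - fy) +
    gather(x0 + 1, y0) * fx * (1 - fy) +
    gather(x0, y0 + 1) * (1 - fx) * fy +
    gather(x0 + 1, y0 + 1) * fx * fy
  matrix(out, h, w)
}

#' Render a ground-truthed synthetic video
#'
#' Per frame, the long-axis orientation performs a seeded random walk on
#' the unit sphere and the centre a seeded drift reflected at the crop
#' walls; the orthographic silhouette ellipse is rasterized with optional
#' appendage, particles, blur, noise and forward distortion are added, and
#' the per-frame ground truth (tilt angle, projected axes, centre, true
#' length) is recorded.
#'
#' @param cfg a [scene_config()].
#' @param dir optional output directory; when given, writes
#'   `<video_name>.tif` (lossless frame stack) and
#'   `<video_name>.truth.csv`.
#' @param video_name stem for outputs (default `"synthetic"`).
#' @return List with `frames` (list of integer matrices), `truth`
#'   (data.frame) and, when written, `video_path` / `truth_path`.
#' @export
render_video <- function(cfg, dir = NULL, video_name = "synthetic") {
  validate_scene_config(cfg)
  with_seed(cfg$seed, render_video_impl(cfg, dir, video_name))
}

render_video_impl <- function(cfg, dir, video_name) {
  w <- cfg$width; h <- cfg$height
  cb <- cfg$crop_box
  a <- cfg$a_px; b <- cfg$b_px
  # margin keeps body and (potential) appendage inside the crop; it is
  # independent of the appendage toggle so that on/off renders of the same
  # seed share identical trajectories and differ only in appendage pixels
  margin <- a + cfg$appendage_length_px + 12
  lo <- c(cb[1] + margin, cb[2] + margin)
  hi <- c(cb[1] + cb[3] - 1 - margin, cb[2] + cb[4] - 1 - margin)
  if (any(hi <= lo)) stop("crop box too small for the body size", call. = FALSE)
  center <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
  heading <- stats::runif(1, 0, 2 * pi)
  u <- if (is.null(cfg$initial_axis)) stats::rnorm(3) else cfg$initial_axis
  u <- u / sqrt(sum(u^2))
  particles <- cbind(stats::runif(cfg$n_particles, cb[1], cb[1] + cb[3] - 1),
                     stats::runif(cfg$n_particles, cb[2], cb[2] + cb[4] - 1))
  frames <- vector("list", cfg$frames)
  truth <- vector("list", cfg$frames)
  for (f in seq_len(cfg$frames)) {
    u <- u + stats::rnorm(3, sd = cfg$angle_step_sd)
    u <- u / sqrt(sum(u^2))
    sin_t <- min(1, abs(u[3]))
    theta <- asin(sin_t)
    phi <- atan2(u[2], u[1])
    A <- sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
    heading <- heading + stats::rnorm(1, sd = cfg$heading_sd)
    step <- cfg$swim_speed_px * c(cos(heading), sin(heading)) +
      stats::rnorm(2, sd = cfg$drift_sd)
    prev <- center
    center <- reflect(center + step, lo, hi)
    # bounce the heading off the wall the reflection touched
    if (abs((prev[1] + step[1]) - center[1]) > 1e-9) heading <- pi - heading
    if (abs((prev[2] + step[2]) - center[2]) > 1e-9) heading <- -heading
    img <- matrix(cfg$background_intensity, h, w)
    # rasterize the body only inside its bounding window
    ext <- A + cfg$appendage_length_px * cfg$appendage + 2
    wx <- max(1L, floor(center[1] - ext) + 1L):min(w, ceiling(center[1] + ext) + 1L)
    wy <- max(1L, floor(center[2] - ext) + 1L):min(h, ceiling(center[2] + ext) + 1L)
    dx <- matrix(rep(wx - 1 - center[1], each = length(wy)),
                 length(wy), length(wx))
    dy <- matrix(rep(wy - 1 - center[2], times = length(wx)),
                 length(wy), length(wx))
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- (xr / A)^2 + (yr / b)^2 <= 1
    patch <- img[wy, wx, drop = FALSE]
    patch[inside] <- cfg$body_intensity +
      stats::rnorm(sum(inside), sd = cfg$body_texture_sd)
    if (cfg$appendage) {
      lp <- cfg$appendage_length_px * cos(theta)
      # a thin spine attached at the posterior tip, tapering nowhere:
      # it must be erodible, like the real animal's spine and antennae
      app <- xr >= A - 1 & xr <= A + lp &
        abs(yr) <= cfg$appendage_width_px / 2 & !inside
      patch[app] <- cfg$body_intensity
    }
    img[wy, wx] <- patch
    particle_windows <- list()
    if (cfg$n_particles > 0L) {
      particles <- particles + matrix(stats::rnorm(2 * cfg$n_particles, sd = 1),
                                      ncol = 2)
      particles[, 1] <- pmin(pmax(particles[, 1], cb[1]), cb[1] + cb[3] - 1)
      particles[, 2] <- pmin(pmax(particles[, 2], cb[2]), cb[2] + cb[4] - 1)
      r <- cfg$particle_radius
      for (p in seq_len(cfg$n_particles)) {
        px <- max(1L, floor(particles[p, 1] - r) + 1L):
          min(w, ceiling(particles[p, 1] + r) + 1L)
        py <- max(1L, floor(particles[p, 2] - r) + 1L):
          min(h, ceiling(particles[p, 2] + r) + 1L)
        pdx <- matrix(rep(px - 1 - particles[p, 1], each = length(py)),
                      length(py), length(px))
        pdy <- matrix(rep(py - 1 - particles[p, 2], times = length(px)),
                      length(py), length(px))
        pp <- img[py, px, drop = FALSE]
        pp[pdx^2 + pdy^2 <= r^2] <- cfg$particle_intensity
        img[py, px] <- pp
        particle_windows[[p]] <- list(py, px)
      }
    }
    if (cfg$blur_sd > 0) {
      # the frame is constant background away from the body and the
      # particles, so blurring those windows is exact and cheap
      img <- blur_patch(img, wy, wx, cfg$blur_sd)
      for (pw in particle_windows) {
        img <- blur_patch(img, pw[[1]], pw[[2]], cfg$blur_sd)
      }
    }
    if (cfg$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = cfg$noise_sd)
    }
    if (!is.null(cfg$camera_model)) {
      img <- distort_frame(img, cfg$camera_model)
    }
    m <- clip255(round(img))
    storage.mode(m) <- "integer"
    frames[[f]] <- m
    truth[[f]] <- data.frame(
      frame_index = f - 1L, theta_rad = theta, phi_rad = phi,
      projected_major_px = 2 * A, projected_minor_px = 2 * b,
      center_x = center[1], center_y = center[2],
      true_length_px = 2 * a, true_length_mm = 2 * a * cfg$mm_per_px)
  }
  truth <- do.call(rbind, truth)
  out <- list(frames = frames, truth = truth, video_name = video_name)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$video_path <- file.path(dir, paste0(video_name, ".tif"))
    out$truth_path <- file.path(dir, paste0(video_name, ".truth.csv"))
    write_video(frames, out$video_path)
    utils::write.csv(truth, out$truth_path, row.names = FALSE)
  }
  out
}

reflect <- function(x, lo, hi) {
  for (i in seq_along(x)) {
    if (x[i] < lo[i]) x[i] <- lo[i] + (lo[i] - x[i])
    if (x[i] > hi[i]) x[i] <- hi[i] - (x[i] - hi[i])
    x[i] <- min(max(x[i], lo[i]), hi[i])
  }
  x
}

#' Build a ground-truthed calibration cohort
#'
#' Draws individuals with true lengths uniform in `length_range_mm`,
#' derives per-individual scene configurations from a template (the
#' spheroid aspect ratio is kept), and simulates the paired manual
#' measurements as true length plus Gaussian error. Videos are rendered
#' lazily from the returned configurations so only one clip need exist in
#' memory at a time; with `dir` given they are rendered to disk instead.
#'
#' @param n_individuals cohort size.
#' @param length_range_mm range of true body lengths (mm).
#' @param template a [scene_config()] used for everything but the axes and
#'   the frame geometry: each scene is sized to its animal (margin plus a
#'   swimming range of several body lengths), mirroring how cuvette sizes
#'   are paired with animal sizes on the instrument.
#' @param manual_sd_mm s.d. of the simulated manual-measurement error
#'   (default 0.02 mm, about one pixel of digitising error).
#' @param seed cohort seed; individual i renders with seed `seed + i`.
#' @param dir optional directory to render all videos into.
#' @return List with `configs` (list of `scene_config`), `manual`
#'   (data.frame `video_name`, `manual_mm`) and `truth` (data.frame
#'   `video_name`, `true_length_mm`).
#' @export
make_calibration_cohort <- function(n_individuals, length_range_mm = c(0.8, 4),
                                    template = scene_config(),
                                    manual_sd_mm = 0.02, seed = 1L,
                                    dir = NULL) {
  stopifnot(n_individuals >= 1L)
  aspect <- template$a_px / template$b_px
  draws <- with_seed(seed, {
    list(len = stats::runif(n_individuals, length_range_mm[1],
                            length_range_mm[2]),
         err = stats::rnorm(n_individuals, sd = manual_sd_mm))
  })
  configs <- vector("list", n_individuals)
  names_ <- sprintf("sim%03d", seq_len(n_individuals))
  for (i in seq_len(n_individuals)) {
    cfg <- template
    cfg$a_px <- draws$len[i] / 2 / template$mm_per_px
    cfg$b_px <- cfg$a_px / aspect
    cfg$seed <- seed + i
    # scale the scene to the animal (as the instrument pairs cuvette sizes
    # to animal sizes): the swimming range must exceed the body footprint
    # so the animal vacates pixels and the background can be learned
    margin <- ceiling(cfg$a_px + cfg$appendage_length_px + 12)
    cfg$width <- as.integer(2 * margin + ceiling(3.2 * cfg$a_px))
    cfg$height <- as.integer(2 * margin + ceiling(2.4 * cfg$a_px))
    cfg$crop_box <- c(0, 0, cfg$width, cfg$height)
    configs[[i]] <- cfg
    if (!is.null(dir)) render_video(cfg, dir = dir, video_name = names_[i])
  }
  list(configs = configs,
       manual = data.frame(video_name = names_,
                           manual_mm = pmax(draws$len + draws$err, 1e-6)),
       truth = data.frame(video_name = names_, true_length_mm = draws$len))
}
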