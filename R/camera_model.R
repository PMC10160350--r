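#' Camera model for lens-distortion correction
#'
#' Bundles the intrinsic camera matrix, Brown-Conrady distortion
#' coefficients, the rectified ("new") camera matrix and the valid-pixel
#' region of interest produced by a one-off checkerboard calibration of the
#' instrument's lens. The model is applied once per frame to remove the
#' barrel distortion of the short-focal-length lens before any measurement.
#'
#' @param intrinsic 3x3 numeric matrix with focal lengths `fx`, `fy` on the
#'   diagonal and principal point `cx`, `cy` in the last column (pixels).
#' @param distortion numeric vector of 5 coefficients `(k1, k2, p1, p2, k3)`:
#'   radial `k1..k3`, tangential `p1`, `p2`. Dimensionless.
#' @param rectified_intrinsic 3x3 matrix used to project the undistorted
#'   image; defaults to `intrinsic`.
#' @param roi integer vector `(x, y, width, height)`, 0-based half-open
#'   rectangle of fully valid pixels after undistortion.
#' @return An object of class `camera_model`.
#' @seealso [load_camera_model()], [undistort()]
#' @export
camera_model <- function(intrinsic, distortion = rep(0, 5),
                         rectified_intrinsic = intrinsic,
                         roi = NULL) {
  intrinsic <- as_matrix33(intrinsic, "intrinsic")
  rectified_intrinsic <- as_matrix33(rectified_intrinsic, "rectified_intrinsic")
  distortion <- as.numeric(distortion)
  if (length(distortion) != 5L || any(!is.finite(distortion))) {
    stop("distortion must be 5 finite coefficients (k1, k2, p1, p2, k3)",
         call. = FALSE)
  }
  if (intrinsic[1, 1] <= 0 || intrinsic[2, 2] <= 0 ||
      rectified_intrinsic[1, 1] <= 0 || rectified_intrinsic[2, 2] <= 0) {
    stop("focal lengths fx, fy must be strictly positive", call. = FALSE)
  }
  if (!is.null(roi)) {
    roi <- as.numeric(roi)
    if (length(roi) != 4L || any(!is.finite(roi)) || roi[3] <= 0 || roi[4] <= 0) {
      stop("roi must be (x, y, width, height) with positive size", call. = FALSE)
    }
  }
  structure(list(intrinsic = intrinsic, distortion = distortion,
                 rectified_intrinsic = rectified_intrinsic, roi = roi),
            class = "camera_model")
}

as_matrix33 <- function(m, what) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || any(!is.finite(m))) {
    stop(sprintf("%s must be a finite 3x3 matrix", what), call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Identity camera model
#'
#' A convenience model with unit focal lengths scaled to the frame, centred
#' principal point and zero distortion, under which [undistort()] is the
#' identity. Useful when no calibration is available or for synthetic data.
#'
#' @param width,height frame size in pixels.
#' @return A `camera_model`.
#' @export
identity_camera_model <- function(width, height) {
  k <- matrix(c(max(width, height), 0, (width - 1) / 2,
                0, max(width, height), (height - 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  camera_model(k, rep(0, 5), k, c(0, 0, width, height))
}

.calibration_files <- c(dist = "dist.out", mtx = "mtx.out",
                        newcameramtx = "newcameramtx.out", roi = "roi.out")

#' Load a camera model from a calibration folder
#'
#' Reads the four whitespace-delimited numeric text files that the one-off
#' checkerboard calibration emits into a `lenscalibration/` folder:
#' `mtx.out` (3x3 intrinsic matrix), `dist.out` (5 distortion coefficients),
#' `newcameramtx.out` (3x3 rectified matrix) and `roi.out` (x, y, width,
#' height of the valid region).
#'
#' @param folder path to the folder holding the four files.
#' @return A validated [camera_model()].
#' @export
load_camera_model <- function(folder) {
  paths <- file.path(folder, .calibration_files)
  names(paths) <- names(.calibration_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing calibration file(s): ",
         paste(.calibration_files[missing], collapse = ", "),
         " in ", folder, call. = FALSE)
  }
  read_num <- function(p, n_expected, file) {
    v <- tryCatch(scan(p, what = double(), quiet = TRUE),
                  error = function(e) stop("cannot parse ", file, ": ",
                                           conditionMessage(e), call. = FALSE))
    if (length(v) != n_expected) {
      stop(sprintf("%s: expected %d values, found %d", file, n_expected,
                   length(v)), call. = FALSE)
    }
    v
  }
  mtx <- matrix(read_num(paths["mtx"], 9L, "mtx.out"), 3, 3, byrow = TRUE)
  dist <- read_num(paths["dist"], 5L, "dist.out")
  newmtx <- matrix(read_num(paths["newcameramtx"], 9L, "newcameramtx.out"),
                   3, 3, byrow = TRUE)
  roi <- read_num(paths["roi"], 4L, "roi.out")
  camera_model(mtx, dist, newmtx, roi)
}

#' Write a camera model to a calibration folder
#'
#' Inverse of [load_camera_model()]; writes the four plain-text files so
#' fixtures and re-deployments never depend on external calibration tools.
#'
#' @param model a [camera_model()].
#' @param folder destination folder (created if absent).
#' @return `folder`, invisibly.
#' @export
write_camera_model <- function(model, folder) {
  stopifnot(inherits(model, "camera_model"))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  writeLines(apply(model$intrinsic, 1, fmt), file.path(folder, "mtx.out"))
  writeLines(fmt(model$distortion), file.path(folder, "dist.out"))
  writeLines(apply(model$rectified_intrinsic, 1, fmt),
             file.path(folder, "newcameramtx.out"))
  roi <- model$roi
  if (is.null(roi)) roi <- c(0, 0, 0, 0)
  writeLines(fmt(roi), file.path(folder, "roi.out"))
  invisible(folder)
}

# Apply the Brown-Conrady forward distortion to ideal (undistorted)
# 0-based pixel coordinates, returning observed (distorted) coordinates.
# `xy` is an n x 2 matrix of (x, y).
distort_points <- function(xy, model) {
  K <- model$intrinsic
  Kn <- model$rectified_intrinsic
  d <- model$distortion
  x <- (xy[, 1] - Kn[1, 3]) / Kn[1, 1]
  y <- (xy[, 2] - Kn[2, 3]) / Kn[2, 2]
  r2 <- x * x + y * y
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x * x)
  yd <- y * radial + d[3] * (r2 + 2 * y * y) + 2 * d[4] * x * y
  cbind(xd * K[1, 1] + K[1, 3], yd * K[2, 2] + K[2, 3])
}

# Numerically invert the distortion (fixed-point iteration in normalized
# coordinates); maps observed coordinates back to ideal ones. Used by the
# synthetic renderer to forward-distort a clean frame.
undistort_points <- function(xy, model, iterations = 8L) {
  K <- model$intrinsic
  Kn <- model$rectified_intrinsic
  d <- model$distortion
  xd <- (xy[, 1] - K[1, 3]) / K[1, 1]
  yd <- (xy[, 2] - K[2, 3]) / K[2, 2]
  x <- xd; y <- yd
  for (i in seq_len(iterations)) {
    r2 <- x * x + y * y
    radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    dx <- 2 * d[3] * x * y + d[4] * (r2 + 2 * x * x)
    dy <- d[3] * (r2 + 2 * y * y) + 2 * d[4] * x * y
    x <- (xd - dx) / radial
    y <- (yd - dy) / radial
  }
  cbind(x * Kn[1, 1] + Kn[1, 3], y * Kn[2, 2] + Kn[2, 3])
}

#' Precompute the undistortion remap for a frame geometry
#'
#' For each output pixel the source position under the forward distortion
#' model is computed once; [undistort()] then only performs the bilinear
#' gather. Precomputing the map amortises the cost over the frames of a
#' video.
#'
#' @param model a [camera_model()].
#' @param width,height frame size in pixels.
#' @param origin 0-based (x, y) offset of the frame within the calibrated
#'   sensor, used when the frame was cropped before undistortion.
#' @return An opaque list consumed by [undistort()].
#' @export
undistort_map <- function(model, width, height, origin = c(0, 0)) {
  u <- rep(seq_len(width) - 1 + origin[1], each = height)
  v <- rep(seq_len(height) - 1 + origin[2], times = width)
  src <- distort_points(cbind(u, v), model)
  xs <- src[, 1] - origin[1]
  ys <- src[, 2] - origin[2]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  inside <- function(xq, yq) xq >= 0 & xq <= width - 1 & yq >= 0 & yq <= height - 1
  idx <- function(xq, yq, ok) ifelse(ok, yq + 1 + xq * height, 1L)
  ok00 <- inside(x0, y0); ok10 <- inside(x0 + 1, y0)
  ok01 <- inside(x0, y0 + 1); ok11 <- inside(x0 + 1, y0 + 1)
  list(width = width, height = height,
       # an exactly identity mapping lets undistort() skip the gather
       identity = max(abs(xs - (u - origin[1])), abs(ys - (v - origin[2]))) < 1e-9,
       i00 = idx(x0, y0, ok00), w00 = (1 - fx) * (1 - fy) * ok00,
       i10 = idx(x0 + 1, y0, ok10), w10 = fx * (1 - fy) * ok10,
       i01 = idx(x0, y0 + 1, ok01), w01 = (1 - fx) * fy * ok01,
       i11 = idx(x0 + 1, y0 + 1, ok11), w11 = fx * fy * ok11)
}

#' Undistort a frame
#'
#' Removes lens distortion by inverse mapping: every output pixel is
#' projected through the rectified matrix, distorted with the radial and
#' tangential Brown-Conrady model, re-projected through the intrinsic
#' matrix, and bilinearly sampled from the source frame. Pixels whose
#' source falls outside the frame are set to 0, which is safe on the
#' dark-field background.
#'
#' @param frame numeric matrix (rows = y, columns = x), 8-bit grayscale.
#' @param model a [camera_model()]; ignored when `map` is given.
#' @param map optional precomputed [undistort_map()].
#' @param crop_roi if `TRUE`, crop the result to the model's `roi`.
#' @return The undistorted frame, same type and (unless cropped) size.
#' @export
undistort <- function(frame, model, map = NULL, crop_roi = FALSE) {
  stopifnot_frame(frame)
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(map)) {
    map <- undistort_map(model, w, h)
  }
  if (map$width != w || map$height != h) {
    stop(sprintf("frame is %dx%d but the undistortion map is %dx%d",
                 w, h, map$width, map$height), call. = FALSE)
  }
  if (isTRUE(map$identity) && !(crop_roi && !is.null(model$roi))) {
    return(frame)
  }
  v <- as.numeric(frame)
  out <- v[map$i00] * map$w00 + v[map$i10] * map$w10 +
    v[map$i01] * map$w01 + v[map$i11] * map$w11
  out <- matrix(out, h, w)
  if (crop_roi && !is.null(model$roi)) {
    r <- round(model$roi)
    out <- out[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3]), drop = FALSE]
  }
  out
}

#' Pixel-to-millimetre scale factor
#'
#' The conversion factor is estimated once when the lens is fixed in the
#' instrument (by imaging an object of known size) and applied linearly to
#' every pixel measurement.
#'
#' @param mm_per_pixel millimetres per pixel, finite and strictly positive.
#' @return An object of class `scale_factor`.
#' @export
scale_factor <- function(mm_per_pixel) {
  mm_per_pixel <- as.numeric(mm_per_pixel)
  if (length(mm_per_pixel) != 1L || !is.finite(mm_per_pixel) ||
      mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a single finite positive number", call. = FALSE)
  }
  structure(list(mm_per_pixel = mm_per_pixel), class = "scale_factor")
}

#' Convert a pixel length to millimetres
#'
#' @param length_px non-negative length(s) in pixels.
#' @param scale a [scale_factor()] or a bare positive number (mm/px).
#' @return Length(s) in millimetres.
#' @export
px_to_mm <- function(length_px, scale) {
  if (!inherits(scale, "scale_factor")) scale <- scale_factor(scale)
  if (any(length_px < 0, na.rm = TRUE)) {
    stop("length_px must be non-negative", call. = FALSE)
  }
  length_px * scale$mm_per_pixel
}
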