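#' Laplacian-variance sharpness of a frame
#'
#' Focus measure used to reject out-of-focus frames: the population
#' variance of the 3x3 Laplacian response (kernel `[[0,1,0],[1,-4,1],
#' [0,1,0]]`, replicate-padded borders). In-focus dark-field frames score
#' well above the default acceptance threshold of 1.8; heavily defocused
#' frames collapse towards 0.
#'
#' @param frame grayscale numeric matrix (0..255).
#' @return Non-negative scalar.
#' @export
sharpness <- function(frame) {
  stopifnot_frame(frame)
  lap <- laplacian(frame)
  mean((lap - mean(lap))^2)
}

# 3x3 Laplacian with replicate padding, via shifted copies.
laplacian <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  up <- frame[c(1, seq_len(h - 1)), , drop = FALSE]
  down <- frame[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  left <- frame[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- frame[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  up + down + left + right - 4 * frame
}

#' Adaptive K-nearest-neighbour background model
#'
#' Sample-based background subtraction for the static dark-field scene:
#' each pixel keeps `n_samples` recent intensity samples; a pixel is
#' classified background when at least `k_required` stored samples lie
#' within `match_radius` (squared intensity difference, ties count as
#' matches) of the current value, otherwise foreground. After
#' classification each pixel's store is stochastically refreshed with the
#' current value at rate `1/history` per frame, so stationary objects are
#' eventually absorbed into the background. The model owns a seeded RNG
#' stream and is fully deterministic given `seed`.
#'
#' @param width,height frame geometry in pixels.
#' @param n_samples samples stored per pixel (default 10).
#' @param k_required matches needed to call background (default 3).
#' @param match_radius squared-intensity match threshold (default 400,
#'   i.e. 20 grey levels on an 8-bit scale).
#' @param history refresh horizon in frames (default 500).
#' @param warmup frames used to seed the store before output is trusted
#'   (default 10); during warmup the mask is all-background.
#' @param seed RNG seed for the stochastic sample refresh.
#' @return A mutable object of class `background_model`.
#' @seealso [bg_subtract()], [bg_prime()]
#' @export
background_model <- function(width, height, n_samples = 10L, k_required = 3L,
                             match_radius = 400, history = 500L,
                             warmup = 10L, seed = 1L) {
  stopifnot(width >= 1, height >= 1, n_samples >= k_required, k_required >= 1,
            match_radius >= 0, history >= 1, warmup >= 0)
  m <- new.env(parent = emptyenv())
  m$width <- as.integer(width); m$height <- as.integer(height)
  m$n <- as.integer(n_samples); m$k <- as.integer(k_required)
  m$radius <- match_radius; m$history <- history
  m$warmup <- as.integer(warmup); m$seed <- seed
  m$t <- 0L
  # per-pixel sample store, one column per sample slot
  m$samples <- matrix(0, nrow = height * width, ncol = n_samples)
  m$rng_state <- NULL
  class(m) <- "background_model"
  m
}

#' Classify a frame against the background model
#'
#' Returns the binary foreground mask (0 background, 255 foreground) and
#' advances the model state (warmup seeding, then stochastic refresh).
#' The model object is updated in place.
#'
#' @param model a [background_model()].
#' @param frame grayscale matrix matching the model geometry.
#' @return Binary mask matrix with values in `{0, 255}`.
#' @export
bg_subtract <- function(model, frame) {
  stopifnot_frame(frame)
  if (nrow(frame) != model$height || ncol(frame) != model$width) {
    stop(sprintf("frame is %dx%d but model expects %dx%d",
                 ncol(frame), nrow(frame), model$width, model$height),
         call. = FALSE)
  }
  model$t <- model$t + 1L
  fv <- as.numeric(frame)
  npix <- length(fv)
  if (model$t <= model$warmup) {
    if (model$t == 1L) {
      model$samples[] <- fv
    } else {
      slot <- ((model$t - 1L) %% model$n) + 1L
      model$samples[, slot] <- fv
    }
    return(matrix(0, model$height, model$width))
  }
  d <- model$samples - fv  # recycles fv down each sample column
  matches <- .rowSums((d * d <= model$radius) + 0L, npix, model$n)
  mask <- matrix((matches < model$k) * 255, model$height, model$width)
  # each pixel refreshes one stored sample with probability 1/history:
  # draw the refreshed-pixel count, then the pixels and slots
  with_stream(model, {
    k <- stats::rbinom(1L, npix, 1 / model$history)
    if (k > 0L) {
      idx <- sample.int(npix, k)
      slots <- sample.int(model$n, k, replace = TRUE)
      model$samples[idx + (slots - 1L) * npix] <- fv[idx]
    }
  })
  mask
}

#' Prime a background model from frames sampled across a clip
#'
#' Batch processing can see the whole clip before segmenting it, so the
#' per-pixel sample store is seeded with a robust background estimate: the
#' per-pixel minimum over frames spread evenly across the video. On a
#' dark-field scene the animal and drifting particles are strictly
#' brighter than the background, so the temporal minimum is the true
#' background wherever the animal moves at all - this avoids both the
#' start-position ghost a streaming warmup would leave and the poisoned
#' samples a frame-subsample store would keep where the swim path revisits
#' itself. After priming, the model reports real masks immediately.
#'
#' @param model a [background_model()].
#' @param frames list of grayscale frames (the whole clip or a subset);
#'   the per-pixel minimum of up to 15 evenly spread frames is used.
#' @return The model, invisibly.
#' @export
bg_prime <- function(model, frames) {
  stopifnot(length(frames) >= 1L)
  picks <- unique(round(seq(1, length(frames), length.out = min(15L, length(frames)))))
  background <- Reduce(pmin, frames[picks])
  for (i in seq_len(model$n)) {
    model$samples[, i] <- as.numeric(background)
  }
  model$t <- model$warmup
  invisible(model)
}

#' Rectangular structuring element
#'
#' @param size odd `(height, width)` of the rectangle (default 3x3).
#' @param iterations how many times the operator is applied (default 1).
#' @return An object of class `struct_el`.
#' @export
struct_el <- function(size = c(3L, 3L), iterations = 1L) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1L) || any(size %% 2L == 0L)) {
    stop("structuring element sides must be odd and >= 1", call. = FALSE)
  }
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  structure(list(size = size, iterations = as.integer(iterations)),
            class = "struct_el")
}

#' Binary erosion and dilation
#'
#' Standard set-definition morphology with a rectangular structuring
#' element; pixels outside the image are treated as background for both
#' operators, so foreground touching the border erodes. Erosion removes
#' particles and thin appendages (the Daphnia spine and antennae), and the
#' matching dilation restores the main body to its original extent.
#'
#' @param mask binary matrix with values in `{0, 255}`.
#' @param se a [struct_el()]; its `iterations` are applied sequentially.
#' @return Binary mask of the same size.
#' @export
erode <- function(mask, se = struct_el()) {
  stopifnot_mask(mask)
  morph(mask, se, erode = TRUE)
}

#' @rdname erode
#' @export
dilate <- function(mask, se = struct_el()) {
  stopifnot_mask(mask)
  morph(mask, se, erode = FALSE)
}

# k iterations of an r-radius rectangle are one application of a
# k*r-radius rectangle (Minkowski composition of rectangles), so the
# operator collapses to a single window pass.
morph <- function(mask, se, erode) {
  ry <- (se$size[1] - 1L) %/% 2L * se$iterations
  rx <- (se$size[2] - 1L) %/% 2L * se$iterations
  if (ry == 0L && rx == 0L) return(mask)
  counts <- box_count(mask > 0, ry, rx)
  full <- (2 * ry + 1) * (2 * rx + 1)
  if (erode) {
    # outside-image cells are background, so border windows (whose
    # clamped count can never reach the full window size) erode away
    (counts == full) * 255
  } else {
    (counts > 0) * 255
  }
}

# Number of TRUE cells in the (2ry+1) x (2rx+1) window around each pixel,
# windows clamped at the image border (outside contributes 0); via an
# integral image, O(npix) for any radius.
box_count <- function(fg, ry, rx) {
  h <- nrow(fg); w <- ncol(fg)
  cs <- colcumsum(fg + 0)
  cs <- t(colcumsum(t(cs)))
  I <- rbind(0, cbind(0, cs))
  y2 <- pmin(seq_len(h) + ry, h) + 1L
  y1 <- pmax(seq_len(h) - ry, 1L)
  x2 <- pmin(seq_len(w) + rx, w) + 1L
  x1 <- pmax(seq_len(w) - rx, 1L)
  I[y2, x2, drop = FALSE] - I[y1, x2, drop = FALSE] -
    I[y2, x1, drop = FALSE] + I[y1, x1, drop = FALSE]
}

# Column-wise cumulative sums without per-column dispatch: one cumsum
# over the full vector, then subtract each column's carried-in total.
colcumsum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(cumsum(m), h, w)
  if (w > 1L) cs <- cs - rep(c(0, cs[h, -w]), each = h)
  cs
}
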