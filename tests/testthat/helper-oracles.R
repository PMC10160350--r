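# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately re-derive results from first principles
# (definitions, exhaustive loops) rather than calling package internals.

# Linear-interpolation percentile straight from the order-statistics
# definition.
bf_percentile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  if (n == 1L) return(v)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= n) return(v[n])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

# Set-definition morphology with outside-image = background, per-pixel
# neighbourhood scan. Erosion of a window that reaches outside the image
# is 0 because the outside cells are background; dilation ignores them
# for the same reason.
bf_morph <- function(mask, ry, rx, erode) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      clipped <- y - ry < 1 || y + ry > h || x - rx < 1 || x + rx > w
      win <- mask[max(1, y - ry):min(h, y + ry),
                  max(1, x - rx):min(w, x + rx)]
      out[y, x] <- if (erode) {
        if (clipped) 0 else min(win)
      } else {
        max(win)
      }
    }
  }
  out
}

# 8-connected component count by iterative flood fill.
bf_component_count <- function(mask) {
  fg <- mask > 0
  h <- nrow(fg); w <- ncol(fg)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (start in which(fg)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      py <- ((p - 1L) %% h) + 1L
      px <- ((p - 1L) %/% h) + 1L
      for (dy in -1:1) {
        for (dx in -1:1) {
          yy <- py + dy; xx <- px + dx
          if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
              fg[yy, xx] && !seen[yy, xx]) {
            seen[yy, xx] <- TRUE
            stack <- c(stack, yy + (xx - 1L) * h)
          }
        }
      }
    }
  }
  count
}

# Reference KNN classification: per-pixel loop over the stored samples.
bf_knn_mask <- function(samples_list, frame, radius, k) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      hits <- sum(vapply(samples_list, function(s) {
        (frame[y, x] - s[y, x])^2 <= radius
      }, logical(1)))
      out[y, x] <- if (hits >= k) 0 else 255
    }
  }
  out
}

# Rasterize a filled rotated ellipse into a {0,255} mask.
make_ellipse_mask <- function(h, w, cx, cy, a, b, phi = 0) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  xr <- (X - cx) * cos(phi) + (Y - cy) * sin(phi)
  yr <- -(X - cx) * sin(phi) + (Y - cy) * cos(phi)
  ifelse((xr / a)^2 + (yr / b)^2 <= 1, 255, 0)
}

# Random blobby test mask made of a few discs.
random_blob_mask <- function(h, w, n_blobs, r_range = c(2, 5)) {
  m <- matrix(0, h, w)
  for (i in seq_len(n_blobs)) {
    r <- runif(1, r_range[1], r_range[2])
    cx <- runif(1, r + 1, w - r - 2)
    cy <- runif(1, r + 1, h - r - 2)
    m <- pmax(m, make_ellipse_mask(h, w, cx, cy, r, r))
  }
  m
}

# Small fast scene used by most pipeline-level tests.
quick_scene <- function(...) {
  args <- utils::modifyList(
    list(width = 240L, height = 200L, frames = 80L,
         a_px = 40, b_px = 28, n_particles = 5L, seed = 1L,
         appendage_length_px = 0),
    list(...))
  do.call(scene_config, args)
}

# Species profile matched to quick_scene-scale synthetic animals.
sim_profile <- function(percentile = 93) {
  species_profile("synthetic", min_area_px = 150, max_area_px = 60000,
                  min_lw_ratio = 1.2, max_lw_ratio = 1.7,
                  min_brightness = 30, optimal_percentile = percentile)
}
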