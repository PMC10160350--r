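#' Label connected foreground components
#'
#' 8-connected component labelling of a binary mask by breadth-first
#' search; components are numbered in deterministic scan order (top row
#' first, then left to right).
#'
#' @param mask binary matrix with values in `{0, 255}` (or logical).
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  fg <- mask > 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  cur <- 0L
  repeat {
    unl <- which(fg & lab == 0L)
    if (length(unl) == 0L) break
    rows <- ((unl - 1L) %% h) + 1L
    cols <- ((unl - 1L) %/% h) + 1L
    seed <- unl[order(rows, cols)[1L]]
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nr <- fr + offs[k, 1L]; nc <- fc + offs[k, 2L]
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        cand <- nr[ok] + (nc[ok] - 1L) * h
        cand <- cand[fg[cand] & lab[cand] == 0L]
        if (length(cand) > 0L) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Find external object contours in a binary mask
#'
#' Traces the outer boundary of every 8-connected foreground component
#' (Moore-neighbour tracing; holes are ignored) and returns one closed
#' polygon per component, vertices at 0-based pixel-centre coordinates, in
#' deterministic scan order. Each contour carries the component's pixel
#' indices and pixel count as attributes for downstream measurement.
#'
#' @param mask binary matrix with values in `{0, 255}`.
#' @return List of n x 2 matrices (columns `x`, `y`); possibly empty.
#' @export
find_contours <- function(mask) {
  stopifnot_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  fg_idx <- which(mask > 0)
  if (length(fg_idx) == 0L) return(list())
  # labelling and tracing only need the foreground bounding box
  ys <- ((fg_idx - 1L) %% h) + 1L
  xs <- ((fg_idx - 1L) %/% h) + 1L
  y0 <- min(ys); y1 <- max(ys); x0 <- min(xs); x1 <- max(xs)
  sub <- mask[y0:y1, x0:x1, drop = FALSE]
  lab <- label_components(sub, 8L)
  n <- max(lab)
  hs <- nrow(sub)
  out <- vector("list", n)
  for (id in seq_len(n)) {
    pix <- which(lab == id)
    poly <- trace_boundary(lab == id, hs, ncol(sub))
    poly[, 1] <- poly[, 1] + (x0 - 1L)
    poly[, 2] <- poly[, 2] + (y0 - 1L)
    # map sub-window pixel indices back to full-frame linear indices
    py <- ((pix - 1L) %% hs) + y0
    px <- ((pix - 1L) %/% hs) + x0
    full_pix <- py + (px - 1L) * h
    attr(poly, "pixels") <- full_pix
    attr(poly, "n_pixels") <- length(full_pix)
    attr(poly, "label") <- id
    out[[id]] <- poly
  }
  out
}

# Moore-neighbour boundary tracing, clockwise, starting at the
# topmost-leftmost pixel. Returns the closed polygon of boundary pixel
# centres (x, y), 0-based, without repeating the start vertex.
trace_boundary <- function(fg, h, w) {
  pix <- which(fg)
  rows <- ((pix - 1L) %% h) + 1L
  cols <- ((pix - 1L) %/% h) + 1L
  first <- order(rows, cols)[1L]
  sr <- rows[first]; sc <- cols[first]
  if (length(pix) == 1L) {
    return(cbind(x = sc - 1L, y = sr - 1L))
  }
  # clockwise directions in screen coordinates (y down), starting East
  dxs <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dys <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && fg[r, c]
  cr <- sr; cc <- sc
  bdir <- 5L  # direction from current pixel towards backtrack (West: index 5)
  xs <- integer(0); ys <- integer(0)
  start_state <- c(sr, sc, bdir)
  guard <- 4L * length(pix) + 8L
  repeat {
    xs <- c(xs, cc - 1L); ys <- c(ys, cr - 1L)
    found <- FALSE
    d <- bdir
    for (step in seq_len(8L)) {
      d <- (d %% 8L) + 1L
      nr <- cr + dys[d]; nc <- cc + dxs[d]
      if (at(nr, nc)) {
        # backtrack for the next pixel points at the last background cell,
        # i.e. the direction preceding d, seen from the new pixel
        prev <- ((d - 2L) %% 8L) + 1L
        pr <- cr + dys[prev]; pc <- cc + dxs[prev]
        ddx <- pc - nc; ddy <- pr - nr
        bdir <- which(dxs == ddx & dys == ddy)
        cr <- nr; cc <- nc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel reached via guard path
    if (cr == start_state[1] && cc == start_state[2] && bdir == start_state[3]) {
      break
    }
    guard <- guard - 1L
    if (guard <= 0L) break
  }
  cbind(x = xs, y = ys)
}

#' Signed-area (shoelace) contour area
#'
#' @param contour n x 2 matrix of polygon vertices.
#' @return Absolute enclosed area in square pixels.
#' @export
contour_area <- function(contour) {
  n <- nrow(contour)
  if (is.null(n) || n < 3L) return(0)
  x <- contour[, 1]; y <- contour[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Select the largest contour
#'
#' The animal is the largest object in the cleaned mask; candidates are
#' ranked by enclosed (shoelace) contour area, ties broken by scan order.
#'
#' @param contours list from [find_contours()].
#' @return The winning contour, or `NULL` for an empty list.
#' @export
select_largest <- function(contours) {
  if (length(contours) == 0L) return(NULL)
  areas <- vapply(contours, contour_area, numeric(1))
  contours[[which.max(areas)]]
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to an ellipse (Fitzgibbon's direct method in
#' the numerically stable Halir-Flusser formulation) to boundary points
#' and converts it to geometric parameters. The fitted major axis is the
#' animal's length, the minor axis its width.
#'
#' @param points n x 2 matrix of (x, y) boundary coordinates, n >= 5.
#' @return `NULL` when the points are degenerate (fewer than 5, collinear,
#'   or no elliptical solution); otherwise a list with `major_axis_px`,
#'   `minor_axis_px` (full axis lengths, major >= minor),
#'   `orientation_deg` (major-axis direction, degrees in `[0, 180)`) and
#'   `center` (x, y).
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) return(NULL)
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- max(stats::sd(points[, 1]), stats::sd(points[, 2]), 1e-9)
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc
  D1 <- cbind(x * x, x * y, y * y)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) return(NULL)
  a1 <- vecs[, ok[1L]]
  coef <- c(a1, as.numeric(T1 %*% a1))  # A B C D E F in scaled frame
  geom <- conic_to_geometric(coef)
  if (is.null(geom)) return(NULL)
  list(major_axis_px = geom$major * sc,
       minor_axis_px = geom$minor * sc,
       orientation_deg = geom$angle_deg,
       center = c(geom$cx * sc + mx, geom$cy * sc + my))
}

conic_to_geometric <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- 4 * A * C - B * B
  if (!is.finite(den) || den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- F + (D * cx + E * cy) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / ev$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(NULL)
  semi <- sqrt(ax2)
  imaj <- which.max(semi)
  vec <- ev$vectors[, imaj]
  ang <- atan2(vec[2], vec[1]) * 180 / pi
  ang <- ang %% 180
  list(major = 2 * semi[imaj], minor = 2 * semi[-imaj][1],
       angle_deg = ang, cx = cx, cy = cy)
}

# Subpixel boundary points of a component: midpoints between each
# foreground pixel centre and each 4-adjacent background (or
# outside-image) pixel centre, i.e. the 0.5-level crossings of the binary
# image. Fitting these removes the half-pixel shrink bias of fitting
# pixel centres.
subpixel_boundary <- function(pixels, h, w) {
  ys <- (pixels - 1L) %% h          # 0-based frame coords
  xs <- (pixels - 1L) %/% h
  y0 <- min(ys); x0 <- min(xs)
  hh <- max(ys) - y0 + 3L; ww <- max(xs) - x0 + 3L  # 1-px pad all round
  fg <- matrix(FALSE, hh, ww)
  fg[cbind(ys - y0 + 2L, xs - x0 + 2L)] <- TRUE
  pts <- NULL
  for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- shift_mat(fg, d[1], d[2], fill = FALSE)
    edge <- which(fg & !nb)
    if (length(edge) > 0L) {
      ex <- ((edge - 1L) %/% hh) - 1L + x0   # back to 0-based frame x
      ey <- ((edge - 1L) %% hh) - 1L + y0
      pts <- rbind(pts, cbind(ex - d[2] / 2, ey - d[1] / 2))
    }
  }
  pts
}

#' Measure the detected object
#'
#' Fits the ellipse to the object's subpixel boundary and collects every
#' quantity the species filter and the per-frame output need: axis
#' lengths, orientation, contour area, mean brightness inside the object
#' (measured on the undistorted grayscale frame, before background
#' subtraction), the frame's sharpness and the distance from the object
#' centre to the nearest cuvette-crop edge.
#'
#' @param contour a contour from [find_contours()] (with pixel attributes).
#' @param gray_frame the grayscale frame the mask was derived from.
#' @param crop_box `(x, y, width, height)` of the cuvette crop, 0-based, in
#'   the frame's own coordinates.
#' @param frame_index 0-based frame number carried into the measurement.
#' @param frame_sharpness the frame's [sharpness()] value.
#' @return `NULL` when the ellipse fit is degenerate; otherwise an
#'   `object_measurement` list.
#' @export
measure_object <- function(contour, gray_frame, crop_box,
                           frame_index = 0L, frame_sharpness = NA_real_) {
  pixels <- attr(contour, "pixels")
  if (is.null(pixels) || length(pixels) == 0L) return(NULL)
  h <- nrow(gray_frame); w <- ncol(gray_frame)
  pts <- subpixel_boundary(pixels, h, w)
  fit <- fit_ellipse(pts)
  if (is.null(fit)) return(NULL)
  cx <- fit$center[1]; cy <- fit$center[2]
  edge <- min(cx - crop_box[1], crop_box[1] + crop_box[3] - cx,
              cy - crop_box[2], crop_box[2] + crop_box[4] - cy)
  structure(list(
    frame_index = as.integer(frame_index),
    major_axis_px = fit$major_axis_px,
    minor_axis_px = fit$minor_axis_px,
    orientation_deg = fit$orientation_deg,
    area_px = contour_area(contour),
    brightness = mean(gray_frame[pixels]),
    sharpness = frame_sharpness,
    center_x = cx, center_y = cy,
    edge_distance_px = edge,
    fit = fit
  ), class = "object_measurement")
}

#' Species filter profile
#'
#' One row of the species table plus the global sharpness and
#' edge-distance thresholds: the acceptance window for per-frame
#' detections of that taxon, and the calibrated percentile used to turn
#' the per-video length distribution into one estimate.
#'
#' @param name species/genus label.
#' @param min_area_px,max_area_px contour-area window in square pixels.
#' @param min_lw_ratio,max_lw_ratio length-to-width (major/minor) window.
#' @param min_brightness minimum mean object brightness (0-255).
#' @param optimal_percentile calibrated percentile, integer in 50..100.
#' @param min_sharpness minimum frame sharpness (default 1.8).
#' @param min_edge_distance_px minimum centre-to-crop-edge distance
#'   (default 10 px).
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, min_area_px, max_area_px, min_lw_ratio,
                            max_lw_ratio, min_brightness, optimal_percentile,
                            min_sharpness = 1.8, min_edge_distance_px = 10) {
  stopifnot(min_area_px < max_area_px, min_lw_ratio >= 1,
            min_lw_ratio <= max_lw_ratio,
            optimal_percentile >= 50, optimal_percentile <= 100)
  structure(list(name = name, min_area_px = min_area_px,
                 max_area_px = max_area_px, min_lw_ratio = min_lw_ratio,
                 max_lw_ratio = max_lw_ratio, min_brightness = min_brightness,
                 min_sharpness = min_sharpness,
                 min_edge_distance_px = min_edge_distance_px,
                 optimal_percentile = as.integer(round(optimal_percentile))),
            class = "species_profile")
}

#' Load species profiles from a YAML file
#'
#' The package ships profiles for six zooplankton taxa in
#' `system.file("extdata", "species.yaml", package = "zoobooth")`; users
#' add new species by editing a copy of that file.
#'
#' @param path YAML file; defaults to the shipped table.
#' @return Named list of [species_profile()] objects.
#' @export
load_species_profiles <- function(path = system.file("extdata", "species.yaml",
                                                     package = "zoobooth")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    species_profile(
      name = nm,
      min_area_px = p$min_area_px, max_area_px = p$max_area_px,
      min_lw_ratio = p$min_lw_ratio, max_lw_ratio = p$max_lw_ratio,
      min_brightness = p$min_brightness,
      optimal_percentile = p$optimal_percentile,
      min_sharpness = if (is.null(p$min_sharpness)) 1.8 else p$min_sharpness,
      min_edge_distance_px = if (is.null(p$min_edge_distance_px)) 10
                             else p$min_edge_distance_px)
  })
  names(out) <- names(raw)
  out
}

#' Write an updated optimal percentile into a species YAML file
#'
#' Used after re-calibration on a new optical set-up: rewrites one
#' species' `optimal_percentile` in place, leaving the other entries
#' untouched.
#'
#' @param path a species YAML file (see [load_species_profiles()]).
#' @param species entry name to update.
#' @param optimal_percentile new integer percentile in 50..100.
#' @return `path`, invisibly.
#' @export
update_species_percentile <- function(path, species, optimal_percentile) {
  stopifnot(optimal_percentile >= 50, optimal_percentile <= 100)
  raw <- yaml::read_yaml(path)
  if (is.null(raw[[species]])) {
    stop("no species '", species, "' in ", path, call. = FALSE)
  }
  raw[[species]]$optimal_percentile <- as.integer(round(optimal_percentile))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Default species profile (Daphnia)
#'
#' Used whenever no species is chosen.
#'
#' @return A [species_profile()].
#' @export
default_species_profile <- function() {
  load_species_profiles()[["daphnia"]]
}

#' Test a measurement against the species criteria
#'
#' The five criteria are checked in a fixed order so the reject reason is
#' deterministic: (i) contour area within `[min_area_px, max_area_px]`,
#' (ii) length-to-width ratio within `[min_lw_ratio, max_lw_ratio]`,
#' (iii) brightness at least `min_brightness`, (iv) sharpness at least
#' `min_sharpness`, (v) centre at least `min_edge_distance_px` from the
#' crop edge. The first failed criterion is reported.
#'
#' @param m an `object_measurement` (or any list with the needed fields).
#' @param profile a [species_profile()].
#' @return List with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise one of `"area"`, `"lw_ratio"`, `"brightness"`,
#'   `"sharpness"`, `"edge"`).
#' @export
apply_species_filter <- function(m, profile) {
  reject <- function(reason) list(accept = FALSE, reason = reason)
  if (m$area_px < profile$min_area_px || m$area_px > profile$max_area_px) {
    return(reject("area"))
  }
  lw <- m$major_axis_px / m$minor_axis_px
  if (lw < profile$min_lw_ratio || lw > profile$max_lw_ratio) {
    return(reject("lw_ratio"))
  }
  if (m$brightness < profile$min_brightness) return(reject("brightness"))
  if (is.na(m$sharpness) || m$sharpness < profile$min_sharpness) {
    return(reject("sharpness"))
  }
  if (m$edge_distance_px < profile$min_edge_distance_px) {
    return(reject("edge"))
  }
  list(accept = TRUE, reason = NA_character_)
}
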