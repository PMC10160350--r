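#' Read a video as a list of 8-bit grayscale frames
#'
#' The package's native video containers are lossless: a multi-page TIFF
#' stack (one page per frame) or a directory of PNG frames sorted by name.
#' Compressed recordings (h264/MP4) should be transcoded to one of these
#' once, outside the analysis, e.g. with ffmpeg. Colour frames are
#' converted to luminance with weights 0.299 R + 0.587 G + 0.114 B,
#' rounded to the nearest integer.
#'
#' @param path a `.tif`/`.tiff` frame stack or a directory of `.png` frames.
#' @return A list of integer matrices (rows = y, columns = x) in 0..255,
#'   in presentation order.
#' @export
read_video <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) {
      stop("empty video: no .png frames in ", path, call. = FALSE)
    }
    return(lapply(files, function(f) to_gray8(png::readPNG(f))))
  }
  if (!file.exists(path)) {
    stop("cannot read video: no such file ", path, call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot decode ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty video: ", path, call. = FALSE)
  lapply(pages, to_gray8)
}

#' Convert a decoded image array to 8-bit grayscale
#'
#' @param img numeric matrix or array in `[0, 1]` (as returned by the PNG
#'   and TIFF readers) or already in 0..255.
#' @return Integer matrix in 0..255.
#' @export
to_gray8 <- function(img) {
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img <- as.matrix(img)
  if (max(img) <= 1) img <- img * 255
  m <- round(img)
  storage.mode(m) <- "integer"
  m
}

#' Write frames as a lossless multi-page TIFF stack
#'
#' @param frames list of numeric matrices in 0..255.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) > 0L)
  pages <- lapply(frames, function(f) clip255(round(f)) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Parse identifying metadata from a video filename
#'
#' The recording script embeds the sample identifiers (individual ID,
#' treatment, age, ...) into the filename as underscore-separated tokens;
#' they travel with every measurement row as the data identifier.
#'
#' @param path video path or bare filename.
#' @return A list of class `video_meta` with `path`, `name` (the stem) and
#'   `tokens` (character vector, in order).
#' @export
parse_filename <- function(path) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) tokens <- stem
  structure(list(path = path, name = stem, tokens = tokens),
            class = "video_meta")
}

#' Build a filename stem from identifier tokens
#'
#' Inverse of [parse_filename()] for token vectors free of underscores.
#'
#' @param tokens character vector of identifiers.
#' @param ext optional extension (without dot).
#' @return A filename string.
#' @export
build_filename <- function(tokens, ext = NULL) {
  stopifnot(all(nzchar(tokens)), !any(grepl("_", tokens, fixed = TRUE)))
  stem <- paste(tokens, collapse = "_")
  if (is.null(ext)) stem else paste0(stem, ".", ext)
}

.detailed_cols <- c("video_name", "frame_index", "length_px", "width_px",
                    "length_mm", "width_mm", "area_px", "brightness",
                    "sharpness", "center_x", "center_y")
.summary_cols <- c("video_name", "species", "percentile_used", "length_mm",
                   "n_frames")

empty_detailed <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(.detailed_cols)),
                               .detailed_cols))
  df$video_name <- character(0)
  df
}

#' Write per-frame measurement rows (`*.detailedsizedata.csv`)
#'
#' One row per accepted video frame: the fitted ellipse axes in pixels and
#' millimetres, contour area, mean object brightness, frame sharpness and
#' object centre. Comma-separated, `.` decimal separator, header line,
#' append-safe across a batch run.
#'
#' @param rows data.frame with the detailed columns.
#' @param path output CSV path.
#' @param append append without a header if `path` already exists.
#' @return `path`, invisibly.
#' @export
write_detailed <- function(rows, path, append = FALSE) {
  write_rows(rows, .detailed_cols, path, append)
}

#' Write per-video summary rows (`*sizedata.csv`)
#'
#' One row per video: the species profile used, the calibrated percentile,
#' the resulting length estimate and the number of accepted frames that
#' supports it.
#'
#' @inheritParams write_detailed
#' @export
write_summary <- function(rows, path, append = FALSE) {
  cols <- .summary_cols
  if ("width_mm" %in% names(rows)) {
    cols <- append(cols, "width_mm", after = which(cols == "length_mm"))
  }
  if ("low_support" %in% names(rows)) cols <- c(cols, "low_support")
  write_rows(rows, cols, path, append)
}

write_rows <- function(rows, cols, path, append) {
  rows <- as.data.frame(rows)
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0L && nrow(rows) > 0L) {
    stop("rows are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  do_append <- append && file.exists(path)
  utils::write.table(rows[, cols, drop = FALSE], path, sep = ",",
                     row.names = FALSE, col.names = !do_append,
                     append = do_append, quote = FALSE)
  invisible(path)
}

#' Read back a result CSV
#'
#' @param path CSV written by [write_detailed()] or [write_summary()].
#' @return A data.frame.
#' @export
read_sizedata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save diagnostic snapshots of the first accepted frames
#'
#' The first (at most) 19 measurement-accepted frames of a video are saved
#' as PNG files, optionally with the fitted ellipse drawn as a 1-pixel
#' outline, so the automated estimates can be validated by manual
#' measurement of the very frames the analysis used.
#'
#' @param frames list of grayscale frames (0..255), accepted frames in order.
#' @param ellipses list of ellipse fits (as from [fit_ellipse()]) parallel
#'   to `frames`, or `NULL` entries to skip annotation.
#' @param out_dir output directory (created if absent).
#' @param video_name stem used in the snapshot filenames.
#' @param limit maximum number of snapshots (default 19).
#' @param annotate draw the ellipse outline (default `TRUE`).
#' @return Character vector of written paths, invisibly.
#' @export
save_snapshots <- function(frames, ellipses = NULL, out_dir, video_name,
                           limit = 19L, annotate = TRUE) {
  n <- min(length(frames), limit)
  if (n == 0L) return(invisible(character(0)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- clip255(round(frames[[i]]))
    fi <- attr(frames[[i]], "frame_index")
    if (is.null(fi)) fi <- i - 1L
    if (annotate && !is.null(ellipses) && !is.null(ellipses[[i]])) {
      img <- draw_ellipse(img, ellipses[[i]], value = 255)
    }
    paths[i] <- file.path(out_dir, sprintf("%s_f%04d.png", video_name, fi))
    png::writePNG(img / 255, paths[i])
  }
  invisible(paths)
}

# Draw a 1-px ellipse outline into a frame (used for snapshot annotation).
draw_ellipse <- function(frame, fit, value = 255) {
  h <- nrow(frame); w <- ncol(frame)
  a <- fit$major_axis_px / 2; b <- fit$minor_axis_px / 2
  phi <- fit$orientation_deg * pi / 180
  t <- seq(0, 2 * pi, length.out = max(64L, ceiling(2 * pi * a)))
  x <- fit$center[1] + a * cos(t) * cos(phi) - b * sin(t) * sin(phi)
  y <- fit$center[2] + a * cos(t) * sin(phi) + b * sin(t) * cos(phi)
  xi <- round(x) + 1L; yi <- round(y) + 1L
  ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
  frame[cbind(yi[ok], xi[ok])] <- value
  frame
}
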