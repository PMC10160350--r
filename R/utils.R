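# Internal helpers shared across modules.

# Run `expr` with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Run `expr` with the RNG stream stored in environment `env` (field
# `rng_state`), capturing the advanced state back into `env`. Gives
# stateful objects (the background model) their own reproducible stream.
with_stream <- function(env, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  if (is.null(env$rng_state)) {
    set.seed(as.integer(env$seed %% .Machine$integer.max))
  } else {
    assign(".Random.seed", env$rng_state, envir = globalenv())
  }
  res <- force(expr)
  env$rng_state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}

stopifnot_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L) {
    stop("expected a non-empty numeric matrix frame", call. = FALSE)
  }
}

stopifnot_mask <- function(mask) {
  stopifnot_frame(mask)
  if (any(mask != 0 & mask != 255)) {
    stop("mask must be binary with values in {0, 255}", call. = FALSE)
  }
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by (dy, dx), padding vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0) {
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  }
  out
}
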