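# Shared internal helpers.

# Round half away from zero at the 8-bit boundary. Pixel intensities are
# non-negative, but keep the general form so intermediate signed values are
# handled identically on every platform (base round() is banker's rounding).
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Quantize a real-valued intensity array back to 8-bit storage.
quantize8 <- function(x) {
  a <- round_half_away(clip255(x))
  storage.mode(a) <- "integer"
  a
}

# Evaluate expr with the global RNG stream swapped for a private one, so the
# package never disturbs (nor is disturbed by) the caller's random state.
# `state` may be a saved .Random.seed vector or a single integer seed.
with_private_rng <- function(state, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  if (length(state) > 1L) assign(".Random.seed", state, envir = globalenv())
  else set.seed(state)
  res <- force(expr)
  attr(res, "rng_state") <- get(".Random.seed", envir = globalenv())
  res
}

stop_pv <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "pulseveil_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == trunc(x)

frame_dims <- function(frame) {
  d <- dim(frame)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_pv("a frame must be an H x W x 3 array", class = "dimension_error")
  d
}

check_frame <- function(frame) {
  d <- frame_dims(frame)
  if (d[1] < 1L || d[2] < 1L)
    stop_pv("frame must have positive dimensions", class = "dimension_error")
  if (any(frame < 0 | frame > 255))
    stop_pv("frame intensities must lie in [0, 255]", class = "range_error")
  invisible(d)
}
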