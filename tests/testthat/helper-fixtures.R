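# Shared fixtures, built in code at test time.

# Deterministic random 8-bit frame.
random_frame <- function(m, n, seed = 1) {
  set.seed(seed)
  array(sample.int(256L, m * n * 3L, replace = TRUE) - 1L, dim = c(m, n, 3L))
}

uniform_frame <- function(m, n, value = 128L) {
  array(as.integer(value), dim = c(m, n, 3L))
}

random_video <- function(m, n, frames, rate = 25, seed = 1) {
  set.seed(seed)
  video_sequence(lapply(seq_len(frames), function(i)
    array(sample.int(256L, m * n * 3L, replace = TRUE) - 1L,
          dim = c(m, n, 3L))), rate)
}

# A square landmark set (face = square, no exclusions populated).
square_landmarks <- function(x0, y0, side) {
  pts <- rbind(c(x0, y0), c(x0 + side, y0),
               c(x0 + side, y0 + side), c(x0, y0 + side))
  landmark_set(pts, list(outer_face = 1:4, left_eye = integer(0),
                         right_eye = integer(0), mouth = integer(0)))
}

# Brute-force point-in-polygon oracle: even-odd ray crossing plus an
# explicit on-segment test, algorithmically independent of the package's
# half-plane rasterizer.
oracle_point_in_poly <- function(px, py, poly, eps = 1e-9) {
  v <- nrow(poly)
  on_edge <- FALSE
  crossings <- 0L
  for (e in seq_len(v)) {
    a <- poly[e, ]; b <- poly[if (e == v) 1L else e + 1L, ]
    # on-segment check
    d <- b - a
    len2 <- sum(d^2)
    if (len2 > 0) {
      t <- ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / len2
      t <- min(max(t, 0), 1)
      if ((px - (a[1] + t * d[1]))^2 + (py - (a[2] + t * d[2]))^2 < eps^2)
        on_edge <- TRUE
    }
    # ray casting to the right
    if ((a[2] > py) != (b[2] > py)) {
      xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (px < xint) crossings <- crossings + 1L
    }
  }
  on_edge || (crossings %% 2L == 1L)
}

oracle_rasterize <- function(poly, shape) {
  out <- matrix(0L, shape[1], shape[2])
  for (y in seq_len(shape[1])) for (x in seq_len(shape[2]))
    out[y, x] <- as.integer(oracle_point_in_poly(x - 0.5, y - 0.5, poly))
  out
}

# Small scenes are reused across files; memoize by config signature.
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(...) {
  cfg <- scene_config(...)
  key <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- render_scene(cfg)
  .scene_cache[[key]]
}

# Closed-form moving-average amplitude gain at frequency fr (Hz) for a
# w-frame window at rate r.
moving_average_gain <- function(fr, w, r) {
  abs(sin(pi * fr * w / r)) / (w * abs(sin(pi * fr / r)))
}

# Least-squares amplitude of a sinusoid of known frequency in x.
fitted_amplitude <- function(x, fr, rate) {
  t <- (seq_along(x) - 1) / rate
  fit <- lm.fit(cbind(1, sin(2 * pi * fr * t), cos(2 * pi * fr * t)), x)
  sqrt(sum(fit$coefficients[2:3]^2))
}
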