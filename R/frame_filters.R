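FILTER_METHODS <- c("MB", "GB", "BB", "TA-C", "TA-S",
                    "AGN", "AGN-L", "SPN", "PoN", "PeN", "SN", "NE")
NOISE_METHODS <- c("AGN", "AGN-L", "SPN", "PoN", "PeN", "SN")

#' Configure a frame-modification operator
#'
#' One configuration object drives all twelve pipeline methods: the three
#' blurs (`MB` median, `GB` Gaussian, `BB` bilateral), the two temporal
#' averages (`TA-C` cumulative, `TA-S` sliding window), the six noise
#' injections (`AGN` additive Gaussian, `AGN-L` additive Gaussian with
#' local variance, `SPN` salt-and-pepper, `PoN` Poisson, `PeN` pepper,
#' `SN` speckle), and the `NE` no-editing baseline.
#'
#' Defaults follow the study conditions: kernel size 5 for `MB`/`GB`,
#' `sigma_space = sigma_range = 75` for `BB`, a 20-frame sliding window for
#' `TA-S`, and conventional toolkit noise parameters on the unit intensity
#' scale (Gaussian variance 0.01, impulse amount 0.05 with salt ratio 0.5,
#' Poisson scale 256).
#'
#' @param method one of `"MB"`, `"GB"`, `"BB"`, `"TA-C"`, `"TA-S"`,
#'   `"AGN"`, `"AGN-L"`, `"SPN"`, `"PoN"`, `"PeN"`, `"SN"`, `"NE"`.
#' @param kernel_size odd blur aperture in pixels (`MB`, `GB`).
#' @param sigma_space spatial Gaussian width for `BB` (pixels).
#' @param sigma_range range Gaussian width for `BB` (8-bit counts).
#' @param bilateral_diameter odd neighborhood diameter for `BB` (pixels).
#' @param window_frames sliding-window length `f` in frames (`TA-S`).
#' @param noise_params list with elements `var` (Gaussian/speckle variance,
#'   unit scale), `amount` (impulse fraction in `[0,1]`), `salt_ratio`
#'   (salt fraction of impulses), `poisson_scale` (photon count at full
#'   intensity).
#' @param seed integer seed for the stochastic methods.
#' @return An object of class `filter_config`.
#' @examples
#' filter_config("TA-S", window_frames = 20)
#' filter_config("AGN", seed = 7)
#' @export
filter_config <- function(method,
                          kernel_size = 5L,
                          sigma_space = 75,
                          sigma_range = 75,
                          bilateral_diameter = 9L,
                          window_frames = 20L,
                          noise_params = list(),
                          seed = 1L) {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% FILTER_METHODS))
    stop_pv("unknown method '%s'", as.character(method)[1],
            class = "config_error")
  if (!is_count(kernel_size) || kernel_size %% 2 == 0)
    stop_pv("kernel_size must be an odd positive integer",
            class = "config_error")
  if (!is_count(bilateral_diameter) || bilateral_diameter %% 2 == 0)
    stop_pv("bilateral_diameter must be an odd positive integer",
            class = "config_error")
  if (!is.numeric(sigma_space) || sigma_space <= 0 ||
      !is.numeric(sigma_range) || sigma_range <= 0)
    stop_pv("sigma_space and sigma_range must be positive",
            class = "config_error")
  if (!is_count(window_frames))
    stop_pv("window_frames must be a positive integer",
            class = "config_error")
  np <- utils::modifyList(list(var = 0.01, amount = 0.05, salt_ratio = 0.5,
                               poisson_scale = 256), noise_params)
  if (np$var < 0)
    stop_pv("noise variance must be non-negative", class = "config_error")
  if (np$amount < 0 || np$amount > 1)
    stop_pv("noise amount must lie in [0, 1]", class = "config_error")
  if (np$salt_ratio < 0 || np$salt_ratio > 1)
    stop_pv("salt_ratio must lie in [0, 1]", class = "config_error")
  structure(list(method = method,
                 kernel_size = as.integer(kernel_size),
                 sigma_space = sigma_space, sigma_range = sigma_range,
                 bilateral_diameter = as.integer(bilateral_diameter),
                 window_frames = as.integer(window_frames),
                 noise_params = np, seed = as.integer(seed)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  extra <- switch(x$method,
    MB = , GB = sprintf("k=%d", x$kernel_size),
    BB = sprintf("d=%d sigma_s=%g sigma_r=%g", x$bilateral_diameter,
                 x$sigma_space, x$sigma_range),
    `TA-S` = sprintf("f=%d", x$window_frames),
    AGN = , `AGN-L` = , SN = sprintf("var=%g seed=%d", x$noise_params$var, x$seed),
    SPN = , PeN = sprintf("amount=%g seed=%d", x$noise_params$amount, x$seed),
    PoN = sprintf("scale=%g seed=%d", x$noise_params$poisson_scale, x$seed),
    "")
  cat(sprintf("<filter_config> %s %s\n", x$method, extra))
  invisible(x)
}

#' Initialize per-video filter state
#'
#' The temporal-averaging operators and the noise generators carry state
#' across frames: the running pixel sum (`TA-C`), the ring buffer of the
#' last `f` frames (`TA-S`), the 0-based count `t` of frames seen, and the
#' random-generator state for the stochastic methods.
#'
#' @param cfg a [filter_config()].
#' @return An object of class `filter_state`.
#' @export
filter_state_init <- function(cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  structure(list(t = 0L, shape = NULL, running_sum = NULL,
                 ring = list(), ring_sum = NULL, rng_state = NULL),
            class = "filter_state")
}

mask3 <- function(mask, d) {
  if (!all(dim(mask$mask) == d[1:2]))
    stop_pv("mask shape %dx%d does not match frame %dx%d",
            nrow(mask$mask), ncol(mask$mask), d[1], d[2],
            class = "dimension_error")
  array(mask$mask == 1L, dim = d)
}

#' Overlay a modified region onto the original frame
#'
#' Bit-exact pixel selection: output takes the modified value where the
#' mask is 1 and the original value elsewhere.
#'
#' @param original,modified `H x W x 3` frames of equal shape.
#' @param mask an `roi_mask` aligned to the frames.
#' @return The composited frame.
#' @export
overlay_roi <- function(original, modified, mask) {
  d <- frame_dims(original)
  if (!all(dim(modified) == d))
    stop_pv("original and modified frames differ in shape",
            class = "dimension_error")
  sel <- mask3(mask, d)
  out <- original
  out[sel] <- modified[sel]
  out
}

blur_full_frame <- function(frame, cfg) {
  d <- frame_dims(frame)
  out <- array(0L, dim = d)
  for (ch in 1:3) {
    x <- frame[, , ch] * 1.0
    y <- switch(cfg$method,
      MB = median_filter_cpp(x, cfg$kernel_size),
      GB = {
        k <- cfg$kernel_size
        sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
        off <- seq_len(k) - (k + 1) / 2
        g <- exp(-off^2 / (2 * sigma^2))
        sep_conv_cpp(x, g / sum(g))
      },
      BB = bilateral_filter_cpp(x, cfg$bilateral_diameter,
                                cfg$sigma_space, cfg$sigma_range))
    out[, , ch] <- quantize8(y)
  }
  out
}

#' Median blur inside an ROI
#'
#' Each in-mask pixel is replaced by the per-channel median of its
#' `k x k` neighborhood (reflect-101 borders). The blur is computed on the
#' full frame and composited by [overlay_roi()], so pixels outside the
#' mask are bit-identical to the input.
#'
#' @param frame `H x W x 3` frame.
#' @param mask an `roi_mask`.
#' @param cfg a [filter_config()] with odd `kernel_size`.
#' @return The modified frame.
#' @export
median_blur <- function(frame, mask, cfg) {
  cfg$method <- "MB"
  overlay_roi(frame, blur_full_frame(frame, cfg), mask)
}

#' Gaussian blur inside an ROI
#'
#' Per-channel convolution with a normalized `k x k` Gaussian kernel whose
#' width follows the standard aperture rule
#' `sigma = 0.3 * ((k - 1)/2 - 1) + 0.8`. Borders use reflect-101 padding;
#' out-of-mask pixels are untouched.
#'
#' @inheritParams median_blur
#' @return The modified frame.
#' @export
gaussian_blur <- function(frame, mask, cfg) {
  cfg$method <- "GB"
  overlay_roi(frame, blur_full_frame(frame, cfg), mask)
}

#' Bilateral blur inside an ROI
#'
#' Edge-preserving smoothing: each in-mask pixel becomes the normalized
#' product-of-Gaussians (spatial x intensity range) weighted average of its
#' neighborhood, so strong edges survive while low-amplitude variation —
#' including the pulse signal — is smoothed away.
#'
#' @inheritParams median_blur
#' @return The modified frame.
#' @export
bilateral_blur <- function(frame, mask, cfg) {
  cfg$method <- "BB"
  overlay_roi(frame, blur_full_frame(frame, cfg), mask)
}

check_state_shape <- function(state, d) {
  if (is.null(state$shape)) state$shape <- d
  else if (!all(state$shape == d))
    stop_pv("frame shape changed mid-video (%dx%d -> %dx%d)",
            state$shape[1], state$shape[2], d[1], d[2], class = "state_error")
  state
}

#' Cumulative temporal-averaging step
#'
#' In-mask pixels of frame `t` are replaced by the rounded per-pixel mean
#' over all frames seen so far (frames `0..t` inclusive). Call once per
#' frame in temporal order; the running sum lives in the state object.
#'
#' @param frame `H x W x 3` frame.
#' @param mask an `roi_mask`.
#' @param state a [filter_state_init()] state, threaded through the video.
#' @return `list(frame = <modified frame>, state = <updated state>)`.
#' @export
ta_cumulative_step <- function(frame, mask, state) {
  d <- frame_dims(frame)
  state <- check_state_shape(state, d)
  if (is.null(state$running_sum)) state$running_sum <- array(0, dim = d)
  state$running_sum <- state$running_sum + frame
  state$t <- state$t + 1L
  avg <- quantize8(state$running_sum / state$t)
  list(frame = overlay_roi(frame, avg, mask), state = state)
}

#' Sliding-window temporal-averaging step
#'
#' In-mask pixels are replaced by the rounded per-pixel mean over the most
#' recent `min(t + 1, f)` frames (the current frame and up to `f - 1`
#' predecessors). During warm-up, before `f` frames have been seen, the
#' mean runs over the frames available, so output is defined from frame 0.
#'
#' @inheritParams ta_cumulative_step
#' @param cfg a [filter_config()] supplying the window length `f`.
#' @return `list(frame = <modified frame>, state = <updated state>)`.
#' @export
ta_sliding_step <- function(frame, mask, state, cfg) {
  f <- cfg$window_frames
  d <- frame_dims(frame)
  state <- check_state_shape(state, d)
  if (is.null(state$ring_sum)) state$ring_sum <- array(0, dim = d)
  state$ring[[length(state$ring) + 1L]] <- frame
  state$ring_sum <- state$ring_sum + frame
  if (length(state$ring) > f) {
    state$ring_sum <- state$ring_sum - state$ring[[1L]]
    state$ring[[1L]] <- NULL
  }
  state$t <- state$t + 1L
  avg <- quantize8(state$ring_sum / length(state$ring))
  list(frame = overlay_roi(frame, avg, mask), state = state)
}

# 3x3 local sample variance (unit scale) with reflect-101 borders,
# floored to avoid zero-variance degeneracy.
local_variance3 <- function(u, floor_var = 1e-6) {
  box <- c(1, 1, 1) / 3
  m1 <- sep_conv_cpp(u, box)
  m2 <- sep_conv_cpp(u * u, box)
  pmax((m2 - m1 * m1) * 9 / 8, floor_var)
}

#' Inject noise inside an ROI
#'
#' All six noise methods operate on the unit-scaled copy `u = pixels / 255`
#' of the in-mask pixels (each channel element independently), then clip to
#' `[0, 1]`, rescale, and round back to 8-bit:
#'
#' * `AGN` — `u + N(0, var)`;
#' * `AGN-L` — `u + N(0, v(x, y))`, with `v` the 3x3 local sample variance
#'   of the channel, floored at `1e-6`;
#' * `SPN` — a fraction `amount` of elements is set to 0 or 1
#'   (salt with probability `salt_ratio`);
#' * `PoN` — `Poisson(u * L) / L` photon-count resampling with `L`
#'   the `poisson_scale`;
#' * `PeN` — a fraction `amount` of elements is set to 0;
#' * `SN` — multiplicative speckle `u + u * N(0, var)`.
#'
#' The generator state is carried in `state`, so a fixed `cfg$seed` makes
#' whole-video runs reproducible, and the caller's global RNG stream is
#' left untouched.
#'
#' @inheritParams ta_cumulative_step
#' @param cfg a [filter_config()] with a noise method and a seed.
#' @return `list(frame = <modified frame>, state = <updated state>)`.
#' @export
add_noise <- function(frame, mask, cfg, state) {
  if (!(cfg$method %in% NOISE_METHODS))
    stop_pv("'%s' is not a noise method", cfg$method, class = "config_error")
  d <- frame_dims(frame)
  state <- check_state_shape(state, d)
  sel <- mask3(mask, d)
  u <- frame[sel] / 255
  np <- cfg$noise_params
  res <- with_private_rng(if (is.null(state$rng_state)) cfg$seed else state$rng_state, {
    switch(cfg$method,
      AGN = u + rnorm(length(u), 0, sqrt(np$var)),
      `AGN-L` = {
        vmap <- array(0, dim = d)
        for (ch in 1:3) vmap[, , ch] <- local_variance3(frame[, , ch] / 255)
        u + rnorm(length(u), 0, sqrt(vmap[sel]))
      },
      SPN = {
        flip <- runif(length(u)) < np$amount
        salt <- runif(length(u)) < np$salt_ratio
        u[flip & salt] <- 1
        u[flip & !salt] <- 0
        u
      },
      PoN = rpois(length(u), u * np$poisson_scale) / np$poisson_scale,
      PeN = {
        flip <- runif(length(u)) < np$amount
        u[flip] <- 0
        u
      },
      SN = u + u * rnorm(length(u), 0, sqrt(np$var)))
  })
  state$rng_state <- attr(res, "rng_state")
  attr(res, "rng_state") <- NULL
  state$t <- state$t + 1L
  out <- frame
  out[sel] <- quantize8(clip01(res) * 255)
  list(frame = out, state = state)
}

# One frame through mask -> operator -> overlay. Returns list(frame, state).
apply_filter_step <- function(frame, mask, cfg, state) {
  switch(cfg$method,
    NE = list(frame = frame, state = state),
    MB = list(frame = median_blur(frame, mask, cfg), state = state),
    GB = list(frame = gaussian_blur(frame, mask, cfg), state = state),
    BB = list(frame = bilateral_blur(frame, mask, cfg), state = state),
    `TA-C` = ta_cumulative_step(frame, mask, state),
    `TA-S` = ta_sliding_step(frame, mask, state, cfg),
    add_noise(frame, mask, cfg, state))
}

#' Modify a whole video inside a region of interest
#'
#' Runs the three-step concealment pipeline frame by frame: build the ROI
#' mask (from per-frame landmarks unless `roi_kind = "full_frame"`), apply
#' the configured operator, and overlay the modified region onto the
#' original frame. Stateful operators (temporal averaging, noise) carry
#' their state across frames in order. `NE` returns the input
#' bit-identically.
#'
#' @param video a [video_sequence()].
#' @param roi_kind `"full_frame"`, `"facial_skin"` or `"forehead_cheeks"`.
#' @param cfg a [filter_config()].
#' @param provider landmark provider `function(frame, index)`; required
#'   unless `roi_kind = "full_frame"`.
#' @return The modified [video_sequence()] (same frame count and rate).
#' @examples
#' sc <- render_scene(scene_config(duration = 1, width = 32, height = 32))
#' out <- modify_video(sc$video, "facial_skin", filter_config("MB"),
#'                     provider = scene_landmark_provider(sc))
#' @export
modify_video <- function(video, roi_kind = "facial_skin", cfg,
                         provider = NULL) {
  stopifnot(inherits(video, "video_sequence"), inherits(cfg, "filter_config"))
  if (cfg$method == "NE") return(video)
  if (roi_kind != "full_frame" && !is.function(provider))
    stop_pv("roi_kind '%s' needs a landmark provider", roi_kind,
            class = "config_error")
  state <- filter_state_init(cfg)
  out <- vector("list", length(video$frames))
  mask <- NULL
  prev_lm <- NULL
  for (i in seq_along(video$frames)) {
    frame <- video$frames[[i]]
    if (roi_kind == "full_frame") {
      if (is.null(mask)) mask <- full_frame_mask(frame)
    } else {
      lm <- detect_landmarks(frame, provider, index = i - 1L)
      if (is.null(mask) || !identical(lm, prev_lm)) {
        mask <- make_roi_mask(roi_kind, frame, lm)
        prev_lm <- lm
      }
    }
    step <- tryCatch(apply_filter_step(frame, mask, cfg, state),
                     error = function(e)
                       stop_pv("frame %d: %s", i - 1L, conditionMessage(e),
                               class = "filter_error"))
    out[[i]] <- step$frame
    state <- step$state
  }
  video_sequence(out, video$frame_rate)
}
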