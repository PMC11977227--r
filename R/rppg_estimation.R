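BVP_METHODS <- c("GREEN", "ICA", "CHROM", "POS", "LGI")

#' Construct an RGB trace
#'
#' Per-frame mean red/green/blue intensities (8-bit counts) sampled from
#' skin patches, at the video frame rate. This is the raw time series every
#' blood-volume-pulse algorithm starts from.
#'
#' @param r,g,b equal-length numeric vectors.
#' @param rate sampling rate in Hz (the video frame rate).
#' @return An object of class `rgb_trace`.
#' @export
rgb_trace <- function(r, g, b, rate) {
  n <- length(r)
  if (n < 1L || length(g) != n || length(b) != n)
    stop_pv("r, g, b must be equal-length, non-empty", class = "config_error")
  if (!is.numeric(rate) || rate <= 0)
    stop_pv("rate must be positive", class = "config_error")
  structure(list(r = as.numeric(r), g = as.numeric(g), b = as.numeric(b),
                 rate = as.numeric(rate)), class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d samples at %g Hz\n", length(x$r), x$rate))
  invisible(x)
}

#' Sample a skin RGB trace from a video
#'
#' For each frame, square patches (side `patch_size`) are centered on up to
#' `n_points` equispaced landmarks drawn from the forehead, cheek and nose
#' groups — the skin regions most strongly modulated by blood volume — and
#' each colour channel is averaged over the union of patch pixels. Patches
#' are clipped to the frame; a patch that clips to nothing is an error.
#'
#' @param video a [video_sequence()].
#' @param landmarks either a list with one [landmark_set()] per frame, or
#'   a provider `function(frame, index)`.
#' @param n_points maximum number of sampling points (default 100).
#' @param patch_size odd patch side in pixels (default 9).
#' @return An [rgb_trace()] at the video frame rate.
#' @export
sample_rgb_trace <- function(video, landmarks, n_points = 100L,
                             patch_size = 9L) {
  stopifnot(inherits(video, "video_sequence"))
  if (!is_count(patch_size) || patch_size %% 2 == 0)
    stop_pv("patch_size must be an odd positive integer",
            class = "config_error")
  nf <- length(video$frames)
  d <- dim(video$frames[[1]])
  get_lm <- if (is.function(landmarks)) {
    function(i) detect_landmarks(video$frames[[i]], landmarks, index = i - 1L)
  } else {
    if (length(landmarks) != nf)
      stop_pv("need one landmark set per frame (%d != %d)",
              length(landmarks), nf, class = "config_error")
    function(i) landmarks[[i]]
  }
  half <- (patch_size - 1L) %/% 2L
  patch_index <- function(lm) {
    pool <- do.call(rbind, lapply(c("forehead", "left_cheek", "right_cheek",
                                    "nose"), function(g) group_points(lm, g)))
    np <- nrow(pool)
    if (np == 0L) stop_pv("no sampling landmarks", class = "sampling_error")
    sel <- if (np > n_points)
      unique(round(seq(1, np, length.out = n_points))) else seq_len(np)
    rr <- integer(0); cc <- integer(0)
    for (s in sel) {
      row0 <- floor(pool[s, 2]) + 1L; col0 <- floor(pool[s, 1]) + 1L
      rows <- max(1L, row0 - half):min(d[1], row0 + half)
      cols <- max(1L, col0 - half):min(d[2], col0 + half)
      if (row0 + half < 1L || row0 - half > d[1] ||
          col0 + half < 1L || col0 - half > d[2])
        stop_pv("sampling patch at (%.1f, %.1f) falls outside the frame",
                pool[s, 1], pool[s, 2], class = "sampling_error")
      rr <- c(rr, rep(rows, times = length(cols)))
      cc <- c(cc, rep(cols, each = length(rows)))
    }
    cbind(rr, cc)
  }
  r <- numeric(nf); g <- numeric(nf); b <- numeric(nf)
  idx <- NULL; prev_lm <- NULL
  for (i in seq_len(nf)) {
    lm <- get_lm(i)
    if (is.null(idx) || !identical(lm, prev_lm)) {
      idx <- patch_index(lm)
      prev_lm <- lm
    }
    fr <- video$frames[[i]]
    r[i] <- mean(fr[cbind(idx, 1L)])
    g[i] <- mean(fr[cbind(idx, 2L)])
    b[i] <- mean(fr[cbind(idx, 3L)])
  }
  rgb_trace(r, g, b, video$frame_rate)
}

#' Split a trace into overlapping analysis windows
#'
#' Maximal set of full windows of `window_seconds` at stride
#' `stride_seconds`; a trailing partial window is dropped. Heart rate is
#' estimated once per window, so the stride sets the bpm series' time
#' resolution.
#'
#' @param trace an [rgb_trace()] or [ppg_record()].
#' @param window_seconds window length in seconds (default 8).
#' @param stride_seconds stride between window starts in seconds (default 1).
#' @return List of `signal_window` objects (`samples` holds the raw rows;
#'   run [preprocess_window()] before BVP extraction).
#' @export
make_windows <- function(trace, window_seconds = 8, stride_seconds = 1) {
  if (inherits(trace, "rgb_trace")) {
    rows <- rbind(trace$r, trace$g, trace$b)
    rate <- trace$rate
  } else if (inherits(trace, "ppg_record")) {
    rows <- matrix(trace$samples, nrow = 1L)
    rate <- trace$sample_rate
  } else stop_pv("trace must be an rgb_trace or ppg_record",
                 class = "config_error")
  L <- round(window_seconds * rate)
  step <- max(1L, round(stride_seconds * rate))
  n <- ncol(rows)
  if (n < L)
    stop_pv("trace spans %.3f s, shorter than one %g s window",
            n / rate, window_seconds, class = "insufficient_data_error")
  starts <- seq.int(1L, n - L + 1L, by = step)
  lapply(starts, function(s) {
    structure(list(samples = rows[, s:(s + L - 1L), drop = FALSE],
                   raw = rows[, s:(s + L - 1L), drop = FALSE],
                   raw_means = rowMeans(rows[, s:(s + L - 1L), drop = FALSE]),
                   start_time = (s - 1L) / rate, rate = rate,
                   preprocessed = FALSE),
              class = "signal_window")
  })
}

# Memoized Butterworth design: sixth-order bandpass over the heart-rate
# band, applied forward-backward (zero phase) via signal::filtfilt.
.butter_cache <- new.env(parent = emptyenv())
butter_bandpass <- function(rate, band) {
  key <- paste(rate, band[1], band[2])
  if (is.null(.butter_cache[[key]]))
    .butter_cache[[key]] <- signal::butter(6, band / (rate / 2), type = "pass")
  .butter_cache[[key]]
}

detrend_linear <- function(x) {
  n <- length(x)
  x - lm.fit(cbind(1, seq_len(n)), x)$fitted.values
}

# Zero-phase bandpass with odd-reflection end padding (3 filter lengths),
# which suppresses the start/end transients of plain filtfilt.
bandpass_row <- function(x, rate, band) {
  bf <- butter_bandpass(rate, band)
  xd <- detrend_linear(x)
  n <- length(xd)
  np <- min(n - 1L, 3L * (length(bf$b) - 1L))
  head_pad <- 2 * xd[1] - xd[(np + 1L):2L]
  tail_pad <- 2 * xd[n] - xd[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, xd, tail_pad))
  y <- y[(np + 1L):(np + n)]
  y - mean(y)
}

#' Preprocess an analysis window
#'
#' Per row: linear detrend, zero-phase sixth-order Butterworth bandpass
#' over the physiological heart-rate band (0.65--4.0 Hz by default, i.e.
#' 39--240 bpm), and mean removal. The raw rows and their means are kept
#' alongside, because the chrominance-based methods normalize by raw
#' channel means and the LGI projection operates on the raw signal.
#'
#' @param w a `signal_window` from [make_windows()].
#' @param band lower/upper band edges in Hz.
#' @return The window with `samples` replaced by the filtered rows.
#' @export
preprocess_window <- function(w, band = c(0.65, 4.0)) {
  stopifnot(inherits(w, "signal_window"))
  if (w$rate <= 2 * band[2])
    stop_pv("sampling rate %g Hz puts the %g Hz band edge at/above Nyquist",
            w$rate, band[2], class = "config_error")
  L <- ncol(w$raw)
  bf <- butter_bandpass(w$rate, band)
  if (L <= 3L * length(bf$b))
    stop_pv("window too short (%d samples) for the bandpass filter", L,
            class = "config_error")
  w$samples <- t(apply(w$raw, 1L, bandpass_row, rate = w$rate, band = band))
  w$band <- band
  w$preprocessed <- TRUE
  w
}

bvp_estimate <- function(signal, method) {
  structure(list(signal = as.numeric(signal), method = method),
            class = "bvp_estimate")
}

check_preprocessed <- function(w, need_rows = 3L) {
  stopifnot(inherits(w, "signal_window"))
  if (!isTRUE(w$preprocessed))
    stop_pv("window must be preprocessed first", class = "config_error")
  if (nrow(w$samples) < need_rows)
    stop_pv("window has %d rows, need %d", nrow(w$samples), need_rows,
            class = "config_error")
  invisible(w)
}

#' GREEN blood-volume-pulse extraction
#'
#' The simplest estimator: the (bandpassed) green channel is taken as the
#' pulse signal, green being the channel where haemoglobin absorption
#' modulates reflected light the most.
#'
#' @param w a preprocessed `signal_window` with 3 rows.
#' @return A `bvp_estimate`.
#' @export
bvp_green <- function(w) {
  check_preprocessed(w)
  s <- w$samples[2L, ]
  bvp_estimate(s - mean(s), "GREEN")
}

#' ICA blood-volume-pulse extraction
#'
#' The three bandpassed colour channels are unmixed into independent
#' components with a seeded deflation FastICA, and the component carrying
#' the pulse is returned. Component order in ICA is arbitrary, so the
#' pulse component is identified deterministically as the one with the
#' highest in-band spectral concentration (power within 0.1 Hz of its own
#' spectral peak, relative to total in-band power) — the most periodic
#' component in the heart-rate band.
#'
#' @param w a preprocessed `signal_window` with 3 rows.
#' @param seed integer seed for the FastICA initialization.
#' @return A `bvp_estimate`; all components are attached as
#'   `attr(, "components")`.
#' @export
bvp_ica <- function(w, seed = 42L) {
  check_preprocessed(w)
  if (all(apply(w$samples, 1L, stats::sd) < 1e-12))
    stop_pv("constant channel rows: ICA decomposition undefined",
            class = "decomposition_error")
  S <- fastica_deflation(w$samples, seed = seed)
  scores <- apply(S, 1L, peak_concentration, rate = w$rate,
                  band = w$band %||% c(0.65, 4.0))
  s <- S[which.max(scores), ]
  out <- bvp_estimate(s - mean(s), "ICA")
  attr(out, "components") <- S
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CHROM blood-volume-pulse extraction
#'
#' Chrominance method: channels are normalized by their raw window means
#' (`Rn = R_bp / mean(R_raw)`, etc.), combined into two chrominance
#' signals `X = 3 Rn - 2 Gn` and `Y = 1.5 Rn + Gn - 1.5 Bn`, and the pulse
#' is `S = X - alpha * Y` with `alpha = sd(X)/sd(Y)` (alpha = 0 when Y has
#' no variance). Mean normalization makes the output invariant to global
#' intensity scaling.
#'
#' @param w a preprocessed `signal_window` with 3 rows.
#' @return A `bvp_estimate`.
#' @export
bvp_chrom <- function(w) {
  check_preprocessed(w)
  if (any(abs(w$raw_means) < 1e-12))
    stop_pv("zero channel mean: cannot normalize", class = "normalization_error")
  Rn <- w$samples[1L, ] / w$raw_means[1L]
  Gn <- w$samples[2L, ] / w$raw_means[2L]
  Bn <- w$samples[3L, ] / w$raw_means[3L]
  X <- 3 * Rn - 2 * Gn
  Y <- 1.5 * Rn + Gn - 1.5 * Bn
  sy <- stats::sd(Y)
  alpha <- if (sy < 1e-300) 0 else stats::sd(X) / sy
  S <- X - alpha * Y
  bvp_estimate(S - mean(S), "CHROM")
}

#' POS blood-volume-pulse extraction
#'
#' Plane-orthogonal-to-skin method: the mean-normalized channels are
#' projected onto the plane orthogonal to the skin-tone direction with
#' `P = [[0, 1, -1], [-2, 1, 1]]`, and the two projections are recombined
#' as `h = S1 + (sd(S1)/sd(S2)) * S2` (second term dropped when S2 has no
#' variance), mean-centered.
#'
#' @param w a preprocessed `signal_window` with 3 rows.
#' @return A `bvp_estimate`.
#' @export
bvp_pos <- function(w) {
  check_preprocessed(w)
  if (any(abs(w$raw_means) < 1e-12))
    stop_pv("zero channel mean: cannot normalize", class = "normalization_error")
  Cn <- w$samples / w$raw_means
  S1 <- Cn[2L, ] - Cn[3L, ]
  S2 <- -2 * Cn[1L, ] + Cn[2L, ] + Cn[3L, ]
  s2 <- stats::sd(S2)
  h <- if (s2 < 1e-300) S1 else S1 + (stats::sd(S1) / s2) * S2
  bvp_estimate(h - mean(h), "POS")
}

#' LGI blood-volume-pulse extraction
#'
#' Local group invariance: the dominant left-singular direction `u1` of the
#' raw 3 x L window — in practice the mean-colour/illumination axis, which
#' absorbs common-mode intensity changes from motion and lighting — is
#' projected out with `P = I - u1 u1'`, and the projected green row is
#' taken as the pulse, then detrended, bandpassed and centered. Computing
#' the projection on the raw (mean-retaining) signal is essential: on the
#' bandpassed signal the dominant direction would be the pulse itself and
#' the projection would annihilate it.
#'
#' @param w a preprocessed `signal_window` with 3 rows.
#' @return A `bvp_estimate`; the projected matrix and `u1` are attached as
#'   attributes `"projection"` and `"u1"`.
#' @export
bvp_lgi <- function(w) {
  check_preprocessed(w)
  if (any(!is.finite(w$raw)))
    stop_pv("non-finite values in window", class = "decomposition_error")
  sv <- tryCatch(svd(w$raw), error = function(e)
    stop_pv("SVD failed: %s", conditionMessage(e),
            class = "decomposition_error"))
  u1 <- sv$u[, 1L]
  Y <- w$raw - u1 %*% (t(u1) %*% w$raw)
  s <- Y[2L, ]
  out <- if (sqrt(mean(s^2)) < 1e-9)
    bvp_estimate(numeric(ncol(w$raw)), "LGI")
  else
    bvp_estimate(bandpass_row(s, w$rate, w$band %||% c(0.65, 4.0)), "LGI")
  attr(out, "projection") <- Y
  attr(out, "u1") <- u1
  out
}

#' Heart rate from a blood-volume-pulse signal
#'
#' Welch power spectral density (Hann taper, 50% overlap, zero-padded to a
#' grid of at most 0.25 bpm), with the peak restricted to the
#' physiological band; bpm is 60 times the peak frequency, so estimates
#' always fall in `[39, 240]` bpm for the default band.
#'
#' @param b a `bvp_estimate` or numeric signal.
#' @param rate sampling rate in Hz.
#' @param band lower/upper peak-search band in Hz.
#' @return Heart rate in beats per minute.
#' @export
bpm_from_bvp <- function(b, rate, band = c(0.65, 4.0)) {
  x <- if (inherits(b, "bvp_estimate")) b$signal else as.numeric(b)
  if (rate <= 2 * band[2])
    stop_pv("rate %g Hz too low for band edge %g Hz", rate, band[2],
            class = "config_error")
  if (all(abs(x - x[1]) < 1e-300))
    stop_pv("constant signal: undefined spectral peak",
            class = "undefined_peak_error")
  60 * spectral_peak_hz(x, rate, band)
}

bpm_series <- function(times, bpm, source = "rppg") {
  if (length(times) != length(bpm))
    stop_pv("times and bpm lengths differ", class = "alignment_error")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_pv("window times must be strictly increasing",
            class = "alignment_error")
  structure(list(times = as.numeric(times), bpm = as.numeric(bpm),
                 source = source), class = "bpm_series")
}

#' @export
print.bpm_series <- function(x, ...) {
  cat(sprintf("<bpm_series> %d windows (%s), mean %.1f bpm\n",
              length(x$bpm), x$source, mean(x$bpm)))
  invisible(x)
}

#' @export
as.data.frame.bpm_series <- function(x, ...) {
  data.frame(window_start_s = x$times, bpm = x$bpm)
}

run_bvp_method <- function(w, method, seed) {
  switch(method,
    GREEN = bvp_green(w),
    ICA = bvp_ica(w, seed = seed),
    CHROM = bvp_chrom(w),
    POS = bvp_pos(w),
    LGI = bvp_lgi(w),
    stop_pv("unknown BVP method '%s'", method, class = "config_error"))
}

#' Estimate a heart-rate series from a facial video
#'
#' End-to-end composition: skin RGB trace, overlapping windows, detrend and
#' bandpass, one of the five BVP algorithms, and the spectral-peak bpm per
#' window.
#'
#' @param video a [video_sequence()].
#' @param landmarks per-frame landmark list or provider function.
#' @param method `"GREEN"`, `"ICA"`, `"CHROM"`, `"POS"` or `"LGI"`.
#' @param window_seconds,stride_seconds windowing parameters (seconds).
#' @param band heart-rate band in Hz.
#' @param seed seed for the ICA decomposition.
#' @param n_points,patch_size trace-sampling parameters, see
#'   [sample_rgb_trace()].
#' @return A `bpm_series` with one estimate per window.
#' @examples
#' sc <- render_scene(scene_config(duration = 10, sensor_noise_sigma = 0))
#' est <- estimate_bpm_series(sc$video, sc$landmarks, "GREEN")
#' mean(est$bpm)  # close to the generating 72 bpm
#' @export
estimate_bpm_series <- function(video, landmarks, method = "POS",
                                window_seconds = 8, stride_seconds = 1,
                                band = c(0.65, 4.0), seed = 42L,
                                n_points = 100L, patch_size = 9L) {
  if (!(method %in% BVP_METHODS))
    stop_pv("unknown BVP method '%s'", method, class = "config_error")
  trace <- sample_rgb_trace(video, landmarks, n_points = n_points,
                            patch_size = patch_size)
  windows <- make_windows(trace, window_seconds, stride_seconds)
  times <- numeric(length(windows)); bpm <- numeric(length(windows))
  for (i in seq_along(windows)) {
    res <- tryCatch({
      w <- preprocess_window(windows[[i]], band = band)
      bpm_from_bvp(run_bvp_method(w, method, seed), w$rate, band = band)
    }, error = function(e)
      stop_pv("window %d (t=%.1f s): %s", i - 1L, windows[[i]]$start_time,
              conditionMessage(e), class = "estimation_error"))
    times[i] <- windows[[i]]$start_time
    bpm[i] <- res
  }
  bpm_series(times, bpm, source = method)
}

#' Heart-rate series from a ground-truth PPG record
#'
#' The contact PPG is pushed through the identical windowing, detrend,
#' bandpass and spectral-peak path as the video signal (skipping the trace
#' and BVP stages), so ground-truth and estimated bpm share any estimator
#' bias and their difference isolates the effect of video modification.
#'
#' @param ppg a [ppg_record()].
#' @inheritParams estimate_bpm_series
#' @return A `bpm_series`.
#' @export
bpm_series_from_ppg <- function(ppg, window_seconds = 8, stride_seconds = 1,
                                band = c(0.65, 4.0)) {
  stopifnot(inherits(ppg, "ppg_record"))
  windows <- make_windows(ppg, window_seconds, stride_seconds)
  times <- numeric(length(windows)); bpm <- numeric(length(windows))
  for (i in seq_along(windows)) {
    w <- preprocess_window(windows[[i]], band = band)
    times[i] <- w$start_time
    bpm[i] <- bpm_from_bvp(w$samples[1L, ], w$rate, band = band)
  }
  bpm_series(times, bpm, source = "ppg")
}
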