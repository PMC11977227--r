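#' Mean absolute heart-rate error
#'
#' `(1/n) * sum(|h_i - hhat_i|)` over aligned windows: the average absolute
#' difference between ground-truth and estimated per-window heart rates, in
#' beats per minute. Robust to single-window outliers, and symmetric in its
#' two arguments.
#'
#' @param gt,est `bpm_series` objects with identical window times
#'   (tolerance 1e-6 s).
#' @return Mean absolute difference in bpm.
#' @export
delta_bpm <- function(gt, est) {
  stopifnot(inherits(gt, "bpm_series"), inherits(est, "bpm_series"))
  if (length(gt$bpm) != length(est$bpm))
    stop_pv("series lengths differ (%d vs %d)", length(gt$bpm),
            length(est$bpm), class = "alignment_error")
  if (any(abs(gt$times - est$times) > 1e-6))
    stop_pv("window times are not aligned", class = "alignment_error")
  mean(abs(gt$bpm - est$bpm))
}

#' Frame information loss (mean squared error)
#'
#' Per frame, the mean squared difference between original and modified
#' pixel intensities, averaged over all pixels and the three colour
#' channels (`1/(m*n*3) * sum((I - K)^2)`), then averaged over frames.
#' With `per_channel_mean = FALSE` the channel sum is kept
#' (`1/(m*n) * sum`), and with a `mask` the average runs over in-mask
#' pixels only.
#'
#' @param original,modified [video_sequence()]s of identical geometry.
#' @param mask optional `roi_mask` restricting the average.
#' @param per_channel_mean divide by the channel count (default) or not.
#' @return Mean squared error in squared 8-bit intensity units.
#' @export
frame_mse <- function(original, modified, mask = NULL,
                      per_channel_mean = TRUE) {
  stopifnot(inherits(original, "video_sequence"),
            inherits(modified, "video_sequence"))
  nf <- length(original$frames)
  if (nf != length(modified$frames))
    stop_pv("frame counts differ (%d vs %d)", nf, length(modified$frames),
            class = "dimension_error")
  d <- dim(original$frames[[1]])
  if (!all(dim(modified$frames[[1]]) == d))
    stop_pv("frame dimensions differ", class = "dimension_error")
  sel <- if (!is.null(mask)) mask3(mask, d) else NULL
  per_frame <- vapply(seq_len(nf), function(i) {
    diff2 <- (original$frames[[i]] - modified$frames[[i]])^2
    if (!is.null(sel)) {
      s <- sum(diff2[sel])
      denom <- if (per_channel_mean) sum(sel) else sum(sel) / 3
    } else {
      s <- sum(diff2)
      denom <- if (per_channel_mean) length(diff2) else d[1] * d[2]
    }
    s / denom
  }, numeric(1))
  mean(per_frame)
}

#' Min-max normalization
#'
#' Maps values to `[0, 1]` by `(v - min) / (max - min)`; a constant vector
#' maps to all zeros.
#'
#' @param values numeric vector of length at least 2.
#' @return Normalized vector.
#' @export
normalize_minmax <- function(values) {
  if (length(values) < 2L)
    stop_pv("min-max normalization needs at least 2 values",
            class = "insufficient_data_error")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Overall concealment score
#'
#' Balances concealment strength against image damage across a set of
#' modification methods:
#' `OS = (dbpm_n + (1 - MSE_n)) / 2`, where `dbpm_n` is the min-max
#' normalized heart-rate error and `1 - MSE_n` the data retention factor
#' (1 minus min-max normalized frame MSE). Both normalizations run across
#' the supplied method set, so OS is a relative ranking within one
#' evaluation: the method with maximal error and minimal damage scores 1.
#' When per-technique errors are supplied (a list of numeric vectors per
#' method), they are first averaged across techniques.
#'
#' @param delta_bpms named numeric vector (per method), or named list of
#'   per-technique error vectors.
#' @param mses named numeric vector of frame MSEs over the same methods.
#' @return `data.frame` with columns `method`, `delta_bpm`, `mse`,
#'   `delta_bpm_norm`, `mse_norm`, `retention`, `os`.
#' @export
overall_score <- function(delta_bpms, mses) {
  if (is.list(delta_bpms))
    delta_bpms <- vapply(delta_bpms, function(v) mean(unlist(v)), numeric(1))
  if (is.null(names(delta_bpms)) || is.null(names(mses)) ||
      !setequal(names(delta_bpms), names(mses)) ||
      anyDuplicated(names(delta_bpms)) || anyDuplicated(names(mses)))
    stop_pv("delta_bpms and mses must be named over the same method set",
            class = "alignment_error")
  mses <- mses[names(delta_bpms)]
  dn <- normalize_minmax(delta_bpms)
  mn <- normalize_minmax(mses)
  data.frame(method = names(delta_bpms),
             delta_bpm = as.numeric(delta_bpms), mse = as.numeric(mses),
             delta_bpm_norm = as.numeric(dn), mse_norm = as.numeric(mn),
             retention = as.numeric(1 - mn),
             os = as.numeric((dn + (1 - mn)) / 2),
             row.names = NULL)
}

#' Measure modification throughput
#'
#' Wall-clock frames per second of the mask + filter + overlay path alone
#' (landmark lookup, mask construction, operator and compositing), i.e.
#' the reciprocal of the mean per-frame processing time. Throughput is
#' hardware-dependent and is reported as descriptive metadata, never as a
#' comparable quantity across machines.
#'
#' @param cfg a [filter_config()].
#' @param video a [video_sequence()]; at least 100 frames recommended.
#' @param roi_kind ROI kind, see [modify_video()].
#' @param provider landmark provider when `roi_kind != "full_frame"`.
#' @return Frames per second, with attributes `frame_size`, `roi_kind`,
#'   `n_frames` and a `hardware_note`.
#' @export
measure_fps <- function(cfg, video, roi_kind = "full_frame",
                        provider = NULL) {
  stopifnot(inherits(cfg, "filter_config"), inherits(video, "video_sequence"))
  nf <- length(video$frames)
  state <- filter_state_init(cfg)
  t0 <- proc.time()[["elapsed"]]
  mask <- NULL; prev_lm <- NULL
  for (i in seq_len(nf)) {
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
    step <- apply_filter_step(frame, mask, cfg, state)
    state <- step$state
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  fps <- nf / max(elapsed, .Machine$double.eps)
  structure(fps,
            frame_size = dim(video$frames[[1]])[1:2],
            roi_kind = roi_kind, n_frames = nf,
            hardware_note = "wall-clock throughput; depends on hardware")
}

#' Evaluate concealment methods end to end
#'
#' For every modification configuration: modify the video inside the ROI,
#' measure the frame MSE against the original, estimate the heart-rate
#' series with each requested rPPG technique, and compute the per-window
#' error against the ground-truth PPG; then min-max normalize across the
#' method set (errors first averaged across techniques) and compute the
#' overall score.
#'
#' @param scene a [render_scene()] result (supplies video, ground-truth
#'   PPG and the landmark provider).
#' @param cfgs list of [filter_config()]s; at least 2 for meaningful
#'   normalization.
#' @param roi_kind ROI for modification.
#' @param techniques character vector of BVP methods to estimate with.
#' @param window_seconds,stride_seconds windowing, see [make_windows()].
#' @param seed seed forwarded to the ICA decomposition.
#' @param with_fps also measure per-method throughput.
#' @return An object of class `eval_report`: list with `rows` (one
#'   data.frame row per method x technique) and `summary` (per-method
#'   scores from [overall_score()], plus `fps` when measured).
#' @export
evaluate_run <- function(scene, cfgs, roi_kind = "facial_skin",
                         techniques = BVP_METHODS,
                         window_seconds = 8, stride_seconds = 1,
                         seed = 42L, with_fps = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!all(techniques %in% BVP_METHODS))
    stop_pv("unknown technique(s): %s",
            paste(setdiff(techniques, BVP_METHODS), collapse = ", "),
            class = "config_error")
  methods <- vapply(cfgs, function(c) c$method, character(1))
  if (anyDuplicated(methods))
    stop_pv("duplicate methods in cfgs", class = "config_error")
  names(cfgs) <- methods
  provider <- scene_landmark_provider(scene)
  gt <- bpm_series_from_ppg(scene$ppg, window_seconds, stride_seconds)
  rows <- list()
  deltas <- list(); mses <- numeric(0); fps <- numeric(0)
  for (m in methods) {
    mod <- modify_video(scene$video, roi_kind, cfgs[[m]], provider = provider)
    mse_m <- frame_mse(scene$video, mod)
    d <- numeric(0)
    for (tech in techniques) {
      est <- estimate_bpm_series(mod, scene$landmarks, tech,
                                 window_seconds, stride_seconds, seed = seed)
      d[tech] <- delta_bpm(gt, est)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, technique = tech, delta_bpm = d[tech], mse = mse_m,
        row.names = NULL)
    }
    deltas[[m]] <- d
    mses[m] <- mse_m
    if (with_fps)
      fps[m] <- as.numeric(measure_fps(cfgs[[m]], scene$video, roi_kind,
                                       provider))
  }
  summary <- overall_score(deltas, mses)
  if (with_fps) summary$fps <- as.numeric(fps[summary$method])
  structure(list(rows = do.call(rbind, rows), summary = summary,
                 roi_kind = roi_kind, techniques = techniques),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> ROI %s, techniques: %s\n", x$roi_kind,
              paste(x$techniques, collapse = ", ")))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-(method, technique) rows merged with the per-method
#' normalized scores as CSV, and a JSON mirror next to it.
#'
#' @param report an `eval_report`.
#' @param path CSV destination; the JSON mirror replaces the extension.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  merged <- merge(report$rows,
                  report$summary[, setdiff(names(report$summary),
                                           c("delta_bpm", "mse"))],
                  by = "method", sort = FALSE)
  utils::write.csv(merged, path, row.names = FALSE)
  jsonlite::write_json(list(rows = report$rows, summary = report$summary,
                            roi_kind = report$roi_kind),
                       sub("\\.[^.]*$", ".json", path), digits = NA)
  invisible(path)
}
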