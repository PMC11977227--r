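#' Parameter sweep over a modification method
#'
#' Evaluates the metric suite at each value of a method's tuning parameter
#' — kernel size for the blurs, window length for sliding temporal
#' averaging — against an unmodified (`NE`) baseline, and returns a tidy
#' long-format table. The overall score is normalized across the whole
#' sweep set (baseline included), so it ranks the grid points against each
#' other.
#'
#' @param scene a [render_scene()] result.
#' @param method one of `"MB"`, `"GB"`, `"BB"`, `"TA-S"`, `"TA-C"` or the
#'   noise methods.
#' @param values numeric grid of parameter values (kernel sizes must be
#'   odd). Ignored for methods without a swept parameter.
#' @param roi_kind ROI for modification.
#' @param techniques BVP methods to estimate with.
#' @param include_baseline include an `NE` reference row (default TRUE).
#' @param ... forwarded to [evaluate_run()] (windowing, seed).
#' @return `data.frame` with columns `parameter`, `method`, `technique`,
#'   `delta_bpm`, `mse`, `os` (os repeated across techniques of one row
#'   group).
#' @export
run_sweep <- function(scene, method, values, roi_kind = "facial_skin",
                      techniques = c("GREEN", "CHROM", "POS"),
                      include_baseline = TRUE, ...) {
  param <- switch(method,
    MB = , GB = "kernel_size",
    BB = "bilateral_diameter",
    `TA-S` = "window_frames",
    stop_pv("method '%s' has no swept parameter", method,
            class = "config_error"))
  if (length(values) < 1L)
    stop_pv("empty parameter grid", class = "config_error")
  cfgs <- list()
  labels <- character(0)
  for (v in values) {
    args <- list(method = method)
    args[[param]] <- v
    cfgs[[length(cfgs) + 1L]] <- do.call(filter_config, args)
    labels <- c(labels, as.character(v))
  }
  if (include_baseline) {
    cfgs[[length(cfgs) + 1L]] <- filter_config("NE")
    labels <- c(labels, NA_character_)
  }
  # evaluate_run() keys methods by name, so run each grid point separately
  # and normalize afterwards across the whole sweep.
  provider <- scene_landmark_provider(scene)
  dots <- list(...)
  ws <- dots$window_seconds %||% 8
  ss <- dots$stride_seconds %||% 1
  seed <- dots$seed %||% 42L
  gt <- bpm_series_from_ppg(scene$ppg, ws, ss)
  rows <- list(); deltas <- list(); mses <- numeric(0)
  for (i in seq_along(cfgs)) {
    key <- paste0(method, ":", i)
    mod <- modify_video(scene$video, roi_kind, cfgs[[i]], provider = provider)
    mses[key] <- frame_mse(scene$video, mod)
    d <- numeric(0)
    for (tech in techniques) {
      est <- estimate_bpm_series(mod, scene$landmarks, tech, ws, ss,
                                 seed = seed)
      d[tech] <- delta_bpm(gt, est)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = labels[i],
        method = cfgs[[i]]$method, technique = tech,
        delta_bpm = d[tech], mse = mses[key], row.names = NULL)
    }
    deltas[[key]] <- d
  }
  os <- overall_score(deltas, mses)
  tab <- do.call(rbind, rows)
  tab$os <- rep(os$os, each = length(techniques))
  tab
}
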