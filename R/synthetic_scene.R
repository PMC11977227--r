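#' Configure a synthetic pulse-modulated scene
#'
#' The scene generator emulates the measurement situation the concealment
#' pipeline is graded in: a facial video at 25 fps with a co-registered
#' 60 Hz ground-truth PPG. A skin-coloured ellipse ("face") carries an
#' additive pulse — a small-signal linear model of blood-volume absorption,
#' strongest in green — plus optional Gaussian sensor noise; dark eye and
#' mouth rectangles inside the ellipse carry no pulse; the background is
#' static; a full landmark set (outer face ring, eye/mouth corners, and
#' over 100 forehead/cheek/nose grid points) is produced per frame and
#' translates exactly with any configured motion.
#'
#' @param width,height frame size in pixels.
#' @param frame_rate video frame rate in Hz.
#' @param duration scene length in seconds.
#' @param hr_bpm generating heart rate in beats per minute; must lie inside
#'   the physiological band (39--240).
#' @param pulse_waveform `"sinusoid"` or `"sinusoid+harmonic"` (adds a 0.3
#'   amplitude second harmonic).
#' @param channel_amplitudes pulse amplitude per RGB channel in 8-bit
#'   counts; the default makes green strongest.
#' @param base_color skin tone as RGB in 8-bit counts.
#' @param sensor_noise_sigma per-pixel, per-frame Gaussian noise s.d. in
#'   counts.
#' @param texture_sigma s.d. (counts) of the static per-pixel skin texture,
#'   drawn once per scene. Real skin is not a uniform colour; the texture
#'   also acts as a spatial dither, so patch-averaged traces respond
#'   linearly to sub-quantization pulse amplitudes instead of inheriting
#'   the 8-bit staircase of a perfectly uniform surface.
#' @param flicker_sigma s.d. (counts) of per-frame global intensity jitter
#'   on the skin, shared by all three channels — the ambient-illumination
#'   fluctuation that dominates real rPPG noise. Unlike per-pixel sensor
#'   noise it does not average away over sampling patches, so it sets the
#'   effective noise floor of the RGB trace.
#' @param wb_jitter_sigma s.d. (counts) of a smaller per-frame,
#'   per-channel jitter, emulating camera white-balance/gain fluctuation
#'   that is independent across channels.
#' @param motion `c(dx, dy)` rigid drift in pixels per second.
#' @param ppg_rate ground-truth PPG sampling rate in Hz.
#' @param seed integer seed for the sensor noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 128L, height = 128L, frame_rate = 25,
                         duration = 10, hr_bpm = 72,
                         pulse_waveform = c("sinusoid", "sinusoid+harmonic"),
                         channel_amplitudes = c(0.45, 1.5, 0.9),
                         base_color = c(180, 120, 100),
                         sensor_noise_sigma = 0.5,
                         texture_sigma = 2, flicker_sigma = 0.5,
                         wb_jitter_sigma = 0.15,
                         motion = c(0, 0), ppg_rate = 60, seed = 1L) {
  pulse_waveform <- match.arg(pulse_waveform)
  if (!is_count(width) || !is_count(height) || width < 16 || height < 16)
    stop_pv("scene must be at least 16x16 pixels", class = "config_error")
  if (frame_rate <= 0 || ppg_rate <= 0)
    stop_pv("rates must be positive", class = "config_error")
  f <- hr_bpm / 60
  if (f <= 0.65 || f >= 4.0)
    stop_pv("hr_bpm %g lies outside the physiological band (39, 240)",
            hr_bpm, class = "config_error")
  if (any(channel_amplitudes < 0))
    stop_pv("channel amplitudes must be non-negative", class = "config_error")
  headroom <- channel_amplitudes *
    (1 + if (pulse_waveform == "sinusoid+harmonic") 0.3 else 0)
  if (any(base_color - headroom < 0) || any(base_color + headroom > 255))
    stop_pv("base_color +/- pulse amplitude must stay within [0, 255]",
            class = "config_error")
  if (sensor_noise_sigma < 0 || texture_sigma < 0 || flicker_sigma < 0 ||
      wb_jitter_sigma < 0)
    stop_pv("noise and texture sigmas must be non-negative",
            class = "config_error")
  structure(list(width = as.integer(width), height = as.integer(height),
                 frame_rate = frame_rate, duration = duration,
                 hr_bpm = hr_bpm, pulse_waveform = pulse_waveform,
                 channel_amplitudes = channel_amplitudes,
                 base_color = base_color,
                 sensor_noise_sigma = sensor_noise_sigma,
                 texture_sigma = texture_sigma,
                 flicker_sigma = flicker_sigma,
                 wb_jitter_sigma = wb_jitter_sigma,
                 motion = motion, ppg_rate = ppg_rate,
                 seed = as.integer(seed)),
            class = "scene_config")
}

pulse_value <- function(cfg, t) {
  f <- cfg$hr_bpm / 60
  w <- sin(2 * pi * f * t)
  if (cfg$pulse_waveform == "sinusoid+harmonic")
    w <- w + 0.3 * sin(4 * pi * f * t)
  w
}

#' Ground-truth PPG waveform for a scene
#'
#' The unit-amplitude pulse waveform at `hr_bpm / 60` Hz, sampled at the
#' PPG rate. The identical closed-form waveform drives the skin modulation
#' in [render_scene()], so the video path and the PPG path measure the
#' same underlying signal exactly.
#'
#' @param cfg a [scene_config()].
#' @return A [ppg_record()].
#' @export
ppg_waveform <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  n <- round(cfg$duration * cfg$ppg_rate)
  if (n < 1L)
    stop_pv("duration %g s yields an empty PPG record", cfg$duration,
            class = "empty_record_error")
  t <- (seq_len(n) - 1L) / cfg$ppg_rate
  ppg_record(pulse_value(cfg, t), cfg$ppg_rate)
}

# Scene geometry in relative coordinates (fractions of width/height).
scene_geometry <- function(cfg, offset = c(0, 0)) {
  w <- cfg$width; h <- cfg$height
  rect <- function(x0, x1, y0, y1)
    cbind(c(x0, x1, x1, x0) * w + offset[1], c(y0, y0, y1, y1) * h + offset[2])
  grid <- function(x0, x1, y0, y1, nx, ny) {
    gx <- seq(x0, x1, length.out = nx) * w + offset[1]
    gy <- seq(y0, y1, length.out = ny) * h + offset[2]
    cbind(rep(gx, each = ny), rep(gy, times = nx))
  }
  ring_t <- seq(0, 2 * pi, length.out = 37L)[-37L]
  list(center = c(0.5 * w + offset[1], 0.52 * h + offset[2]),
       axes = c(0.34 * w, 0.42 * h),
       outer_face = cbind(0.5 * w + 0.34 * w * cos(ring_t) + offset[1],
                          0.52 * h + 0.42 * h * sin(ring_t) + offset[2]),
       left_eye = rect(0.32, 0.44, 0.38, 0.44),
       right_eye = rect(0.56, 0.68, 0.38, 0.44),
       mouth = rect(0.38, 0.62, 0.70, 0.78),
       forehead = grid(0.35, 0.65, 0.18, 0.30, 7L, 6L),
       left_cheek = grid(0.24, 0.36, 0.50, 0.64, 4L, 5L),
       right_cheek = grid(0.64, 0.76, 0.50, 0.64, 4L, 5L),
       nose = grid(0.465, 0.535, 0.50, 0.62, 3L, 7L))
}

geometry_landmarks <- function(geom) {
  parts <- c("outer_face", "left_eye", "right_eye", "mouth",
             "forehead", "left_cheek", "right_cheek", "nose")
  pts <- do.call(rbind, geom[parts])
  counts <- vapply(geom[parts], nrow, integer(1))
  ends <- cumsum(counts)
  groups <- Map(function(e, c) seq.int(e - c + 1L, e), ends, counts)
  names(groups) <- parts
  landmark_set(pts, groups)
}

rect_mask <- function(corners, m, n) {
  cols <- seq_len(n) - 0.5; rows <- seq_len(m) - 0.5
  cx <- cols >= min(corners[, 1]) & cols <= max(corners[, 1])
  cy <- rows >= min(corners[, 2]) & rows <= max(corners[, 2])
  outer(cy, cx)
}

#' Render a synthetic scene
#'
#' Produces the video, the co-registered ground-truth PPG, the per-frame
#' landmark sets and the generating heart rate. Per frame `t`, skin-ellipse
#' pixels take
#' `base_color + texture + channel_amplitudes * w(t) + flicker_ch(t) +
#' N(0, sigma^2)` (clipped and rounded to 8 bits), where `w(t)` is the
#' shared pulse waveform evaluated at frame times, `texture` is a static
#' per-pixel offset and `flicker_ch(t)` a per-frame, per-channel global
#' jitter; the eye and mouth rectangles and the background are static. All
#' randomness derives from `cfg$seed`, so identical configurations render
#' bit-identical scenes.
#'
#' @param cfg a [scene_config()].
#' @return An object of class `synthetic_scene`: list with elements
#'   `video`, `ppg`, `landmarks`, `truth_bpm`, `config`.
#' @examples
#' sc <- render_scene(scene_config(duration = 2, seed = 7))
#' sc$video
#' sc$truth_bpm
#' @export
render_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nf <- round(cfg$duration * cfg$frame_rate)
  if (nf < 1L)
    stop_pv("duration %g s yields no frames", cfg$duration,
            class = "empty_record_error")
  m <- cfg$height; n <- cfg$width
  times <- (seq_len(nf) - 1L) / cfg$frame_rate
  wt <- pulse_value(cfg, times)
  background <- c(60, 60, 65)
  eye_color <- c(45, 35, 35)
  res <- with_private_rng(cfg$seed, {
    frames <- vector("list", nf)
    landmarks <- vector("list", nf)
    texture <- if (cfg$texture_sigma > 0)
      matrix(rnorm(m * n, 0, cfg$texture_sigma), m, n) else matrix(0, m, n)
    flicker <- matrix(0, nf, 3L)
    if (cfg$flicker_sigma > 0)
      flicker <- flicker + rnorm(nf, 0, cfg$flicker_sigma)
    if (cfg$wb_jitter_sigma > 0)
      flicker <- flicker + matrix(rnorm(nf * 3L, 0, cfg$wb_jitter_sigma),
                                  nf, 3L)
    for (i in seq_len(nf)) {
      off <- cfg$motion * times[i]
      geom <- scene_geometry(cfg, offset = off)
      landmarks[[i]] <- geometry_landmarks(geom)
      cx <- geom$center[1]; cy <- geom$center[2]
      a <- geom$axes[1]; b <- geom$axes[2]
      px <- seq_len(n) - 0.5; py <- seq_len(m) - 0.5
      skin <- outer(((py - cy) / b)^2, ((px - cx) / a)^2, `+`) <= 1
      dark <- rect_mask(geom$left_eye, m, n) | rect_mask(geom$right_eye, m, n) |
        rect_mask(geom$mouth, m, n)
      dark <- dark & skin
      skin_only <- skin & !dark
      ns <- sum(skin_only)
      fr <- array(0, dim = c(m, n, 3))
      for (ch in 1:3) {
        plane <- matrix(background[ch], m, n)
        val <- cfg$base_color[ch] + cfg$channel_amplitudes[ch] * wt[i] +
          flicker[i, ch] + texture[skin_only]
        plane[skin_only] <- if (cfg$sensor_noise_sigma > 0)
          val + rnorm(ns, 0, cfg$sensor_noise_sigma) else val
        plane[dark] <- eye_color[ch]
        fr[, , ch] <- plane
      }
      frames[[i]] <- quantize8(fr)
    }
    list(frames = frames, landmarks = landmarks)
  })
  attr(res, "rng_state") <- NULL
  structure(list(video = video_sequence(res$frames, cfg$frame_rate),
                 ppg = ppg_waveform(cfg),
                 landmarks = res$landmarks,
                 truth_bpm = cfg$hr_bpm,
                 config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d frames, %g bpm pulse, noise sd %g\n",
              length(x$video$frames), x$truth_bpm,
              x$config$sensor_noise_sigma))
  invisible(x)
}

#' Landmarks of a scene at one frame
#'
#' @param scene a [render_scene()] result.
#' @param t 0-based frame index.
#' @return A [landmark_set()].
#' @export
scene_landmarks <- function(scene, t) {
  stopifnot(inherits(scene, "synthetic_scene"))
  nf <- length(scene$landmarks)
  if (!is_count(t + 1) || t < 0 || t >= nf)
    stop_pv("frame index %s out of range [0, %d)", format(t), nf,
            class = "index_error")
  scene$landmarks[[t + 1L]]
}

#' Landmark provider bound to a synthetic scene
#'
#' Returns a `function(frame, index)` suitable for [modify_video()],
#' [detect_landmarks()] and [estimate_bpm_series()], replaying the scene's
#' exact generated geometry — the ground-truth analogue of an external
#' face-mesh detector.
#'
#' @param scene a [render_scene()] result.
#' @return A provider function.
#' @export
scene_landmark_provider <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  function(frame, index) scene_landmarks(scene, index)
}

#' Export a scene to disk
#'
#' Writes the lossless PNG frame directory, `ppg.csv`, `landmarks.json`
#' (first frame plus per-frame offsets are reconstructible from the config)
#' and `truth.json` under `path`.
#'
#' @param scene a [render_scene()] result.
#' @param path destination directory.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop_pv("cannot create '%s'", path, class = "io_error")
  write_video(scene$video, file.path(path, "frames"))
  write_ppg(scene$ppg, file.path(path, "ppg.csv"))
  lm <- scene$landmarks[[1L]]
  jsonlite::write_json(
    list(points = unname(apply(lm$points, 1L, as.numeric, simplify = FALSE)),
         groups = lapply(lm$groups, function(i) as.integer(i - 1L))),
    file.path(path, "landmarks.json"), auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(list(truth_bpm = scene$truth_bpm,
                            frame_rate = scene$config$frame_rate,
                            ppg_rate = scene$config$ppg_rate,
                            seed = scene$config$seed),
                       file.path(path, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
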