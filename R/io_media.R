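#' Construct a video sequence
#'
#' A video sequence is an ordered list of 8-bit RGB frames sharing one
#' geometry, plus a frame rate. Frames are `H x W x 3` integer arrays with
#' intensities in `[0, 255]`; the channel order is RGB everywhere inside the
#' package, and any conversion from other conventions happens only at the
#' I/O boundary.
#'
#' @param frames list of `H x W x 3` integer arrays (RGB, 0--255).
#' @param frame_rate frames per second; must be positive.
#' @return An object of class `video_sequence` with elements `frames` and
#'   `frame_rate`.
#' @examples
#' f <- array(128L, dim = c(4, 4, 3))
#' v <- video_sequence(list(f, f), frame_rate = 25)
#' length(v$frames)
#' @export
video_sequence <- function(frames, frame_rate) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_pv("a video needs at least one frame", class = "empty_input_error")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop_pv("frame_rate must be a positive scalar", class = "config_error")
  d0 <- check_frame(frames[[1]])
  for (i in seq_along(frames)) {
    d <- check_frame(frames[[i]])
    if (!all(d == d0))
      stop_pv("frame %d has dimensions %dx%d, expected %dx%d", i,
              d[1], d[2], d0[1], d0[2], class = "dimension_error")
    if (!is.integer(frames[[i]])) {
      fi <- frames[[i]]
      storage.mode(fi) <- "integer"
      frames[[i]] <- fi
    }
  }
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate)),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_sequence> %d frames, %dx%d px, %.6g fps (%.2f s)\n",
              length(x$frames), d[1], d[2], x$frame_rate,
              length(x$frames) / x$frame_rate))
  invisible(x)
}

#' Construct a PPG record
#'
#' Holds a contact photoplethysmography waveform (arbitrary units) with its
#' sampling rate, e.g. a fingertip pulse-oximeter trace recorded at 60 Hz
#' alongside a 25 fps facial video.
#'
#' @param samples numeric vector of finite sample values.
#' @param sample_rate sampling rate in Hz; must be positive.
#' @param start_offset start time in seconds relative to the video start.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, sample_rate, start_offset = 0) {
  if (length(samples) < 1L)
    stop_pv("a PPG record needs at least one sample",
            class = "empty_record_error")
  if (!all(is.finite(samples)))
    stop_pv("PPG samples must be finite", class = "parse_error")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_pv("sample_rate must be a positive scalar", class = "config_error")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 start_offset = as.numeric(start_offset)),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

frame_file <- function(dir, i) file.path(dir, sprintf("frame_%06d.png", i))

#' Write a video sequence losslessly
#'
#' Frames are persisted as individual PNG files (`frame_000001.png`, ...)
#' plus a JSON sidecar `video.json` recording the frame rate, frame count
#' and channel order. PNG is lossless, so [read_video()] on the written
#' directory returns bit-identical pixels. Lossless persistence is a hard
#' contract here: lossy compression alters exactly the low-amplitude colour
#' variation that both the pulse signal and its concealment live in, so a
#' compressing writer would corrupt every downstream measurement.
#'
#' @param video a [video_sequence()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_video()]
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_sequence"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop_pv("cannot create directory '%s'", path, class = "io_error")
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]] / 255, target = frame_file(path, i))
  }
  sidecar <- list(frame_rate = video$frame_rate,
                  n_frames = length(video$frames),
                  channel_order = "RGB")
  jsonlite::write_json(sidecar, file.path(path, "video.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a video sequence from a lossless frame directory
#'
#' Reads a directory written by [write_video()]: numbered PNG frames plus a
#' `video.json` sidecar. Decoded pixel values are returned unaltered in RGB
#' order. If the sidecar is absent, `frame_rate` must be supplied.
#'
#' @param path directory containing numbered PNG frames.
#' @param frame_rate frame rate override in Hz; required when no sidecar
#'   exists, ignored otherwise.
#' @return A [video_sequence()].
#' @export
read_video <- function(path, frame_rate = NULL) {
  if (!dir.exists(path))
    stop_pv("'%s' is not a readable frame directory", path,
            class = "format_error")
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop_pv("no PNG frames found in '%s'", path, class = "empty_input_error")
  sidecar_path <- file.path(path, "video.json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path)
    rate <- as.numeric(sidecar$frame_rate)
    if (!identical(sidecar$channel_order, "RGB"))
      stop_pv("unsupported channel order '%s'", sidecar$channel_order,
              class = "format_error")
    if (length(files) != sidecar$n_frames)
      stop_pv("sidecar declares %d frames but %d found", sidecar$n_frames,
              length(files), class = "format_error")
  } else {
    if (is.null(frame_rate))
      stop_pv("no video.json sidecar: supply frame_rate explicitly",
              class = "config_error")
    rate <- frame_rate
  }
  frames <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
    a <- round_half_away(px * 255)
    storage.mode(a) <- "integer"
    a
  })
  video_sequence(frames, rate)
}

#' Read a ground-truth PPG record from delimited text
#'
#' Accepts either a two-column file (time-or-index, value) or a
#' single-column file of values. The sampling rate is taken from a header
#' line of the form `# rate_hz=<float>` when present, otherwise
#' `sample_rate` must be supplied. Rows that do not parse as finite numbers
#' are rejected with the offending row number.
#'
#' @param path path to a CSV/whitespace-delimited text file.
#' @param sample_rate sampling rate in Hz; overrides nothing, used only when
#'   the file carries no `# rate_hz=` header.
#' @return A [ppg_record()].
#' @export
read_ppg <- function(path, sample_rate = NULL) {
  if (!file.exists(path))
    stop_pv("'%s' does not exist", path, class = "format_error")
  lines <- readLines(path, warn = FALSE)
  rate <- sample_rate
  hdr <- grep("^#", lines)
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("rate_hz\\s*=\\s*([0-9.eE+-]+)", lines[h]))[[1]]
    if (length(m) == 2L) rate <- as.numeric(m[2])
  }
  if (is.null(rate) || !is.finite(rate))
    stop_pv("no '# rate_hz=' header in '%s': supply sample_rate", path,
            class = "config_error")
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    stop_pv("'%s' contains no data rows", path, class = "empty_record_error")
  values <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "[,;\t ]+")[[1]]
    v <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (length(v) != 1L || !is.finite(v))
      stop_pv("non-numeric or non-finite value at data row %d of '%s'",
              i, path, class = "parse_error")
    values[i] <- v
  }
  ppg_record(values, rate)
}

#' Write a PPG record as delimited text
#'
#' Writes a `# rate_hz=` header followed by `time,value` rows, the format
#' [read_ppg()] consumes. Values are written at full double precision so
#' the round trip is exact to within formatting (~1e-15 relative).
#'
#' @param ppg a [ppg_record()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_ppg <- function(ppg, path) {
  stopifnot(inherits(ppg, "ppg_record"))
  t <- ppg$start_offset + (seq_along(ppg$samples) - 1) / ppg$sample_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.17g", ppg$sample_rate), con)
  writeLines(sprintf("%.17g,%.17g", t, ppg$samples), con)
  invisible(path)
}
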