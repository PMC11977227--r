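#' Construct a landmark set
#'
#' Facial landmarks as sub-pixel `(x, y)` coordinates (0-based, origin at
#' the top-left pixel corner, x across columns, y down rows) plus named
#' semantic groups of indices into the point list. The groups mirror what a
#' face-mesh detector provides: `outer_face`, `left_eye`, `right_eye`,
#' `mouth`, `forehead`, `left_cheek`, `right_cheek`, `nose`.
#'
#' @param points numeric matrix with two columns (x, y).
#' @param groups named list of integer index vectors into `points`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, groups) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L)
    stop_pv("points must be an n x 2 matrix", class = "geometry_error")
  if (!is.list(groups) || is.null(names(groups)))
    stop_pv("groups must be a named list of indices", class = "geometry_error")
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(points)))
      stop_pv("group '%s' indexes outside the point list", g,
              class = "geometry_error")
  }
  structure(list(points = unname(points), groups = groups),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, groups: %s\n", nrow(x$points),
              paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

group_points <- function(lm, name) {
  idx <- lm$groups[[name]]
  if (is.null(idx) || length(idx) == 0L)
    stop_pv("landmark group '%s' is empty or missing", name,
            class = "geometry_error")
  lm$points[idx, , drop = FALSE]
}

roi_mask <- function(mask, roi_kind) {
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, roi_kind = roi_kind), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %dx%d, %d/%d pixels selected\n", x$roi_kind,
              nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$mask)))
  invisible(x)
}

# Convex hull of a point set, ordered counter-clockwise in the image
# coordinate frame. Errors when fewer than 3 non-collinear points exist.
convex_hull_ccw <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L)
    stop_pv("convex hull needs at least 3 distinct points",
            class = "geometry_error")
  h <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  if (nrow(h) < 3L)
    stop_pv("degenerate hull: points are collinear", class = "geometry_error")
  v <- nrow(h)
  area2 <- sum(h[, 1] * h[c(2:v, 1), 2] - h[c(2:v, 1), 1] * h[, 2])
  if (abs(area2) < 1e-12)
    stop_pv("degenerate hull: points are collinear", class = "geometry_error")
  if (area2 < 0) h <- h[v:1, , drop = FALSE]
  h
}

# Rasterize a filled convex polygon onto an m x n pixel grid. A pixel
# belongs to the polygon iff its center (x + 0.5, y + 0.5) lies inside or
# on the boundary (half-plane tests with a 1e-9 slack). Returns an m x n
# 0/1 integer matrix.
rasterize_convex <- function(pts, shape) {
  m <- shape[1]; n <- shape[2]
  h <- convex_hull_ccw(pts)
  v <- nrow(h)
  xmin <- max(0L, floor(min(h[, 1]) - 0.5))
  xmax <- min(n - 1L, ceiling(max(h[, 1]) - 0.5))
  ymin <- max(0L, floor(min(h[, 2]) - 0.5))
  ymax <- min(m - 1L, ceiling(max(h[, 2]) - 0.5))
  out <- matrix(0L, m, n)
  if (xmax < xmin || ymax < ymin) return(out)
  xs <- seq.int(xmin, xmax); ys <- seq.int(ymin, ymax)
  cx <- rep(xs + 0.5, each = length(ys))
  cy <- rep(ys + 0.5, times = length(xs))
  inside <- rep(TRUE, length(cx))
  for (e in seq_len(v)) {
    a <- h[e, ]; b <- h[if (e == v) 1L else e + 1L, ]
    cross <- (b[1] - a[1]) * (cy - a[2]) - (b[2] - a[2]) * (cx - a[1])
    inside <- inside & (cross >= -1e-9)
  }
  sub <- matrix(as.integer(inside), nrow = length(ys))
  out[ys + 1L, xs + 1L] <- sub
  out
}

#' Full-frame region of interest
#'
#' The trivial ROI: every pixel of the frame is eligible for modification.
#'
#' @param frame an `H x W x 3` frame array, or an object with dimensions.
#' @return An `roi_mask` of all ones with `roi_kind = "full_frame"`.
#' @export
full_frame_mask <- function(frame) {
  d <- frame_dims(frame)
  roi_mask(matrix(1L, d[1], d[2]), "full_frame")
}

#' Facial-skin region of interest
#'
#' The facial-skin ROI is the filled convex hull of all mesh points with the
#' eye and mouth polygons removed — everything on the face except the eyes
#' and mouth. Exclusion polygons are the filled convex hulls of their
#' landmark groups, which makes the construction robust to landmark
#' ordering.
#'
#' @param landmarks a [landmark_set()] with `left_eye`, `right_eye` and
#'   `mouth` groups populated.
#' @param shape integer vector `c(height, width)` of the target frame.
#' @return An `roi_mask` with `roi_kind = "facial_skin"`.
#' @export
facial_skin_mask <- function(landmarks, shape) {
  stopifnot(inherits(landmarks, "landmark_set"))
  face <- rasterize_convex(landmarks$points, shape)
  for (g in c("left_eye", "right_eye", "mouth")) {
    idx <- landmarks$groups[[g]]
    if (is.null(idx) || length(idx) == 0L) next
    excl <- rasterize_convex(landmarks$points[idx, , drop = FALSE], shape)
    face[excl == 1L] <- 0L
  }
  roi_mask(face, "facial_skin")
}

#' Forehead-and-cheeks region of interest
#'
#' The most selective ROI: the union of three separately filled convex
#' hulls over the forehead, left-cheek and right-cheek landmark groups —
#' the regions most strongly modulated by blood volume.
#'
#' @inheritParams facial_skin_mask
#' @return An `roi_mask` with `roi_kind = "forehead_cheeks"`.
#' @export
forehead_cheeks_mask <- function(landmarks, shape) {
  stopifnot(inherits(landmarks, "landmark_set"))
  acc <- matrix(0L, shape[1], shape[2])
  for (g in c("forehead", "left_cheek", "right_cheek")) {
    hull <- rasterize_convex(group_points(landmarks, g), shape)
    acc[hull == 1L] <- 1L
  }
  roi_mask(acc, "forehead_cheeks")
}

#' Build an ROI mask of a given kind
#'
#' Dispatch helper used by the video pipeline: `full_frame` needs no
#' landmarks; the other kinds are built from the supplied landmark set.
#'
#' @param roi_kind one of `"full_frame"`, `"facial_skin"`,
#'   `"forehead_cheeks"`.
#' @param frame the target frame (for its dimensions).
#' @param landmarks a [landmark_set()]; ignored for `full_frame`.
#' @return An `roi_mask`.
#' @export
make_roi_mask <- function(roi_kind, frame, landmarks = NULL) {
  d <- frame_dims(frame)
  switch(roi_kind,
    full_frame = full_frame_mask(frame),
    facial_skin = facial_skin_mask(landmarks, d[1:2]),
    forehead_cheeks = forehead_cheeks_mask(landmarks, d[1:2]),
    stop_pv("unknown roi_kind '%s'", roi_kind, class = "config_error"))
}

#' Detect landmarks on a frame through a provider
#'
#' Landmark detection is pluggable: a provider is a function
#' `function(frame, index)` returning a [landmark_set()] (for example
#' [scene_landmark_provider()], which replays a synthetic scene's exact
#' geometry). An adapter around an external face-mesh detector fits the
#' same interface; none is bundled because the test path must run offline.
#'
#' @param frame the frame to detect on.
#' @param provider a function `(frame, index) -> landmark_set`.
#' @param index 0-based frame index, forwarded to the provider and included
#'   in error messages.
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(frame, provider, index = 0L) {
  if (!is.function(provider))
    stop_pv("provider must be a function(frame, index)", class = "config_error")
  lm <- tryCatch(provider(frame, index), error = function(e)
    stop_pv("landmark detection failed at frame %d: %s", index,
            conditionMessage(e), class = "detection_error"))
  if (!inherits(lm, "landmark_set"))
    stop_pv("no face found at frame %d", index, class = "detection_error")
  lm
}

#' Export an ROI mask as a PNG for inspection
#'
#' Selected pixels are written as 255, others 0.
#'
#' @param mask an `roi_mask`.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(mask$mask * 1.0, target = path)
  invisible(path)
}
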