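#' Line ROI along a dendrite
#'
#' A segmented-line region of interest: an ordered polyline in pixel
#' coordinates (`x` = column, `y` = row, 1-based) with a sampling width.
#' Dendritic segments are traced with a wide line (default 50 px) so the
#' profile at each arc-length step is the mean over the perpendicular.
#'
#' @param points numeric matrix (or two-column data frame) of `(x, y)`
#'   vertices, at least 2 rows.
#' @param width_px sampling width in pixels (>= 1).
#' @return a list of class `line_roi`.
#' @export
line_roi <- function(points, width_px = 50) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  check_that(nrow(points) >= 2L, "points", "need at least 2 vertices")
  check_that(width_px >= 1, "width_px", "must be >= 1")
  seg <- sqrt(rowSums(diff(points)^2))
  check_that(all(seg > 0), "points", "consecutive vertices must be distinct")
  colnames(points) <- c("x", "y")
  structure(list(points = points, width_px = as.integer(round(width_px))),
            class = "line_roi")
}

#' Kymograph container
#' @param values frames x positions matrix (AU).
#' @param fps frames per second.
#' @param px_size micrometres per pixel.
#' @param frame_range first and last source frame index.
#' @return a list of class `kymograph`.
#' @export
kymograph <- function(values, fps = default_fps(), px_size = default_px_size(),
                      frame_range = c(1L, nrow(values))) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)))
  structure(list(values = values, fps = fps, px_size = px_size,
                 frame_range = as.integer(frame_range)),
            class = "kymograph")
}

# Arc-length sample points (step 1 px) along a polyline plus the local unit
# perpendicular, mirroring segmented-line profile semantics (per-segment
# direction; total length rounded down to whole px).
.polyline_samples <- function(points) {
  d <- diff(points)
  seg_len <- sqrt(rowSums(d^2))
  total <- sum(seg_len)
  arc <- seq(0, floor(total), by = 1)
  cum <- c(0, cumsum(seg_len))
  seg_idx <- pmin(findInterval(arc, cum, rightmost.closed = TRUE),
                  length(seg_len))
  t_loc <- (arc - cum[seg_idx]) / seg_len[seg_idx]
  ux <- d[, 1] / seg_len
  uy <- d[, 2] / seg_len
  list(x = points[seg_idx, 1] + t_loc * d[seg_idx, 1],
       y = points[seg_idx, 2] + t_loc * d[seg_idx, 2],
       # perpendicular: rotate the tangent by +90 degrees
       px = -uy[seg_idx], py = ux[seg_idx])
}

# Bilinear interpolation of matrix `img` at real-valued (x = col, y = row).
# Coordinates within 1e-9 of a pixel centre are snapped so that axis-aligned
# integer sampling reproduces raster values exactly.
.bilinear <- function(img, x, y) {
  xr <- round(x); yr <- round(y)
  x <- ifelse(abs(x - xr) < 1e-9, xr, x)
  y <- ifelse(abs(y - yr) < 1e-9, yr, y)
  x1 <- floor(x); y1 <- floor(y)
  x2 <- pmin(x1 + 1, ncol(img)); y2 <- pmin(y1 + 1, nrow(img))
  fx <- x - x1; fy <- y - y1
  img[cbind(y1, x1)] * (1 - fx) * (1 - fy) +
    img[cbind(y1, x2)] * fx * (1 - fy) +
    img[cbind(y2, x1)] * (1 - fx) * fy +
    img[cbind(y2, x2)] * fx * fy
}

#' Extract a kymograph along a wide line ROI
#'
#' Reproduces stack-profile semantics: for every frame, the intensity profile
#' along the polyline is computed at 1-px arc-length steps, where each value
#' is the mean of `width_px` bilinear samples taken along the local
#' perpendicular. Profiles are stacked into a frames x positions matrix.
#'
#' @param movie 3-D array `[rows, cols, frames]` or list of matrices.
#' @param roi a [line_roi()].
#' @param frame_range optional `c(first, last)` frames to use.
#' @param fps,px_size temporal and spatial calibration.
#' @return a [kymograph()].
#' @export
extract_kymograph <- function(movie, roi, frame_range = NULL,
                              fps = default_fps(), px_size = default_px_size()) {
  stopifnot(inherits(roi, "line_roi"))
  if (is.list(movie)) movie <- simplify2array(movie)
  stopifnot(length(dim(movie)) == 3L)
  nf <- dim(movie)[3]
  if (is.null(frame_range)) frame_range <- c(1L, nf)
  check_that(length(frame_range) == 2L && frame_range[1] >= 1 &&
               frame_range[2] <= nf && frame_range[1] <= frame_range[2],
             "frame_range", "must be a valid, non-empty frame interval")
  sp <- .polyline_samples(roi$points)
  w <- roi$width_px
  off <- seq_len(w) - (w + 1) / 2
  xs <- sp$x + outer(sp$px, off)   # positions x offsets
  ys <- sp$y + outer(sp$py, off)
  if (min(xs) < 1 || max(xs) > dim(movie)[2] ||
      min(ys) < 1 || max(ys) > dim(movie)[1]) {
    stop("ROI (with width) falls outside the image bounds", call. = FALSE)
  }
  frames <- frame_range[1]:frame_range[2]
  vals <- matrix(0, nrow = length(frames), ncol = length(sp$x))
  for (i in seq_along(frames)) {
    samp <- .bilinear(movie[, , frames[i]], as.vector(xs), as.vector(ys))
    vals[i, ] <- rowMeans(matrix(samp, nrow = length(sp$x)))
  }
  kymograph(vals, fps = fps, px_size = px_size, frame_range = frame_range)
}

#' Baseline-normalise a kymograph to ΔF/F0
#'
#' F0 is computed per position: either the mean over an explicit set of
#' event-free baseline frames, or (default) the mean of that position's
#' lowest-decile frames, which approximates the fluorescence of the ROI "in
#' an inactive state" without manual frame selection.
#'
#' @param kymo a [kymograph()].
#' @param baseline_frames integer frame indices known to contain no events,
#'   or `NULL` for the automatic per-position lowest-decile rule.
#' @return a list of class `dff_kymograph` with `dff` (frames x positions),
#'   `f0` (per-position baseline) and `baseline_frames`.
#' @export
compute_dff <- function(kymo, baseline_frames = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  v <- kymo$values
  if (is.null(baseline_frames)) {
    f0 <- apply(v, 2, function(col) {
      q <- stats::quantile(col, 0.1, names = FALSE, type = 7)
      mean(col[col <= q])
    })
    bl <- "auto-p10"
  } else {
    stopifnot(all(baseline_frames >= 1), all(baseline_frames <= nrow(v)))
    f0 <- colMeans(v[baseline_frames, , drop = FALSE])
    bl <- as.integer(baseline_frames)
  }
  if (any(f0 <= 0)) {
    stop("baseline F0 <= 0 at ", sum(f0 <= 0), " position(s)", call. = FALSE)
  }
  structure(list(dff = sweep(sweep(v, 2, f0), 2, f0, "/"),
                 f0 = f0, baseline_frames = bl,
                 fps = kymo$fps, px_size = kymo$px_size),
            class = "dff_kymograph")
}
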