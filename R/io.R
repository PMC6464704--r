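#' Write / read a movie as multi-page TIFF
#'
#' Movies are stored as 32-bit float multi-page greyscale TIFF after
#' dividing by `scale`, which is recorded in a JSON sidecar so AU values
#' round-trip.
#'
#' @param movie array `[rows, cols, frames]` (AU).
#' @param path output `.tif` path.
#' @param scale divisor mapping AU into the unit range.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie) * 1.01) {
  stopifnot(length(dim(movie)) == 3L, scale > 0)
  pages <- lapply(seq_len(dim(movie)[3]), function(f) movie[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path `.tif` path written by [write_movie_tiff()].
#' @rdname write_movie_tiff
#' @return `read_movie_tiff()`: the movie array in AU.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    scale <- jsonlite::read_json(sidecar)$scale
  }
  simplify2array(pages) * scale
}

#' Write / read a line ROI as JSON
#'
#' Format: `{"points": [[x, y], ...], "width_px": n}` with 1-based pixel
#' coordinates.
#'
#' @param roi a [line_roi()].
#' @param path output `.json` path.
#' @return `path` (write) or a [line_roi()] (read).
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "line_roi"))
  jsonlite::write_json(
    list(points = unname(apply(roi$points, 1, as.numeric, simplify = FALSE)),
         width_px = roi$width_px),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path)
  pts <- do.call(rbind, lapply(j$points, function(p) c(p[[1]], p[[2]])))
  line_roi(pts, j$width_px)
}

#' Write / read an EPSC trace as CSV
#'
#' Columns `time_ms`, `current_pA`; the stimulus onset travels in a comment
#' header line `# stim_onset_ms=<value>`.
#'
#' @param trace an [epsc_trace()].
#' @param path output `.csv` path.
#' @return `path` (write) or an [epsc_trace()] (read).
#' @export
write_epsc_csv <- function(trace, path) {
  stopifnot(inherits(trace, "epsc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stim_onset_ms=%.10g", trace$stim_onset), con)
  utils::write.csv(data.frame(time_ms = trace$time,
                              current_pA = trace$current),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epsc_csv
#' @export
read_epsc_csv <- function(path) {
  first <- readLines(path, n = 1L)
  onset <- if (startsWith(first, "# stim_onset_ms=")) {
    as.numeric(sub("# stim_onset_ms=", "", first))
  } else {
    stop("missing `# stim_onset_ms=` header in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  epsc_trace(df$time_ms, df$current_pA, onset)
}
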