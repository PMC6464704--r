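#' Spatial and temporal calibration
#'
#' The imaging setup these pipelines were designed around acquires at
#' approximately 7 frames per second with a pixel pitch of 10/65 micrometres
#' (65 pixels span 10 um). Both values are configurable everywhere they are
#' used; these helpers centralise the conversion.
#'
#' @param n_px number of pixels.
#' @param px_size micrometres per pixel.
#' @return `px_to_um()`: distance in micrometres.
#' @examples
#' px_to_um(65)           # 10 um
#' frames_to_seconds(350) # 50 s
#' @export
px_to_um <- function(n_px, px_size = default_px_size()) {
  stopifnot(px_size > 0)
  n_px * px_size
}

#' @param n_frames number of movie frames.
#' @param fps frames per second.
#' @return `frames_to_seconds()`: duration in seconds.
#' @rdname px_to_um
#' @export
frames_to_seconds <- function(n_frames, fps = default_fps()) {
  stopifnot(fps > 0)
  n_frames / fps
}

#' @rdname px_to_um
#' @export
default_px_size <- function() 10 / 65

#' @rdname px_to_um
#' @export
default_fps <- function() 7
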