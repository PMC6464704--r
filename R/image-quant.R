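#' Quantify AL and lysosome load in one soma
#'
#' Reproduces the fixed-threshold, particle-based soma work-up: each channel
#' is thresholded with the shared [threshold_spec()]; cytosolic area is the
#' soma (MAP2) mask area minus the nucleus (DAPI) mask area; AL deposits and
#' lysosomes are counted with their respective particle presets restricted
#' to the soma ROI; percentages are particle area over cytosolic area.
#'
#' @param channels named list of matrices with at least `soma`, `nucleus`,
#'   `al`; `lysosome` optional.
#' @param spec a [threshold_spec()] covering the channels present.
#' @param soma_roi optional logical matrix overriding the thresholded soma
#'   channel as the soma ROI.
#' @return list: `cytosol_area` (px^2), `pct_al_area`, `n_al`,
#'   `al_positive`, and when a lysosome channel is present
#'   `pct_lysosome_area`, `n_lysosomes`, `mean_lysosome_area`.
#' @export
quantify_soma <- function(channels, spec, soma_roi = NULL) {
  stopifnot(is.list(channels),
            all(c("soma", "nucleus", "al") %in% names(channels)))
  soma_mask <- soma_roi %||% threshold_mask(channels$soma, spec, "soma")
  nuc_mask <- threshold_mask(channels$nucleus, spec, "nucleus")
  cytosol_area <- sum(soma_mask) - sum(nuc_mask & soma_mask)
  if (cytosol_area <= 0) {
    stop("degenerate cell: cytosolic area <= 0", call. = FALSE)
  }
  al_mask <- threshold_mask(channels$al, spec, "al") & soma_mask
  al <- find_particles(al_mask, preset = "al")
  out <- list(cytosol_area = cytosol_area,
              pct_al_area = 100 * sum(al$area) / cytosol_area,
              n_al = nrow(al), al_positive = nrow(al) >= 1)
  if ("lysosome" %in% names(channels)) {
    lys_mask <- threshold_mask(channels$lysosome, spec, "lysosome") & soma_mask
    lys <- find_particles(lys_mask, preset = "lysosome")
    out$pct_lysosome_area <- 100 * sum(lys$area) / cytosol_area
    out$n_lysosomes <- nrow(lys)
    out$mean_lysosome_area <- if (nrow(lys)) mean(lys$area) else NA_real_
  }
  out
}

#' Percent AL area across a cortical-column image set
#'
#' Per image, the percentage of pixels (of the whole image, or of each layer
#' ROI) whose AL signal satisfies the shared threshold; the column value is
#' the mean across images — one value per animal in the original design.
#'
#' @param images list of AL-channel matrices acquired under identical
#'   conditions.
#' @param spec a [threshold_spec()] with an `al` cutoff (or a single number).
#' @param layer_rois optional named list of `list(rows =, cols =)` rectangles
#'   delimiting cortical layers.
#' @return list: `per_image` (percent per image), `mean_pct`, and
#'   `per_layer` (matrix images x layers) when layer ROIs are given.
#' @export
percent_area_column <- function(images, spec, layer_rois = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  pct <- vapply(images, function(img) {
    100 * mean(threshold_mask(img, spec, "al"))
  }, numeric(1))
  out <- list(per_image = pct, mean_pct = mean(pct))
  if (!is.null(layer_rois)) {
    cover <- matrix(0L, nrow(images[[1]]), ncol(images[[1]]))
    for (r in layer_rois) cover[r$rows, r$cols] <- cover[r$rows, r$cols] + 1L
    if (any(cover > 1L)) warning("layer ROIs overlap")
    out$per_layer <- t(vapply(images, function(img) {
      m <- threshold_mask(img, spec, "al")
      vapply(layer_rois, function(r) {
        100 * mean(m[r$rows, r$cols])
      }, numeric(1))
    }, numeric(length(layer_rois))))
    if (length(layer_rois) == 1L) out$per_layer <- t(out$per_layer)
    dimnames(out$per_layer) <- list(NULL, names(layer_rois))
  }
  out
}

#' Multi-channel line scan
#'
#' Samples every channel along the same 1-px line ROI (bilinear
#' interpolation at 1-px arc steps) so the per-channel intensity profiles
#' share one position axis, as in plot-profile colocalization figures.
#'
#' @param channels named list of matrices.
#' @param roi a [line_roi()]; its width is ignored (width-1 semantics).
#' @return data frame with `position_px` and one column per channel.
#' @export
line_scan <- function(channels, roi) {
  stopifnot(is.list(channels), length(channels) >= 1,
            inherits(roi, "line_roi"))
  sp <- .polyline_samples(roi$points)
  dims <- dim(channels[[1]])
  if (min(sp$x) < 1 || max(sp$x) > dims[2] ||
      min(sp$y) < 1 || max(sp$y) > dims[1]) {
    stop("line ROI falls outside the image bounds", call. = FALSE)
  }
  out <- data.frame(position_px = seq_along(sp$x) - 1L)
  for (nm in names(channels)) {
    stopifnot(identical(dim(channels[[nm]]), dims))
    out[[nm]] <- .bilinear(channels[[nm]], sp$x, sp$y)
  }
  out
}
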