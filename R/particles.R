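#' Per-channel threshold specification
#'
#' Grey-level cutoffs applied identically to every image of a comparison
#' set — automatic thresholding is deliberately not offered, mirroring the
#' fixed-threshold convention of the quantification these functions
#' reproduce.
#'
#' @param cutoffs named numeric vector of per-channel cutoffs (AU).
#' @param note free-text provenance note (who chose the cutoffs and how).
#' @return a list of class `threshold_spec`.
#' @export
threshold_spec <- function(cutoffs, note = "") {
  stopifnot(is.numeric(cutoffs), !is.null(names(cutoffs)),
            all(nzchar(names(cutoffs))))
  structure(list(cutoffs = cutoffs, note = note), class = "threshold_spec")
}

#' Binary mask from a grey-level cutoff
#'
#' @param img numeric matrix (AU).
#' @param spec a [threshold_spec()] or a single numeric cutoff.
#' @param channel channel name to look up when `spec` is a `threshold_spec`.
#' @return logical matrix; `TRUE` where `img >= cutoff`.
#' @export
threshold_mask <- function(img, spec, channel = NULL) {
  cutoff <- if (inherits(spec, "threshold_spec")) {
    if (is.null(channel) || !channel %in% names(spec$cutoffs)) {
      stop("no threshold configured for channel `", channel %||% "<missing>",
           "`", call. = FALSE)
    }
    spec$cutoffs[[channel]]
  } else {
    stopifnot(is.numeric(spec), length(spec) == 1L)
    spec
  }
  img >= cutoff
}

# zero-padded shift helper used by the label propagation; background slots
# are filled with Inf so pmin ignores them
.shift_inf <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(Inf, H, W)
  ty <- max(1, 1 + dy):min(H, H + dy); tx <- max(1, 1 + dx):min(W, W + dx)
  sy <- max(1, 1 - dy):min(H, H - dy); sx <- max(1, 1 - dx):min(W, W - dx)
  out[ty, tx] <- m[sy, sx]
  out
}

#' Label 8-connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 8-neighbourhood until a
#' fixed point; components are then renumbered 1..k in raster order.
#' "Adjacent" pixels are 8-neighbours throughout, matching the particle
#' analyser convention these filters were written against.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  lab[mask] <- which(mask)
  nbrs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in nbrs) new <- pmin(new, .shift_inf(lab, s[1], s[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, H, W)
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- as.integer(match(ids, sort(unique(ids))))
  }
  out
}

# Moore boundary trace of a single component given as a logical matrix.
# Returns the clockwise chain of (dy, dx) steps; length 0 for one pixel.
.boundary_chain <- function(comp) {
  pad <- matrix(FALSE, nrow(comp) + 2L, ncol(comp) + 2L)
  pad[2:(nrow(comp) + 1L), 2:(ncol(comp) + 1L)] <- comp
  idx <- which(pad, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  # Moore neighbourhood in clockwise order beginning west
  moore <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  back_dir <- 1L            # entered from the west
  first_move <- NULL
  steps <- NULL
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      j <- ((back_dir - 1L + k - 1L) %% 8L) + 1L
      nb <- cur + moore[j, ]
      if (pad[nb[1], nb[2]]) {
        step <- moore[j, ]
        prev_j <- ((j - 2L) %% 8L) + 1L
        if (is.null(first_move)) first_move <- c(start, step)
        else if (all(cur == start) && all(step == first_move[3:4])) {
          return(steps)    # Jacob's stopping criterion
        }
        steps <- rbind(steps, step)
        # backtrack for the next scan: the neighbour examined just before
        # the hit, expressed relative to the new current pixel (consecutive
        # ring cells are always 8-adjacent, so this is a unit offset)
        off <- moore[prev_j, ] - moore[j, ]
        back_dir <- which(moore[, 1] == off[1] & moore[, 2] == off[2])
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(steps)          # isolated pixel
    if (nrow(steps) > 8L * sum(comp) + 8L) return(steps)  # safety stop
  }
}

# Boundary-chain perimeter with the Vossepoel-Smeulders corner correction:
# 0.980 per axial step + 1.406 per diagonal step - 0.091 per direction
# change. Converges to the true outline length for smooth shapes.
.chain_perimeter <- function(steps) {
  if (is.null(steps) || nrow(steps) == 0L) return(4)   # single pixel outline
  diag <- steps[, 1] != 0 & steps[, 2] != 0
  n_even <- sum(!diag); n_odd <- sum(diag)
  nxt <- rbind(steps[-1, , drop = FALSE], steps[1, , drop = FALSE])
  corners <- sum(steps[, 1] != nxt[, 1] | steps[, 2] != nxt[, 2])
  max(0.980 * n_even + 1.406 * n_odd - 0.091 * corners, 1e-6)
}

#' Particle analysis with size and circularity filters
#'
#' Finds 8-connected components of a binary mask and computes per-particle
#' area, boundary-chain perimeter, circularity `4 * pi * area / perimeter^2`
#' (clamped to 1 to absorb rasterization overshoot) and centroid, then
#' retains particles passing the filters. Presets encode the study's rules:
#' `"al"` keeps autofluorescent-lipopigment deposits of more than eight
#' adjacent pixels (area >= 9) with circularity > 0.4; `"lysosome"` keeps
#' circularity > 0.5 at any size (so clusters of lysosomes are not counted
#' as one unit).
#'
#' @param mask logical matrix.
#' @param min_pixels minimum component size in pixels (inclusive).
#' @param circ_min exclusive lower circularity bound.
#' @param circ_max inclusive upper circularity bound.
#' @param preset `"al"`, `"lysosome"`, or `NULL` to use the explicit bounds.
#' @return data frame with `label`, `area`, `perimeter`, `circularity`,
#'   `centroid_x`, `centroid_y` and a list-column `pixels` of linear indices.
#' @export
find_particles <- function(mask, min_pixels = 1, circ_min = 0, circ_max = 1,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("al", "lysosome"))
    if (preset == "al") { min_pixels <- 9; circ_min <- 0.4 }
    else { min_pixels <- 1; circ_min <- 0.5 }
    circ_max <- 1
  }
  lab <- label_components(mask)
  k <- max(lab)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    pix <- which(lab == i)
    area <- length(pix)
    rc <- arrayInd(pix, dim(lab))
    comp <- matrix(FALSE, diff(range(rc[, 1])) + 1L, diff(range(rc[, 2])) + 1L)
    comp[cbind(rc[, 1] - min(rc[, 1]) + 1L, rc[, 2] - min(rc[, 2]) + 1L)] <- TRUE
    per <- .chain_perimeter(.boundary_chain(comp))
    circ <- min(4 * pi * area / per^2, 1)
    rows[[i]] <- data.frame(label = i, area = area, perimeter = per,
                            circularity = circ,
                            centroid_x = mean(rc[, 2]),
                            centroid_y = mean(rc[, 1]))
    rows[[i]]$pixels <- I(list(pix))
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(label = integer(), area = integer(), perimeter = numeric(),
               circularity = numeric(), centroid_x = numeric(),
               centroid_y = numeric(), pixels = I(list()))
  keep <- out$area >= min_pixels & out$circularity > circ_min &
    out$circularity <= circ_max
  out[keep, , drop = FALSE]
}
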