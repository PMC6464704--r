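#' Parameters for the synthetic soma image generator
#'
#' Produces a four-channel image emulating a cultured neuron soma: a soma
#' disc (MAP2-like), a nucleus disc inside it (DAPI-like), circular
#' lysosome puncta (LAMP-2-like) and round-to-irregular autofluorescent
#' lipopigment (AL) deposits, all on a low constant background. Every
#' punctum is recorded in the ground truth with its pixel set, area and
#' circularity so particle quantification can be scored against it.
#'
#' @param image_size side of the square image (px).
#' @param n_al number of AL deposits.
#' @param al_radius_range `c(min, max)` AL radius (px).
#' @param al_irregularity radial perturbation amplitude (0 = perfect discs).
#' @param n_lysosomes number of lysosome puncta.
#' @param lys_radius_range `c(min, max)` lysosome radius (px).
#' @param soma_mask_radius soma disc radius (px).
#' @param nucleus_radius nucleus disc radius (px), smaller than the soma.
#' @param channel_intensities named AU vector for `soma`, `nucleus`,
#'   `lysosome`, `al` foreground signal.
#' @param background background level (AU) in every channel.
#' @param seed integer seed.
#' @return a list of class `soma_sim_params`.
#' @export
soma_sim_params <- function(image_size = 192, n_al = 5,
                            al_radius_range = c(3, 6), al_irregularity = 0.3,
                            n_lysosomes = 8, lys_radius_range = c(2, 4),
                            soma_mask_radius = 70, nucleus_radius = 25,
                            channel_intensities = c(soma = 120, nucleus = 200,
                                                    lysosome = 180, al = 160),
                            background = 5, seed = 1L) {
  check_that(image_size >= 32, "image_size", "must be >= 32 px")
  check_that(n_al >= 0 && n_lysosomes >= 0, "n_al/n_lysosomes", "must be >= 0")
  check_that(all(al_radius_range > 0) && all(lys_radius_range > 0),
             "radius ranges", "must be > 0")
  check_that(al_irregularity >= 0, "al_irregularity", "must be >= 0")
  check_that(nucleus_radius > 0 && nucleus_radius < soma_mask_radius,
             "nucleus_radius", "nucleus must fit inside the soma")
  check_that(soma_mask_radius < image_size / 2, "soma_mask_radius",
             "soma must fit inside the image")
  check_that(all(c("soma", "nucleus", "lysosome", "al") %in%
                   names(channel_intensities)),
             "channel_intensities", "must name soma, nucleus, lysosome, al")
  check_that(background >= 0 &&
               background < min(channel_intensities), "background",
             "must be below every channel intensity")
  structure(list(image_size = as.integer(image_size), n_al = as.integer(n_al),
                 al_radius_range = al_radius_range,
                 al_irregularity = al_irregularity,
                 n_lysosomes = as.integer(n_lysosomes),
                 lys_radius_range = lys_radius_range,
                 soma_mask_radius = soma_mask_radius,
                 nucleus_radius = nucleus_radius,
                 channel_intensities = channel_intensities,
                 background = background, seed = as.integer(seed)),
            class = "soma_sim_params")
}

# rasterize a (possibly irregular) blob: pixels whose distance to (cy, cx)
# is <= r0 * (1 + irregularity * smooth periodic noise of the angle)
.raster_blob <- function(size, cy, cx, r0, irregularity = 0) {
  y <- matrix(seq_len(size), size, size)
  x <- t(y)
  d <- sqrt((y - cy)^2 + (x - cx)^2)
  if (irregularity > 0) {
    theta <- atan2(y - cy, x - cx)
    a <- stats::runif(3, -1, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    wob <- (a[1] * sin(2 * theta + ph[1]) + a[2] * sin(3 * theta + ph[2]) +
              a[3] * sin(5 * theta + ph[3])) / sum(abs(a))
    r <- r0 * (1 + irregularity * wob)
  } else {
    r <- r0
  }
  d <= r
}

# independent truth circularity: perimeter from the 0.5-level iso-contour of
# the mask (grDevices contouring), not from the analysis module's chain code
.truth_circularity <- function(mask) {
  area <- sum(mask)
  if (area <= 1) return(1)
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  cl <- grDevices::contourLines(seq_len(nrow(m)), seq_len(ncol(m)), m,
                                levels = 0.5)
  if (!length(cl)) return(1)
  per <- max(vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1)))
  min(4 * pi * area / per^2, 1)
}

#' Generate a synthetic multi-channel soma image
#'
#' Puncta are placed uniformly in the cytosol (inside the soma, outside the
#' nucleus) without overlap within a channel; placement is retried a bounded
#' number of times and fails with an error if the requested puncta cannot
#' fit.
#'
#' @param params a [soma_sim_params()] object.
#' @return list with `channels` (named list of matrices: `soma`, `nucleus`,
#'   `lysosome`, `al`) and `truth` (per-particle pixel sets, areas,
#'   circularities, the soma/nucleus/cytosol pixel areas, and the true AL
#'   percent of cytosol area).
#' @export
gen_soma_image <- function(params) {
  stopifnot(inherits(params, "soma_sim_params"))
  p <- params
  S <- p$image_size
  c0 <- (S + 1) / 2
  soma_mask <- .raster_blob(S, c0, c0, p$soma_mask_radius)
  nuc_mask <- .raster_blob(S, c0, c0, p$nucleus_radius)

  with_seed(p$seed, {
    place <- function(n, rad_range, irregularity, occupied) {
      out <- vector("list", n)
      geom <- data.frame(center_y = numeric(n), center_x = numeric(n),
                         radius = numeric(n))
      for (i in seq_len(n)) {
        done <- FALSE
        for (try in seq_len(200L)) {
          r0 <- stats::runif(1, rad_range[1], rad_range[2])
          rmax <- r0 * (1 + irregularity)
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1)) * (p$soma_mask_radius - rmax - 2)
          cy <- c0 + rr * sin(ang); cx <- c0 + rr * cos(ang)
          if (rr - rmax - 1 < p$nucleus_radius) next  # keep out of the nucleus
          m <- .raster_blob(S, cy, cx, r0, irregularity)
          if (!any(m & occupied)) {
            occupied <- occupied | m
            out[[i]] <- m
            geom[i, ] <- c(cy, cx, r0)
            done <- TRUE
            break
          }
        }
        if (!done) {
          stop("could not place punctum ", i, " after bounded retries",
               call. = FALSE)
        }
      }
      list(masks = out, geom = geom, occupied = occupied)
    }
    lys <- place(p$n_lysosomes, p$lys_radius_range, 0, nuc_mask | !soma_mask)
    al <- place(p$n_al, p$al_radius_range, p$al_irregularity, lys$occupied)

    bg <- p$background
    ci <- p$channel_intensities
    chan <- function(mask, level) {
      m <- matrix(bg, S, S)
      m[mask] <- level
      m
    }
    al_mask <- Reduce(`|`, al$masks, matrix(FALSE, S, S))
    lys_mask <- Reduce(`|`, lys$masks, matrix(FALSE, S, S))
    channels <- list(soma = chan(soma_mask, ci[["soma"]]),
                     nucleus = chan(nuc_mask, ci[["nucleus"]]),
                     lysosome = chan(lys_mask, ci[["lysosome"]]),
                     al = chan(al_mask, ci[["al"]]))

    particle_truth <- function(placed, channel) {
      masks <- placed$masks
      if (!length(masks)) {
        return(data.frame(channel = character(), area = integer(),
                          circularity = numeric(), center_y = numeric(),
                          center_x = numeric(), radius = numeric()))
      }
      df <- do.call(rbind, lapply(masks, function(m) {
        data.frame(channel = channel, area = sum(m),
                   circularity = .truth_circularity(m))
      }))
      df <- cbind(df, placed$geom)
      df$pixels <- I(lapply(masks, which))
      df
    }
    cytosol_area <- sum(soma_mask & !nuc_mask)
    truth <- list(params = unclass(p),
                  al = particle_truth(al, "al"),
                  lysosome = particle_truth(lys, "lysosome"),
                  soma_area = sum(soma_mask),
                  nucleus_area = sum(nuc_mask),
                  cytosol_area = cytosol_area,
                  pct_al_area = 100 * sum(al_mask & soma_mask) / cytosol_area,
                  pct_lysosome_area =
                    100 * sum(lys_mask & soma_mask) / cytosol_area)
    list(channels = channels, truth = truth)
  })
}
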