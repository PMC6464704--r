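#' Parameters for the synthetic dendritic calcium movie
#'
#' The generator renders a horizontal dendrite band in a 2-D movie and
#' inserts calcium transients at a set of synaptic sites along it. Each
#' event multiplies the local baseline fluorescence by
#' `1 + amplitude * exp(-(x - site)^2 / (2 spatial_sigma^2)) * exp(-dt/decay_tau)`,
#' so the generated peak ΔF/F0 at the site centre equals `amplitude` exactly.
#' A small `spatial_sigma` emulates compartmentalized (spine-restricted)
#' signals; a large one emulates diffuse influx spreading through the shaft.
#'
#' Event times are Bernoulli per frame at `transient_rate / 500`; synchrony
#' across sites is injected by mixing a shared event stream with independent
#' per-site streams at weight `common_drive` (0 = independent, 1 = all sites
#' fire together), which leaves the per-site rate unchanged.
#'
#' @param n_frames number of frames.
#' @param fps frame rate (frames/s).
#' @param px_size micrometres per pixel.
#' @param roi_length dendrite length in px (movie width).
#' @param n_sites number of synaptic sites.
#' @param site_positions optional site x-positions (px, 1-based); default
#'   evenly spaced.
#' @param transient_rate expected events per site per 500 frames.
#' @param amplitude peak ΔF/F0 of one event.
#' @param spatial_sigma Gaussian spatial spread (px).
#' @param decay_tau temporal decay constant (frames).
#' @param common_drive fraction of events shared across sites, in `[0, 1]`.
#' @param baseline_f0 dendrite baseline fluorescence (AU).
#' @param noise_sd additive Gaussian pixel noise SD (AU).
#' @param seed integer seed.
#' @return a list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_frames = 600, fps = default_fps(),
                               px_size = default_px_size(),
                               roi_length = 200, n_sites = 5,
                               site_positions = NULL,
                               transient_rate = 5, amplitude = 1,
                               spatial_sigma = 3, decay_tau = 5,
                               common_drive = 0, baseline_f0 = 100,
                               noise_sd = 0, seed = 1L) {
  check_that(n_frames >= 1, "n_frames", "must be >= 1")
  check_that(fps > 0, "fps", "must be > 0")
  check_that(px_size > 0, "px_size", "must be > 0")
  check_that(roi_length >= 10, "roi_length", "must be >= 10 px")
  check_that(n_sites >= 0, "n_sites", "must be >= 0")
  check_that(!(n_sites == 0 && transient_rate > 0), "n_sites",
             "transient_rate > 0 requires at least one site")
  if (is.null(site_positions) && n_sites > 0) {
    site_positions <- round(seq(0.1, 0.9, length.out = n_sites) * roi_length)
  }
  check_that(all(site_positions >= 1 & site_positions <= roi_length),
             "site_positions", "must lie within [1, roi_length]")
  check_that(transient_rate >= 0, "transient_rate", "must be >= 0")
  check_that(amplitude >= 0, "amplitude", "must be >= 0")
  check_that(spatial_sigma > 0, "spatial_sigma", "must be > 0")
  check_that(decay_tau > 0, "decay_tau", "must be > 0")
  check_that(common_drive >= 0 && common_drive <= 1, "common_drive",
             "must be in [0, 1]")
  check_that(baseline_f0 > 0, "baseline_f0", "must be > 0")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 px_size = px_size, roi_length = as.integer(roi_length),
                 n_sites = as.integer(n_sites),
                 site_positions = as.numeric(site_positions),
                 transient_rate = transient_rate, amplitude = amplitude,
                 spatial_sigma = spatial_sigma, decay_tau = decay_tau,
                 common_drive = common_drive, baseline_f0 = baseline_f0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "calcium_sim_params")
}

# movie geometry: dendrite band thickness and background level are fixed
# renderer choices, not study conditions
.movie_height <- 25L
.dendrite_halfwidth <- 4L
.background_frac <- 0.2

#' Generate a synthetic dendrite calcium movie
#'
#' @param params a [calcium_sim_params()] object.
#' @return a list with `movie` (array `[rows, cols, frames]`, AU), `roi` (a
#'   [line_roi()] along the dendrite covering its full width), and `truth`
#'   (site positions, every inserted event as `(site, position_px,
#'   onset_frame, amplitude)`, and the expected baseline kymograph level per
#'   position).
#' @export
gen_calcium_movie <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  H <- .movie_height
  W <- p$roi_length
  y0 <- (H + 1L) %/% 2L
  dend <- abs(seq_len(H) - y0) <= .dendrite_halfwidth
  f0_col <- ifelse(dend, p$baseline_f0, .background_frac * p$baseline_f0)
  f0 <- matrix(f0_col, nrow = H, ncol = W)

  ev <- with_seed(p$seed, {
    events <- .draw_events(p)
    noise <- if (p$noise_sd > 0) {
      array(rnorm(H * W * p$n_frames, 0, p$noise_sd), dim = c(H, W, p$n_frames))
    } else NULL
    list(events = events, noise = noise)
  })
  events <- ev$events

  # per-frame multiplicative ΔF/F0 field over positions
  x <- seq_len(W)
  s <- array(0, dim = c(W, p$n_frames))
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      e <- events[k, ]
      fr <- e$onset_frame:p$n_frames
      g <- exp(-(x - e$position_px)^2 / (2 * p$spatial_sigma^2))
      d <- exp(-(fr - e$onset_frame) / p$decay_tau)
      s[, fr] <- s[, fr] + e$amplitude * outer(g, d)
    }
  }
  movie <- array(0, dim = c(H, W, p$n_frames))
  for (f in seq_len(p$n_frames)) {
    movie[, , f] <- f0 * (1 + matrix(s[, f], nrow = H, ncol = W, byrow = TRUE))
  }
  if (!is.null(ev$noise)) movie <- movie + ev$noise

  roi <- line_roi(cbind(x = c(1, W), y = c(y0, y0)), width_px = H)
  truth <- list(params = unclass(p),
                site_positions = p$site_positions,
                events = events,
                baseline_profile = rep(mean(f0_col), W))
  list(movie = movie, roi = roi, truth = truth)
}

# Bernoulli event streams with a shared component at weight common_drive.
# Called inside with_seed().
.draw_events <- function(p) {
  empty <- data.frame(site = integer(), position_px = numeric(),
                      onset_frame = integer(), amplitude = numeric())
  if (p$n_sites == 0 || p$transient_rate == 0) return(empty)
  pr <- p$transient_rate / 500
  shared <- runif(p$n_frames) < pr
  out <- vector("list", p$n_sites)
  for (s in seq_len(p$n_sites)) {
    indep <- runif(p$n_frames) < pr
    use_shared <- runif(p$n_frames) < p$common_drive
    fire <- ifelse(use_shared, shared, indep)
    on <- which(fire)
    out[[s]] <- if (length(on)) {
      data.frame(site = s, position_px = p$site_positions[s],
                 onset_frame = on, amplitude = p$amplitude)
    } else empty
  }
  do.call(rbind, out)
}
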