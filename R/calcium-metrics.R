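#' Locate synaptic sites along a ΔF/F0 kymograph
#'
#' Candidate sites are local maxima of the temporal-maximum spatial profile
#' (the largest ΔF/F0 each position ever reaches) above `threshold`,
#' accepted greedily in order of decreasing height subject to a minimum
#' centre separation. Deterministic given the input.
#'
#' @param dffk a `dff_kymograph` from [compute_dff()].
#' @param min_separation minimum distance between site centres (px).
#' @param threshold minimum temporal-max ΔF/F0 for a candidate.
#' @return data frame with columns `id`, `center` (px), `halfwidth` (px);
#'   zero rows when nothing exceeds the threshold.
#' @export
identify_sites <- function(dffk, min_separation = 10, threshold = 0.1) {
  stopifnot(inherits(dffk, "dff_kymograph"))
  prof <- apply(dffk$dff, 2, max)
  n <- length(prof)
  left <- c(-Inf, prof[-n]); right <- c(prof[-1], -Inf)
  cand <- which(prof > threshold & prof >= left & prof >= right)
  cand <- cand[order(prof[cand], decreasing = TRUE)]
  centers <- numeric(0)
  for (i in cand) {
    if (!length(centers) || min(abs(centers - i)) >= min_separation) {
      centers <- c(centers, i)
    }
  }
  centers <- sort(centers)
  data.frame(id = seq_along(centers), center = centers,
             halfwidth = rep(max(1L, floor(min_separation / 2)),
                             length(centers)))
}

#' Detect calcium transients at one synaptic site
#'
#' Events are runs of at least `min_frames` consecutive frames in which the
#' site-centre ΔF/F0 trace exceeds `k_sd` baseline standard deviations
#' (robustly estimated by the median absolute deviation, so sparse events do
#' not inflate it). When the baseline variance is essentially zero — e.g.
#' noiseless simulations — an absolute ΔF/F0 floor is used instead.
#'
#' @param dffk a `dff_kymograph`.
#' @param site one row of [identify_sites()] output (or a list with
#'   `id`/`center`).
#' @param k_sd threshold in baseline SD units.
#' @param min_frames minimum run length in frames.
#' @param floor_dff absolute ΔF/F0 floor on the threshold; it governs when
#'   the baseline SD is ~ 0 (noiseless simulations) and keeps
#'   sub-physiological noise blips out when the SD estimate is very small.
#' @details Because a new transient can arrive before the previous one has
#'   decayed back to baseline, each run is further split by hysteresis: once
#'   the trace has fallen at least one threshold below the running peak, a
#'   rise of one threshold above the intervening minimum opens a new event.
#'   Without this rule, bursts of transients are counted as one event and
#'   frequency is systematically underestimated.
#' @return data frame: `site`, `onset_frame`, `offset_frame`, `peak_frame`,
#'   `peak_dff`.
#' @export
detect_transients <- function(dffk, site, k_sd = 3, min_frames = 2,
                              floor_dff = 0.05) {
  stopifnot(inherits(dffk, "dff_kymograph"))
  center <- round(site$center)
  stopifnot(center >= 1, center <= ncol(dffk$dff))
  tr <- dffk$dff[, center]
  sigma <- stats::mad(tr)
  # absolute ΔF/F0 floor: governs when baseline variance ~ 0 and guards
  # against sub-physiological blips when the noise estimate is small
  thr <- max(k_sd * sigma, floor_dff)
  above <- tr > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  empty <- data.frame(site = integer(), onset_frame = integer(),
                      offset_frame = integer(), peak_frame = integer(),
                      peak_dff = numeric())
  if (!any(keep)) return(empty)
  segs <- do.call(rbind, mapply(function(a, b) {
    .split_run(tr, a, b, drop = thr)
  }, starts[keep], ends[keep], SIMPLIFY = FALSE))
  segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_frames, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  peak_frame <- mapply(function(a, b) a - 1L + which.max(tr[a:b]),
                       segs[, 1], segs[, 2])
  data.frame(site = rep(site$id %||% NA_integer_, nrow(segs)),
             onset_frame = as.integer(segs[, 1]),
             offset_frame = as.integer(segs[, 2]),
             peak_frame = as.integer(peak_frame),
             peak_dff = tr[peak_frame])
}

# hysteresis split of one above-threshold run [a, b]: after the trace falls
# >= drop below the running peak, a rise >= drop above the running minimum
# closes the current event at the minimum and opens the next one
.split_run <- function(tr, a, b, drop) {
  bounds <- NULL
  start <- a
  peak <- tr[a]
  valley <- tr[a]; valley_i <- a
  armed <- FALSE
  t <- a
  while (t < b) {
    t <- t + 1L
    v <- tr[t]
    if (!armed) {
      if (v > peak) peak <- v
      if (peak - v >= drop) { armed <- TRUE; valley <- v; valley_i <- t }
    } else {
      if (v < valley) { valley <- v; valley_i <- t }
      if (v - valley >= drop) {
        bounds <- rbind(bounds, c(start, valley_i))
        start <- valley_i + 1L
        peak <- v
        armed <- FALSE
      }
    }
  }
  rbind(bounds, c(start, b))
}

#' Average spatial profile of a site's transients
#'
#' Each event contributes the full spatial ΔF/F0 profile at its peak frame;
#' the site profile is the pointwise mean across events, the per-site
#' "average transient" from which AUC and diffusion distance are read.
#'
#' @param dffk a `dff_kymograph`.
#' @param events data frame from [detect_transients()] (>= 1 row).
#' @return list of class `site_profile`: `profile` (ΔF/F0 per position),
#'   `n_events`, `peak_position` (px), `px_size`.
#' @export
average_site_transients <- function(dffk, events) {
  stopifnot(inherits(dffk, "dff_kymograph"))
  if (!nrow(events)) {
    stop("no events at this site; exclude it downstream", call. = FALSE)
  }
  prof <- colMeans(dffk$dff[events$peak_frame, , drop = FALSE])
  structure(list(profile = prof, n_events = nrow(events),
                 peak_position = which.max(prof), px_size = dffk$px_size),
            class = "site_profile")
}

.profile_values <- function(profile) {
  if (inherits(profile, "site_profile")) profile$profile else as.numeric(profile)
}

# contiguous index run containing `peak` where `ok` holds
.span_around <- function(ok, peak) {
  lo <- peak
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- peak
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  lo:hi
}

#' Area under the averaged transient profile
#'
#' Trapezoidal integral of `max(profile - baseline_level, 0)` over position
#' (1-px steps), restricted to the contiguous above-baseline span containing
#' the peak; a proxy for the calcium influx of the average transient.
#'
#' @param profile a `site_profile` or numeric vector.
#' @param baseline_level ΔF/F0 baseline to subtract.
#' @return area in ΔF/F0 · px.
#' @export
site_auc <- function(profile, baseline_level = 0) {
  v <- .profile_values(profile) - baseline_level
  if (!length(v) || max(v) <= 0) return(0)
  idx <- .span_around(v > 0, which.max(v))
  # include the bounding at-or-below-baseline samples so the descent to
  # baseline is integrated (a unit plateau over 10 px scores 10, not 9)
  idx <- max(1L, min(idx) - 1L):min(length(v), max(idx) + 1L)
  trapz(idx, pmax(v[idx], 0))
}

#' Spatial diffusion distance of the averaged transient
#'
#' The length of the contiguous span around the peak over which the profile
#' stays at or above a fraction `f` of its peak, converted to micrometres
#' (65 px corresponds to 10 um at the default calibration). Small distances
#' indicate compartmentalized (spine-restricted) transients; large ones
#' indicate influx diffusing through the shaft.
#'
#' @param profile a `site_profile` or numeric vector.
#' @param f peak fraction defining the span (default 0.1).
#' @param px_size micrometres per pixel.
#' @return distance in micrometres.
#' @export
diffusion_distance <- function(profile, f = 0.1, px_size = NULL) {
  v <- .profile_values(profile)
  if (is.null(px_size)) {
    px_size <- if (inherits(profile, "site_profile")) profile$px_size
               else default_px_size()
  }
  peak <- max(v)
  stopifnot(peak > 0)
  idx <- .span_around(v >= f * peak, which.max(v))
  length(idx) * px_size
}

#' Transient frequency per 500 frames
#' @param events data frame of detected events.
#' @param n_frames_analyzed number of frames analysed (> 0).
#' @return events per 500 frames.
#' @export
transient_frequency <- function(events, n_frames_analyzed) {
  stopifnot(n_frames_analyzed > 0)
  nrow(events) * 500 / n_frames_analyzed
}

#' Synaptic synchrony across sites
#'
#' Pearson-correlates the site-centre ΔF/F0 time courses of up to
#' `n_sample` randomly chosen sites over a frame window (default the central
#' 500 frames), and reports for each site the mean of its off-diagonal
#' correlation row — the paper-style per-site synchrony score.
#'
#' @param dffk a `dff_kymograph`.
#' @param sites data frame from [identify_sites()] (>= 2 rows).
#' @param n_sample number of sites to sample without replacement.
#' @param frame_window `c(first, last)` or `NULL` for the central 500 frames.
#' @param seed seed for the site sampling.
#' @return list with `per_site` (data frame `site`, `mean_sync`), the full
#'   correlation `matrix`, and the `frames` used.
#' @export
synchrony <- function(dffk, sites, n_sample = 20, frame_window = NULL,
                      seed = 1L) {
  stopifnot(inherits(dffk, "dff_kymograph"), nrow(sites) >= 2)
  nf <- nrow(dffk$dff)
  if (is.null(frame_window)) {
    w <- min(500L, nf)
    start <- max(1L, floor((nf - w) / 2) + 1L)
    frame_window <- c(start, start + w - 1L)
  }
  stopifnot(frame_window[1] >= 1, frame_window[2] <= nf)
  frames <- frame_window[1]:frame_window[2]
  take <- if (nrow(sites) > n_sample) {
    with_seed(seed, sort(sample(nrow(sites), n_sample)))
  } else seq_len(nrow(sites))
  sel <- sites[take, ]
  tr <- dffk$dff[frames, round(sel$center), drop = FALSE]
  const <- apply(tr, 2, function(z) stats::sd(z) < 1e-12)
  if (any(const)) {
    warning(sum(const), " constant site trace(s) dropped from synchrony")
    sel <- sel[!const, , drop = FALSE]
    tr <- tr[, !const, drop = FALSE]
  }
  if (ncol(tr) < 2) stop("fewer than 2 usable sites for synchrony", call. = FALSE)
  cm <- stats::cor(tr)
  per_site <- data.frame(
    site = sel$id,
    mean_sync = vapply(seq_len(ncol(cm)),
                       function(i) mean(cm[i, -i]), numeric(1)))
  list(per_site = per_site, matrix = cm, frames = frame_window)
}

#' Score detected transients against ground-truth events
#'
#' A truth event is recalled when some detected event at the same site
#' either covers the truth onset with its onset-offset span or starts
#' within `tol_frames` of it; a detected event is a true positive when it
#' matches at least one truth event the same way. Matching is many-to-one
#' on purpose: closely spaced true events that merge into one
#' above-threshold run are counted as found, not missed.
#'
#' @param detected data frame from [detect_transients()] (any number of
#'   sites row-bound; needs `site`, `onset_frame`, `offset_frame`).
#' @param truth data frame of generator events (`site`, `onset_frame`).
#' @param site_map optional integer vector mapping detected site ids to
#'   truth site ids (defaults to identity).
#' @param tol_frames onset tolerance in frames.
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
match_events <- function(detected, truth, site_map = NULL, tol_frames = 2) {
  if (!nrow(truth)) {
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_truth = 0L, n_detected = nrow(detected)))
  }
  det_site <- if (is.null(site_map)) detected$site else site_map[detected$site]
  truth_hit <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which(det_site == truth$site[i])
    any(detected$onset_frame[j] - tol_frames <= truth$onset_frame[i] &
          detected$offset_frame[j] + tol_frames >= truth$onset_frame[i])
  }, logical(1))
  det_hit <- vapply(seq_len(nrow(detected)), function(k) {
    i <- which(truth$site == det_site[k])
    any(detected$onset_frame[k] - tol_frames <= truth$onset_frame[i] &
          detected$offset_frame[k] + tol_frames >= truth$onset_frame[i])
  }, logical(1))
  list(recall = mean(truth_hit),
       precision = if (nrow(detected)) mean(det_hit) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected))
}

#' Split events at a drug-application frame
#'
#' Events are assigned to the before/after partition by their peak frame;
#' events whose onset-offset span crosses the boundary are flagged.
#'
#' @param events data frame from [detect_transients()].
#' @param application_frame the frame at which the drug was applied.
#' @return list with `before` and `after` event data frames (each gains a
#'   logical `spans_boundary` column).
#' @export
split_before_after <- function(events, application_frame) {
  stopifnot(application_frame >= 0)
  spans <- events$onset_frame < application_frame &
    events$offset_frame >= application_frame
  events$spans_boundary <- spans
  list(before = events[events$peak_frame < application_frame, , drop = FALSE],
       after = events[events$peak_frame >= application_frame, , drop = FALSE])
}

#' End-to-end per-site calcium metrics for one movie
#'
#' Convenience driver chaining kymograph extraction, ΔF/F0, site
#' identification, transient detection and all per-site read-outs.
#'
#' @param movie array `[rows, cols, frames]`.
#' @param roi a [line_roi()].
#' @inheritParams extract_kymograph
#' @inheritParams identify_sites
#' @inheritParams detect_transients
#' @param f diffusion-distance peak fraction.
#' @param sync_seed seed for synchrony site sampling.
#' @return list with `sites` (per-site metrics data frame), `events`
#'   (all detected events) and the intermediate `dff`.
#' @export
calcium_site_metrics <- function(movie, roi, frame_range = NULL,
                                 fps = default_fps(),
                                 px_size = default_px_size(),
                                 min_separation = 10, threshold = 0.1,
                                 k_sd = 3, min_frames = 2, f = 0.1,
                                 sync_seed = 1L) {
  kym <- extract_kymograph(movie, roi, frame_range, fps, px_size)
  dffk <- compute_dff(kym)
  sites <- identify_sites(dffk, min_separation, threshold)
  if (!nrow(sites)) {
    return(list(sites = data.frame(), events = data.frame(), dff = dffk))
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    detect_transients(dffk, sites[i, ], k_sd, min_frames)
  }))
  nf <- nrow(dffk$dff)
  met <- lapply(seq_len(nrow(sites)), function(i) {
    e <- ev[ev$site == sites$id[i], , drop = FALSE]
    if (!nrow(e)) {
      return(data.frame(site = sites$id[i], center = sites$center[i],
                        n_events = 0L, auc = NA_real_,
                        diffusion_distance_um = NA_real_,
                        frequency_per_500 = 0))
    }
    prof <- average_site_transients(dffk, e)
    data.frame(site = sites$id[i], center = sites$center[i],
               n_events = nrow(e), auc = site_auc(prof),
               diffusion_distance_um = diffusion_distance(prof, f),
               frequency_per_500 = transient_frequency(e, nf))
  })
  met <- do.call(rbind, met)
  if (nrow(sites) >= 2) {
    sy <- synchrony(dffk, sites, seed = sync_seed)
    met$mean_sync <- sy$per_site$mean_sync[match(met$site, sy$per_site$site)]
  } else {
    met$mean_sync <- NA_real_
  }
  list(sites = met, events = ev, dff = dffk)
}
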