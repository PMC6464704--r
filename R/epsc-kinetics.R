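#' Average aligned EPSC sweeps
#'
#' Pointwise mean of 5-10 (or any number of) sweeps recorded with the same
#' time base and stimulus onset; fitting is done on the averaged response.
#'
#' @param traces list of [epsc_trace()] objects with identical time axes.
#' @return an [epsc_trace()].
#' @export
average_sweeps <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "epsc_trace")))
  t0 <- traces[[1]]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time, t0$time)) ||
        !isTRUE(all.equal(tr$stim_onset, t0$stim_onset))) {
      stop("sweeps must share the time base and stimulus onset", call. = FALSE)
    }
  }
  cur <- rowMeans(vapply(traces, `[[`, numeric(length(t0$time)), "current"))
  epsc_trace(t0$time, cur, t0$stim_onset, t0$holding_label)
}

# index of the post-stimulus extremum (by magnitude, after baseline removal)
.peak_index <- function(trace) {
  base <- .pre_stim_baseline(trace)
  post <- which(trace$time >= trace$stim_onset)
  i <- post[which.max(abs(trace$current[post] - base))]
  i
}

.pre_stim_baseline <- function(trace) {
  pre <- trace$current[trace$time < trace$stim_onset]
  if (length(pre)) mean(pre) else 0
}

#' Normalize an EPSC trace to unit peak
#'
#' Subtracts the pre-stimulus baseline, flips the sign if the post-stimulus
#' extremum is negative (outward-positive convention), and scales so the
#' peak equals 1. Idempotent and shape-preserving.
#'
#' @param trace an [epsc_trace()].
#' @return an [epsc_trace()] with peak amplitude 1.
#' @export
normalize_to_peak <- function(trace) {
  stopifnot(inherits(trace, "epsc_trace"))
  base <- .pre_stim_baseline(trace)
  cur <- trace$current - base
  i <- .peak_index(trace)
  pk <- cur[i]
  if (abs(pk) < .Machine$double.eps * 100) {
    stop("degenerate trace: no nonzero post-stimulus extremum", call. = FALSE)
  }
  epsc_trace(trace$time, cur / pk, trace$stim_onset, trace$holding_label)
}

#' Rise time: time to peak amplitude
#'
#' Time from the stimulus onset to the post-stimulus peak, the convention
#' used when the stimulus artefact marks time zero. Invariant to constant
#' current offsets.
#'
#' @param trace an [epsc_trace()].
#' @return rise time in ms.
#' @export
rise_time <- function(trace) {
  stopifnot(inherits(trace, "epsc_trace"))
  i <- .peak_index(trace)
  if (i == length(trace$time)) {
    warning("peak at trace end; rise time may be truncated")
  }
  trace$time[i] - trace$stim_onset
}

#' Amplitude-weighted decay time constant
#'
#' \deqn{\tau_w = \tau_f \frac{A_f}{A_f + A_s} + \tau_s \frac{A_s}{A_f + A_s}}
#'
#' @param fit a `biexp_fit` from [fit_biexp_decay()], or a list with
#'   `amp_fast`, `amp_slow`, `tau_fast`, `tau_slow`.
#' @return tau_w in ms.
#' @export
weighted_tau <- function(fit) {
  a <- fit$amp_fast + fit$amp_slow
  if (!is.finite(a) || a <= 0) {
    stop("degenerate fit: amp_fast + amp_slow must be > 0", call. = FALSE)
  }
  (fit$amp_fast * fit$tau_fast + fit$amp_slow * fit$tau_slow) / a
}

#' Fit the EPSC decay phase with a double exponential
#'
#' Least-squares fit of
#' \deqn{Y(t) = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}}
#' to the decay phase (by default from the post-stimulus peak to the end of
#' the sweep) after pre-stimulus baseline subtraction. Components are
#' reported ordered so `tau_fast < tau_slow`, with fractional amplitudes,
#' the weighted time constant, rise time and the R-squared of the decay
#' fit. Near-degenerate fits (tau ratio < 1.2) are flagged
#' `quasi_single_exp` rather than rejected. Amplitudes are referenced to
#' the stimulus onset (extrapolated back along each exponential from the
#' window start), so fractional contributions are comparable across cells
#' with different rise times.
#'
#' Levenberg-Marquardt optimisation starts from tau_f0 = time for the decay
#' to fall to 1/e of the peak, tau_s0 = 6 tau_f0, amplitudes split evenly,
#' with bounds tau in `[1, 5000]` ms and amplitudes >= 0 — a robust recipe
#' across the NMDAR kinetics range (~50 ms GluN2A to ~300 ms GluN2B).
#'
#' @param trace an [epsc_trace()].
#' @param window `c(start, end)` in ms (start at/after the peak), or `NULL`
#'   for peak-to-end.
#' @return a list of class `biexp_fit`: `amp_fast`, `amp_slow`, `tau_fast`,
#'   `tau_slow`, `frac_fast`, `frac_slow`, `tau_w`, `rise_time`, `gof`,
#'   `fit_window`, `quasi_single_exp`.
#' @export
fit_biexp_decay <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "epsc_trace"))
  base <- .pre_stim_baseline(trace)
  i_peak <- .peak_index(trace)
  cur <- trace$current - base
  if (cur[i_peak] < 0) cur <- -cur      # outward-positive convention
  t_peak <- trace$time[i_peak]
  if (is.null(window)) {
    window <- c(t_peak, max(trace$time))
  } else if (window[1] < t_peak - 1e-9) {
    stop("fit window must start at or after the post-stimulus peak",
         call. = FALSE)
  }
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 20L) stop("need >= 20 samples in the fit window",
                           call. = FALSE)
  tt <- trace$time[sel] - window[1]
  yy <- cur[sel]
  pk <- yy[1]

  # data-driven starting values
  below <- which(yy <= pk / exp(1))
  tau_f0 <- if (length(below)) max(tt[below[1]], 1.5) else max(tt) / 3
  start <- c(af = pk / 2, asl = pk / 2, tf = tau_f0,
             ts = min(6 * tau_f0, 4999))
  resid_fn <- function(par) {
    par[1] * exp(-tt / par[3]) + par[2] * exp(-tt / par[4]) - yy
  }
  lm_fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(0, 0, 1, 1), upper = c(Inf, Inf, 5000, 5000),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!lm_fit$info %in% 1:4 || !all(is.finite(lm_fit$par))) {
    stop("biexponential fit failed to converge (", lm_fit$message, ")",
         "\n  window = [", signif(window[1], 6), ", ",
         signif(window[2], 6), "] ms, n = ", length(tt),
         ", peak = ", signif(pk, 6), call. = FALSE)
  }
  cf <- lm_fit$par
  comp <- if (cf[["tf"]] <= cf[["ts"]]) {
    c(af = cf[["af"]], as = cf[["asl"]], tf = cf[["tf"]], ts = cf[["ts"]])
  } else {
    c(af = cf[["asl"]], as = cf[["af"]], tf = cf[["ts"]], ts = cf[["tf"]])
  }
  res <- lm_fit$fvec
  gof <- 1 - sum(res^2) / sum((yy - mean(yy))^2)
  # reference amplitudes back to the stimulus onset: the window starts at
  # the peak, so the raw coefficients are amplitudes at window[1]; without
  # this the fast fraction depends on the rise time of the cell
  t_ref <- window[1] - trace$stim_onset
  comp[["af"]] <- comp[["af"]] * exp(t_ref / comp[["tf"]])
  comp[["as"]] <- comp[["as"]] * exp(t_ref / comp[["ts"]])
  atot <- comp[["af"]] + comp[["as"]]
  out <- list(amp_fast = comp[["af"]], amp_slow = comp[["as"]],
              tau_fast = comp[["tf"]], tau_slow = comp[["ts"]],
              frac_fast = comp[["af"]] / atot,
              frac_slow = comp[["as"]] / atot,
              rise_time = t_peak - trace$stim_onset,
              gof = gof, fit_window = window,
              quasi_single_exp = comp[["ts"]] / comp[["tf"]] < 1.2)
  out$tau_w <- weighted_tau(out)
  structure(out, class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(paste0("<biexp_fit> tau_f = %.1f ms (%.0f%%), tau_s = %.1f ms",
                     " (%.0f%%), tau_w = %.1f ms, rise = %.1f ms, R2 = %.4f%s\n"),
              x$tau_fast, 100 * x$frac_fast, x$tau_slow, 100 * x$frac_slow,
              x$tau_w, x$rise_time, x$gof,
              if (x$quasi_single_exp) " [quasi-single-exp]" else ""))
  invisible(x)
}

#' Per-cell percent change in tau_w after drug application
#'
#' @param baseline,treated lists of `biexp_fit` objects (or anything
#'   [weighted_tau()] accepts), aligned by cell when `paired_by_cell`.
#' @param paired_by_cell require equal lengths and pair positionally.
#' @return list with `per_cell` percent changes, `mean` and `sem`.
#' @export
percent_change_tau <- function(baseline, treated, paired_by_cell = TRUE) {
  if (paired_by_cell && length(baseline) != length(treated)) {
    stop("paired comparison requires equally many baseline and treated fits",
         call. = FALSE)
  }
  tw_b <- vapply(baseline, weighted_tau, numeric(1))
  tw_t <- vapply(treated, weighted_tau, numeric(1))
  per_cell <- 100 * (tw_t - tw_b) / tw_b
  list(per_cell = per_cell, mean = mean(per_cell), sem = sem(per_cell))
}
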