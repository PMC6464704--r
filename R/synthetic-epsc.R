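#' Parameters for the evoked-EPSC generator
#'
#' The generative model is an instantaneous stimulus at `stim_onset` followed
#' by a saturating rise filter multiplying a biexponential decay:
#' \deqn{I(t) = (1 - e^{-t/\tau_{rise}})\,(A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}) + \epsilon}
#' with Gaussian noise of standard deviation `noise_sd`. The two decay
#' components correspond to the fast (GluN2A-like, ~50 ms) and slow
#' (GluN2B-like, ~300 ms) NMDAR kinetic regimes. Current is reported with the
#' outward (positive at +50 mV) sign convention.
#'
#' @param amp_fast,amp_slow component amplitudes (pA), both >= 0 and not both 0.
#' @param tau_fast,tau_slow decay time constants (ms), `tau_fast < tau_slow`.
#' @param rise_tau rise time constant (ms).
#' @param sample_rate sampling rate in kHz (samples per ms).
#' @param duration sweep length (ms).
#' @param stim_onset stimulus time (ms).
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed integer seed.
#' @return a list of class `epsc_sim_params`.
#' @export
epsc_sim_params <- function(amp_fast = 100, amp_slow = 100,
                            tau_fast = 50, tau_slow = 300,
                            rise_tau = 2, sample_rate = 10,
                            duration = 1500, stim_onset = 100,
                            noise_sd = 0, seed = 1L) {
  check_that(tau_fast > 0 && tau_slow > 0, "tau_fast/tau_slow", "must be > 0")
  check_that(tau_fast < tau_slow, "tau_fast", "must be smaller than tau_slow")
  check_that(amp_fast >= 0 && amp_slow >= 0, "amp_fast/amp_slow", "must be >= 0")
  check_that(amp_fast + amp_slow > 0, "amp_fast/amp_slow", "must not both be 0")
  check_that(rise_tau > 0, "rise_tau", "must be > 0")
  check_that(sample_rate > 0, "sample_rate", "must be > 0")
  check_that(duration > 0, "duration", "must be > 0")
  check_that(stim_onset >= 0 && stim_onset < duration, "stim_onset",
             "must lie within the sweep")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(list(amp_fast = amp_fast, amp_slow = amp_slow,
                 tau_fast = tau_fast, tau_slow = tau_slow,
                 rise_tau = rise_tau, sample_rate = sample_rate,
                 duration = duration, stim_onset = stim_onset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "epsc_sim_params")
}

#' Construct an EPSC trace object
#'
#' @param time time axis in ms, uniform and strictly increasing.
#' @param current current in pA (outward positive).
#' @param stim_onset stimulus time (ms).
#' @param holding_label free-text holding-potential label.
#' @return a list of class `epsc_trace`.
#' @export
epsc_trace <- function(time, current, stim_onset, holding_label = "+50 mV") {
  stopifnot(length(time) == length(current), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("`time` must be strictly increasing with a uniform step", call. = FALSE)
  }
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 stim_onset = stim_onset, holding_label = holding_label),
            class = "epsc_trace")
}

#' @export
print.epsc_trace <- function(x, ...) {
  cat(sprintf("<epsc_trace> %d samples, %.1f ms, stim at %.1f ms, %s\n",
              length(x$time), max(x$time), x$stim_onset, x$holding_label))
  invisible(x)
}

# Noiseless generative waveform; shared by the generator and its truth record.
epsc_waveform <- function(time, p) {
  tt <- time - p$stim_onset
  y <- numeric(length(time))
  on <- tt >= 0
  y[on] <- (1 - exp(-tt[on] / p$rise_tau)) *
    (p$amp_fast * exp(-tt[on] / p$tau_fast) +
       p$amp_slow * exp(-tt[on] / p$tau_slow))
  y
}

#' Generate a simulated evoked NMDAR-EPSC
#'
#' @param params an [epsc_sim_params()] object.
#' @return a list with `trace` (an [epsc_trace()]) and `truth`, a record of
#'   the generative parameters plus the noiseless peak time/amplitude located
#'   by a fine grid scan (independent of the fitting code).
#' @examples
#' sim <- gen_epsc(epsc_sim_params(noise_sd = 0))
#' sim$truth$peak_time_ms
#' @export
gen_epsc <- function(params) {
  stopifnot(inherits(params, "epsc_sim_params"))
  p <- params
  n <- round(p$duration * p$sample_rate)
  time <- (seq_len(n) - 1L) / p$sample_rate
  clean <- epsc_waveform(time, p)
  noise <- if (p$noise_sd > 0) {
    with_seed(p$seed, rnorm(n, 0, p$noise_sd))
  } else numeric(n)
  trace <- epsc_trace(time, clean + noise, p$stim_onset)

  # truth peak from a 100x-oversampled scan of the closed form
  tfine <- seq(p$stim_onset, p$duration, by = 1 / (100 * p$sample_rate))
  yfine <- epsc_waveform(tfine, p)
  i <- which.max(yfine)
  truth <- list(params = unclass(p),
                peak_time_ms = tfine[i],
                peak_amp_pA = yfine[i],
                rise_time_ms = tfine[i] - p$stim_onset,
                tau_w_ms = (p$amp_fast * p$tau_fast + p$amp_slow * p$tau_slow) /
                  (p$amp_fast + p$amp_slow))
  list(trace = trace, truth = truth)
}
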