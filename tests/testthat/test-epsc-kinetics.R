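make_trace <- function(...) gen_epsc(epsc_sim_params(...))$trace

test_that("normalize_to_peak scales to unit peak, preserves shape, is idempotent", {
  tr <- make_trace(amp_fast = 60, amp_slow = 60, noise_sd = 0)
  nt <- normalize_to_peak(tr)
  post <- nt$time >= nt$stim_onset
  expect_equal(max(nt$current[post]), 1)
  # shape: all sample ratios preserved
  pk <- max(tr$current[post])
  expect_equal(nt$current, tr$current / pk, tolerance = 1e-12)
  # idempotence
  nt2 <- normalize_to_peak(nt)
  expect_equal(nt2$current, nt$current, tolerance = 1e-12)
  # peak sample index unchanged (argmax oracle)
  expect_equal(which.max(nt$current), which.max(tr$current))
  # negative-going trace is flipped to the outward-positive convention
  flipped <- epsc_trace(tr$time, -tr$current, tr$stim_onset)
  expect_equal(normalize_to_peak(flipped)$current, nt$current,
               tolerance = 1e-12)
  # degenerate all-zero trace
  zero <- epsc_trace(tr$time, rep(0, length(tr$time)), tr$stim_onset)
  expect_error(normalize_to_peak(zero), "degenerate")
})

test_that("weighted_tau evaluates the printed formula and its limits", {
  expect_equal(weighted_tau(list(amp_fast = 1, amp_slow = 1,
                                 tau_fast = 100, tau_slow = 100)), 100)
  expect_equal(weighted_tau(list(amp_fast = 3, amp_slow = 0,
                                 tau_fast = 50, tau_slow = 300)), 50)
  expect_equal(weighted_tau(list(amp_fast = 1, amp_slow = 1,
                                 tau_fast = 50, tau_slow = 300)), 175)
  expect_error(weighted_tau(list(amp_fast = 0, amp_slow = 0,
                                 tau_fast = 50, tau_slow = 300)),
               "degenerate")
  # closed-form equivalence against the independently written formula
  set.seed(41)
  for (i in 1:25) {
    af <- runif(1, 0, 5); as_ <- runif(1, 0.01, 5)
    tf <- runif(1, 10, 100); ts <- runif(1, 150, 600)
    expect_equal(weighted_tau(list(amp_fast = af, amp_slow = as_,
                                   tau_fast = tf, tau_slow = ts)),
                 oracle_tau_w(af, as_, tf, ts), tolerance = 1e-12)
  }
})

test_that("rise_time is time to peak, shift-invariant, argmax-consistent", {
  tr <- make_trace(noise_sd = 0, rise_tau = 2)
  rt <- rise_time(tr)
  # brute-force argmax oracle
  i <- which.max(tr$current)
  expect_equal(rt, tr$time[i] - tr$stim_onset)
  # constant current shift leaves rise time unchanged
  shifted <- epsc_trace(tr$time, tr$current + 12.5, tr$stim_onset)
  expect_equal(rise_time(shifted), rt)
  # synthetic pulse peaking exactly 8 ms after the stimulus
  t <- seq(0, 100, by = 0.1)
  cur <- ifelse(t >= 20 & t <= 28, (t - 20) / 8, exp(-(t - 28) / 30))
  cur[t < 20] <- 0
  expect_equal(rise_time(epsc_trace(t, cur, 20)), 8)
})

test_that("noiseless biexponential decay parameters are recovered within 1%", {
  tr <- make_trace(amp_fast = 100, amp_slow = 100, tau_fast = 50,
                   tau_slow = 300, noise_sd = 0)
  # window past the rise filter (~5 rise time constants after the peak) so
  # the windowed data are a pure biexponential
  t_peak <- tr$time[which.max(tr$current)]
  fit <- fit_biexp_decay(tr, window = c(t_peak + 10, max(tr$time)))
  expect_equal(fit$tau_fast, 50, tolerance = 0.01)
  expect_equal(fit$tau_slow, 300, tolerance = 0.01)
  expect_equal(fit$frac_fast, 0.5, tolerance = 0.01)
  expect_equal(fit$tau_w, 175, tolerance = 0.01)
  expect_gt(fit$gof, 0.999)
  expect_false(fit$quasi_single_exp)
})

test_that("single-exponential limit drives frac_fast to 1 and tau_w to tau", {
  tr <- make_trace(amp_fast = 120, amp_slow = 0, tau_fast = 50,
                   tau_slow = 300, rise_tau = 1e-6, noise_sd = 0)
  fit <- fit_biexp_decay(tr)
  # the slow component should carry (almost) no amplitude
  expect_gt(max(fit$frac_fast, fit$frac_slow), 0.999)
  tau_dom <- if (fit$frac_fast > fit$frac_slow) fit$tau_fast else fit$tau_slow
  expect_equal(tau_dom, 50, tolerance = 0.01)
  expect_equal(fit$tau_w, 50, tolerance = 0.01)
})

test_that("noisy fit beats a coarse grid-search oracle on decay RMSE", {
  p <- epsc_sim_params(amp_fast = 100, amp_slow = 100, tau_fast = 50,
                       tau_slow = 300, noise_sd = 9, seed = 17)
  sim <- gen_epsc(p)
  tr <- sim$trace
  fit <- fit_biexp_decay(tr)
  t_peak <- tr$time[which.max(tr$current)]
  sel <- tr$time >= t_peak
  tt <- tr$time[sel] - t_peak
  yy <- tr$current[sel]
  model_rmse <- function(af, as_, tf, ts) {
    sqrt(mean((yy - af * exp(-tt / tf) - as_ * exp(-tt / ts))^2))
  }
  # brute-force grid around the generating values
  grid <- expand.grid(tf = seq(30, 80, by = 5), ts = seq(200, 400, by = 20),
                      af = seq(60, 140, by = 10), as_ = seq(60, 140, by = 10))
  grid_best <- min(mapply(model_rmse, grid$af, grid$as_, grid$tf, grid$ts))
  fit_rmse <- model_rmse(fit$amp_fast * exp(-(t_peak - tr$stim_onset) / fit$tau_fast),
                         fit$amp_slow * exp(-(t_peak - tr$stim_onset) / fit$tau_slow),
                         fit$tau_fast, fit$tau_slow)
  expect_lte(fit_rmse, grid_best + 1e-9)
})

test_that("component ordering holds regardless of generator amplitude order", {
  for (s in 1:6) {
    amps <- if (s %% 2) c(150, 50) else c(50, 150)
    tr <- make_trace(amp_fast = amps[1], amp_slow = amps[2], tau_fast = 50,
                     tau_slow = 300, noise_sd = 5, seed = s)
    fit <- fit_biexp_decay(tr)
    expect_lt(fit$tau_fast, fit$tau_slow)
    expect_equal(fit$frac_fast + fit$frac_slow, 1, tolerance = 1e-12)
    expect_gte(fit$tau_w, fit$tau_fast)
    expect_lte(fit$tau_w, fit$tau_slow)
  }
})

test_that("fitted tau_w is monotone in the generator's slow fraction", {
  fracs <- c(0.2, 0.4, 0.6, 0.8)
  tw <- vapply(fracs, function(fs) {
    tr <- make_trace(amp_fast = 100 * (1 - fs), amp_slow = 100 * fs,
                     tau_fast = 50, tau_slow = 300, noise_sd = 0)
    fit_biexp_decay(tr)$tau_w
  }, numeric(1))
  expect_true(all(diff(tw) > 0))
})

test_that("fit window preconditions are enforced", {
  tr <- make_trace(noise_sd = 0)
  t_peak <- tr$time[which.max(tr$current)]
  expect_error(fit_biexp_decay(tr, window = c(t_peak - 20, max(tr$time))),
               "peak")
  expect_error(fit_biexp_decay(tr, window = c(t_peak, t_peak + 1)),
               "20 samples")
})

test_that("percent_change_tau computes per-cell percent changes", {
  f <- function(tw) list(amp_fast = 1, amp_slow = 0, tau_fast = tw,
                         tau_slow = tw + 1)
  same <- percent_change_tau(list(f(200), f(150)), list(f(200), f(150)))
  expect_equal(same$per_cell, c(0, 0))
  halved <- percent_change_tau(list(f(200)), list(f(100)))
  expect_equal(halved$per_cell, -50)
  # three simulated cells against a hand-computed vector
  base <- list(f(100), f(200), f(250))
  trt <- list(f(150), f(150), f(300))
  pc <- percent_change_tau(base, trt)
  expect_equal(pc$per_cell, c(50, -25, 20))
  expect_equal(pc$mean, 15)
  expect_equal(pc$sem, sd(c(50, -25, 20)) / sqrt(3))
  expect_error(percent_change_tau(base, trt[1:2]), "equally many")
})

test_that("average_sweeps is the pointwise mean and checks alignment", {
  tr1 <- make_trace(noise_sd = 4, seed = 1)
  tr2 <- make_trace(noise_sd = 4, seed = 2)
  avg <- average_sweeps(list(tr1, tr2))
  expect_equal(avg$current, (tr1$current + tr2$current) / 2)
  tr3 <- make_trace(noise_sd = 0, duration = 1000)
  expect_error(average_sweeps(list(tr1, tr3)), "time base")
})
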