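test_that("kymograph extraction reproduces hand-computable geometries", {
  # spatially uniform movie: every entry equals the pixel value
  mov <- array(3.5, dim = c(10, 20, 4))
  roi1 <- line_roi(cbind(c(2, 19), c(5, 5)), width_px = 1)
  k <- extract_kymograph(mov, roi1)
  expect_true(all(k$values == 3.5))
  expect_equal(dim(k$values), c(4L, 18L))

  # width-1 axis-aligned line equals direct raster indexing, exactly
  mov2 <- array(0, dim = c(8, 30, 3))
  for (f in 1:3) mov2[, , f] <- matrix(runif(8 * 30), 8, 30)
  k2 <- extract_kymograph(mov2, line_roi(cbind(c(1, 30), c(4, 4)), 1))
  for (f in 1:3) expect_identical(k2$values[f, ], mov2[4, 1:30, f])

  # width 3 over rows valued 1/2/3: perpendicular mean is constant 2
  mov3 <- array(rep(c(1, 2, 3), times = 1), dim = c(3, 12, 2))
  mov3[1, , ] <- 1; mov3[2, , ] <- 2; mov3[3, , ] <- 3
  k3 <- extract_kymograph(mov3, line_roi(cbind(c(1, 12), c(2, 2)), 3))
  expect_true(all(abs(k3$values - 2) < 1e-12))

  # geometry errors
  expect_error(extract_kymograph(mov, line_roi(cbind(c(1, 25), c(5, 5)), 1)),
               "bounds")
  expect_error(extract_kymograph(mov, roi1, frame_range = c(3, 2)),
               "frame_range")
})

test_that("compute_dff recovers inserted ΔF/F0 amplitudes", {
  # F identical to F0 -> dff is identically 0
  k <- kymograph(matrix(7, nrow = 20, ncol = 15))
  d <- compute_dff(k, baseline_frames = 1:5)
  expect_true(all(d$dff == 0))

  # a single doubled entry -> dff = 1 there
  v <- matrix(10, 20, 15); v[12, 7] <- 20
  d2 <- compute_dff(kymograph(v), baseline_frames = 1:5)
  expect_equal(d2$dff[12, 7], 1)
  expect_equal(sum(d2$dff != 0), 1L)

  # generator truth: noiseless movie, known amplitude
  p <- calcium_sim_params(n_frames = 300, n_sites = 2, transient_rate = 4,
                          amplitude = 0.8, noise_sd = 0, seed = 21)
  g <- gen_calcium_movie(p)
  dffk <- compute_dff(extract_kymograph(g$movie, g$roi))
  ev <- g$truth$events
  iso <- ev[!duplicated(ev$site) & ev$onset_frame > 30, ]
  peaks <- mapply(function(s, f) dffk$dff[f, g$truth$site_positions[s]],
                  iso$site, iso$onset_frame)
  expect_true(all(abs(peaks - 0.8) / 0.8 < 0.02))

  # F0 <= 0 is refused
  expect_error(compute_dff(kymograph(matrix(0, 10, 5)), 1:5), "F0")
})

test_that("identify_sites finds constructed and simulated bump centres", {
  flat <- dff_from_matrix(matrix(0, 100, 60))
  expect_equal(nrow(identify_sites(flat)), 0L)

  # two noiseless Gaussian bumps 30 px apart
  x <- 1:80
  prof <- exp(-(x - 20)^2 / 8) + exp(-(x - 50)^2 / 8)
  bump <- dff_from_matrix(rbind(matrix(0, 30, 80),
                                matrix(prof, 10, 80, byrow = TRUE),
                                matrix(0, 30, 80)))
  s <- identify_sites(bump, min_separation = 10)
  expect_equal(s$center, c(20, 50))

  # generator truth: recovered centres within 1 px
  p <- calcium_sim_params(n_frames = 400, n_sites = 4, transient_rate = 8,
                          noise_sd = 0, seed = 12)
  g <- gen_calcium_movie(p)
  dffk <- compute_dff(extract_kymograph(g$movie, g$roi))
  s2 <- identify_sites(dffk, min_separation = 10)
  active <- sort(unique(g$truth$events$position_px))
  expect_equal(nrow(s2), length(active))
  expect_true(all(abs(sort(s2$center) - active) <= 1))
})

test_that("detect_transients marks threshold-crossing runs", {
  zero <- dff_from_matrix(matrix(0, 100, 10))
  ev0 <- detect_transients(zero, list(id = 1L, center = 5))
  expect_equal(nrow(ev0), 0L)

  # rectangular pulse of 5 frames with min_frames = 3 -> one event at the
  # pulse edges
  m <- matrix(0, 100, 10)
  m[40:44, 5] <- 1
  ev1 <- detect_transients(dff_from_matrix(m), list(id = 1L, center = 5),
                           min_frames = 3)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$onset_frame, 40L)
  expect_equal(ev1$offset_frame, 44L)
  expect_equal(ev1$peak_dff, 1)

  # a 1-frame blip is rejected at min_frames = 2
  m2 <- matrix(0, 100, 10); m2[50, 5] <- 1
  ev2 <- detect_transients(dff_from_matrix(m2), list(id = 1L, center = 5))
  expect_equal(nrow(ev2), 0L)
})

test_that("detection recall and precision reach 0.95 at high SNR", {
  p <- calcium_sim_params(n_frames = 600, n_sites = 5, transient_rate = 5,
                          amplitude = 1, noise_sd = 2, baseline_f0 = 100,
                          seed = 31)
  g <- gen_calcium_movie(p)
  res <- calcium_site_metrics(g$movie, g$roi)
  smap <- site_map_by_position(res$sites$center, g$truth$site_positions)
  m <- match_events(res$events, g$truth$events, site_map = smap)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("average_site_transients is the pointwise mean over event peaks", {
  prof <- exp(-((1:40) - 20)^2 / 18)
  m <- rbind(matrix(0, 10, 40),
             matrix(prof, 1, 40),        # event 1 peak frame (frame 11)
             matrix(0, 10, 40),
             matrix(3 * prof, 1, 40),    # event 2 peak frame (frame 22)
             matrix(0, 10, 40))
  dffk <- dff_from_matrix(m)
  ev <- data.frame(site = 1L, onset_frame = c(11L, 22L),
                   offset_frame = c(11L, 22L), peak_frame = c(11L, 22L),
                   peak_dff = c(1, 3))
  sp <- average_site_transients(dffk, ev)
  expect_equal(sp$profile, 2 * prof)     # mean of p and 3p
  expect_equal(sp$n_events, 2L)
  one <- average_site_transients(dffk, ev[1, ])
  expect_equal(one$profile, prof)
  expect_error(average_site_transients(dffk, ev[0, ]), "no events")
})

test_that("site_auc integrates the above-baseline span", {
  expect_equal(site_auc(rep(0, 30)), 0)
  # unit plateau over 10 px bounded by baseline samples
  expect_equal(site_auc(c(rep(0, 5), rep(1, 10), rep(0, 5))), 10)
  # fine-sampled Gaussian: closed-form A * sigma * sqrt(2*pi)
  a <- 1.7; sigma <- 20
  x <- 1:301
  g <- a * exp(-(x - 151)^2 / (2 * sigma^2))
  expect_equal(site_auc(g), a * sigma * sqrt(2 * pi), tolerance = 0.01)
  # only the span containing the peak is integrated
  two <- c(rep(0, 4), rep(0.5, 4), rep(0, 4), rep(2, 4), rep(0, 4))
  expect_lt(site_auc(two), 2 * 5)
})

test_that("diffusion_distance applies the pixel calibration", {
  spike <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(diffusion_distance(spike), 10 / 65)
  wide <- c(0, rep(1, 65), 0)
  expect_equal(diffusion_distance(wide), 10)
  # Gaussian FWHM at f = 0.5
  x <- 1:201
  g <- exp(-(x - 101)^2 / (2 * 5^2))
  expect_equal(diffusion_distance(g, f = 0.5, px_size = 1), 2.355 * 5,
               tolerance = 0.09)
})

test_that("transient_frequency scales counts to 500 frames", {
  ev <- data.frame(site = 1, onset_frame = 1:10)
  expect_equal(transient_frequency(ev[0, ], 1000), 0)
  expect_equal(transient_frequency(ev, 1000), 5)
  # seeded generator: estimate inside the binomial 95% band of the truth
  p <- calcium_sim_params(n_frames = 2000, n_sites = 3, transient_rate = 5,
                          noise_sd = 0, seed = 8)
  g <- gen_calcium_movie(p)
  res <- calcium_site_metrics(g$movie, g$roi)
  # pooled over 3 sites x 2000 frames of Bernoulli draws at p = 5/500
  half_band <- 1.96 * sqrt((5 / 500) * (1 - 5 / 500) / (3 * 2000)) * 500
  expect_lt(abs(mean(res$sites$frequency_per_500) - 5), half_band)
})

test_that("synchrony attains its bounds and rejects degenerate input", {
  tr <- sin((1:500) / 10) + 1
  ident <- dff_from_matrix(matrix(tr, 500, 6))
  sites <- data.frame(id = 1:6, center = 1:6, halfwidth = 2)
  sy <- synchrony(ident, sites)
  expect_equal(sy$per_site$mean_sync, rep(1, 6), tolerance = 1e-12)

  inv <- dff_from_matrix(cbind(tr, -tr))
  sy2 <- synchrony(inv, data.frame(id = 1:2, center = 1:2, halfwidth = 1))
  expect_equal(sy2$per_site$mean_sync, c(-1, -1), tolerance = 1e-12)

  # independent noise traces: near-zero mean correlation
  set.seed(5)
  noise <- dff_from_matrix(matrix(rnorm(500 * 20), 500, 20))
  sy3 <- synchrony(noise, data.frame(id = 1:20, center = 1:20, halfwidth = 1))
  expect_true(all(abs(sy3$per_site$mean_sync) < 0.1))

  # constant trace dropped with warning
  cm <- cbind(tr, tr, rep(2, 500))
  expect_warning(
    sy4 <- synchrony(dff_from_matrix(cm),
                     data.frame(id = 1:3, center = 1:3, halfwidth = 1)),
    "constant")
  expect_equal(nrow(sy4$per_site), 2L)
  expect_error(synchrony(ident, sites[1, ]), "2")
})

test_that("synchrony is monotone in the generator's common drive", {
  ms <- vapply(c(0, 0.5, 1), function(w) {
    p <- calcium_sim_params(n_frames = 600, n_sites = 8, transient_rate = 8,
                            common_drive = w, noise_sd = 0, seed = 14)
    g <- gen_calcium_movie(p)
    dffk <- compute_dff(extract_kymograph(g$movie, g$roi))
    sites <- identify_sites(dffk)
    mean(synchrony(dffk, sites, seed = 2)$per_site$mean_sync)
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_equal(ms[3], 1, tolerance = 1e-6)
})

test_that("split_before_after partitions by peak frame and flags spanners", {
  ev <- data.frame(site = 1,
                   onset_frame = c(10L, 48L, 60L),
                   offset_frame = c(14L, 53L, 66L),
                   peak_frame = c(11L, 49L, 63L),
                   peak_dff = c(1, 1, 1))
  sp <- split_before_after(ev, 50)
  expect_equal(nrow(sp$before), 2L)
  expect_equal(nrow(sp$after), 1L)
  expect_true(sp$before$spans_boundary[2])   # 48-53 crosses frame 50
  expect_false(any(sp$after$spans_boundary))
  all_before <- split_before_after(ev, 100)
  expect_equal(nrow(all_before$after), 0L)
  none_before <- split_before_after(ev, 0)
  expect_equal(nrow(none_before$before), 0L)
})

test_that("compartmentalized movies yield shorter diffusion distances than diffuse", {
  run <- function(sigma) {
    p <- calcium_sim_params(n_frames = 500, n_sites = 4, transient_rate = 6,
                            spatial_sigma = sigma, noise_sd = 0, seed = 19)
    g <- gen_calcium_movie(p)
    calcium_site_metrics(g$movie, g$roi)$sites
  }
  tight <- run(2)
  diffuse <- run(20)
  expect_true(all(tight$diffusion_distance_um <
                    min(diffuse$diffusion_distance_um)))
  # AUC rises with spatial spread of the same-amplitude events
  expect_gt(mean(diffuse$auc), mean(tight$auc))
})

test_that("AUC is monotone in generator amplitude on noiseless movies", {
  auc_at <- function(a) {
    p <- calcium_sim_params(n_frames = 400, n_sites = 3, transient_rate = 6,
                            amplitude = a, noise_sd = 0, seed = 23)
    g <- gen_calcium_movie(p)
    mean(calcium_site_metrics(g$movie, g$roi)$sites$auc)
  }
  aucs <- vapply(c(0.4, 0.8, 1.6), auc_at, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
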