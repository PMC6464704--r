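#!/usr/bin/env Rscript
# Build the synthetic study datasets every later stage consumes: evoked
# NMDAR-EPSC sweeps for two groups with different fast/slow balance,
# calcium movies in compartmentalized and diffuse regimes, four-channel
# soma images with and without AL deposits, and a viability plate.
# Everything is seeded; ground truth is saved alongside each dataset.

library(synaptodev)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

# --- EPSC sweeps: "mature" group is fast-dominated, "immature" slow-shifted
epsc_groups <- list(
  mature = list(amp_fast = 120, amp_slow = 80),    # frac_fast 0.6
  immature = list(amp_fast = 80, amp_slow = 120))  # frac_fast 0.4
for (gname in names(epsc_groups)) {
  gpar <- epsc_groups[[gname]]
  for (cell in 1:8) {
    sweeps <- lapply(1:6, function(sw) {
      gen_epsc(epsc_sim_params(amp_fast = gpar$amp_fast,
                               amp_slow = gpar$amp_slow,
                               tau_fast = 50, tau_slow = 300,
                               noise_sd = 15,
                               seed = seed + 100L * cell + sw +
                                 1000L * match(gname, names(epsc_groups))))$trace
    })
    write_epsc_csv(average_sweeps(sweeps),
                   file.path(out, sprintf("epsc_%s_cell%02d.csv", gname, cell)))
  }
}
cat("EPSC: 2 groups x 8 cells x 6 averaged sweeps ->", out, "\n")

# --- calcium movies: spine-restricted (sigma 2 px) vs shaft-diffuse (20 px)
for (regime in c(compartmentalized = 2, diffuse = 20)) {
  nm <- names(which(c(compartmentalized = 2, diffuse = 20) == regime))
  p <- calcium_sim_params(n_frames = 600, n_sites = 5, transient_rate = 5,
                          spatial_sigma = regime, noise_sd = 1,
                          seed = seed + regime)
  g <- gen_calcium_movie(p)
  write_movie_tiff(g$movie, file.path(out, paste0("movie_", nm, ".tif")))
  write_roi_json(g$roi, file.path(out, paste0("roi_", nm, ".json")))
  jsonlite::write_json(g$truth[c("site_positions", "events")],
                       file.path(out, paste0("truth_", nm, ".json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("calcium movie (%s): %d true events at %d sites\n",
              nm, nrow(g$truth$events), length(g$truth$site_positions)))
}

# --- plate: dose series mirroring an NMDA/glycine excitotoxicity assay
plate <- gen_plate(plate_sim_params(
  true_viability = c(vehicle = 1, nmda_10uM = 0.76, nmda_100uM = 0.42,
                     nmda_300uM = 0.38),
  cv = 0.06, n_wells = 6, seed = seed))
write.csv(plate$plate, file.path(out, "plate.csv"), row.names = FALSE)
cat("plate:", nrow(plate$plate), "wells,",
    length(unique(plate$plate$condition)), "conditions\n")

cat("done; soma images are regenerated in 04_image_quant.R (seeded)\n")
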