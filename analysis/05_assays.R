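#!/usr/bin/env Rscript
# Viability normalization of the simulated NMDA dose plate, APEGS
# palmitoylation ratios from a densitometry table, the within-lane subunit
# ratio, and the group-statistics stage over the viability read-out.

library(synaptodev)
dir.create("results", showWarnings = FALSE)

plate <- read.csv("results/data/plate.csv")
viab <- normalize_viability(plate)
write.csv(viab$summary, "results/viability_summary.csv", row.names = FALSE)
for (i in seq_len(nrow(viab$summary))) {
  cat(sprintf("%-11s %6.1f +/- %4.1f %% of vehicle (n = %d wells)\n",
              viab$summary$condition[i], viab$summary$mean_pct[i],
              viab$summary$sem_pct[i], viab$summary$n[i]))
}
aov_res <- compare_groups(data.frame(value = viab$wells$pct_of_vehicle,
                                     group = viab$wells$condition),
                          test = "anova_tukey")
sig <- aov_res$tukey[aov_res$tukey$p_adj < 0.05, ]
cat(sprintf("ANOVA + Tukey: %d/%d pairwise contrasts significant at 0.05\n",
            nrow(sig), nrow(aov_res$tukey)))
write.csv(aov_res$tukey, "results/viability_tukey.csv", row.names = FALSE)

# APEGS densitometry: lanes as (shifted band densities | unshifted | actin);
# numbers emulate a protein with high baseline palmitoylation that drops
# under depalmitoylating conditions
lanes <- data.frame(
  sample = c("ctrl_1", "ctrl_2", "treat_1", "treat_2"),
  shifted_1 = c(0.42, 0.39, 0.18, 0.15),
  shifted_2 = c(0.21, 0.24, 0.08, 0.09),
  nonpalm = c(0.30, 0.28, 0.52, 0.49),
  actin = c(1.1, 0.95, 1.05, 1.0))
lanes$ratio <- vapply(seq_len(nrow(lanes)), function(i) {
  apegs_ratio(c(lanes$shifted_1[i], lanes$shifted_2[i]),
              lanes$nonpalm[i], lanes$actin[i])$ratio
}, numeric(1))
write.csv(lanes, "results/apegs_ratios.csv", row.names = FALSE)
cat(sprintf("APEGS palmitoylation ratio: ctrl %.2f vs treated %.2f\n",
            mean(lanes$ratio[1:2]), mean(lanes$ratio[3:4])))

# within-lane GluN2A/GluN2B ratio for a small synthetic cohort
dens <- data.frame(animal = 1:6,
                   glun2a = c(0.9, 1.0, 0.85, 0.5, 0.45, 0.55),
                   glun2b = c(0.6, 0.62, 0.58, 0.7, 0.75, 0.72),
                   group = rep(c("wt", "ko"), each = 3))
dens$ratio <- subunit_ratio(dens$glun2a, dens$glun2b)
t_ratio <- compare_groups(data.frame(value = dens$ratio,
                                     group = dens$group), test = "t")
cat(sprintf("GluN2A/GluN2B ratio: wt %.2f vs ko %.2f (p = %.3g)\n",
            t_ratio$groups$mean[t_ratio$groups$group == "wt"],
            t_ratio$groups$mean[t_ratio$groups$group == "ko"],
            t_ratio$p_value))
write.csv(dens, "results/subunit_ratios.csv", row.names = FALSE)
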