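#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study populations with known ground truth.
#
# Emulated conditions (one seed; the acceptance script averages over many):
#   - two strains ("b6n", "bdf1"), n = 150 each, the bdf1 mean aspect ratio
#     planted 5.7% below b6n, both with CV 5.3%
#   - three epididymal collection sites at the published group sizes
#     (caput n = 69, corpus n = 85, cauda n = 118) with decreasing CVs
#     (8.4, 6.0, 5.3%) and small planted mean shifts
#   - one cauda population with a planted 10% abnormal admixture
#
# Outputs (results/data/): per-study contour CSVs, a group label map, and
# the ground-truth table.

suppressPackageStartupMessages(library(spermshape))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

studies <- list(
  strain = list(
    population_spec(150, mean_aspect = 0.5, cv_aspect = 0.053,
                    rng_seed = 101, group_label = "b6n"),
    population_spec(150, mean_aspect = 0.5 * (1 - 0.057), cv_aspect = 0.053,
                    rng_seed = 102, group_label = "bdf1")),
  maturation = list(
    population_spec(69, mean_aspect = 0.5, cv_aspect = 0.084,
                    rng_seed = 111, group_label = "caput"),
    population_spec(85, mean_aspect = 0.5 * (1 - 0.030), cv_aspect = 0.060,
                    rng_seed = 112, group_label = "corpus"),
    population_spec(118, mean_aspect = 0.5 * (1 - 0.026), cv_aspect = 0.053,
                    scale_px = 80 * (1 - 0.031) / (1 - 0.026),
                    rng_seed = 113, group_label = "cauda")),
  admixture = list(
    population_spec(150, abnormal_fraction = 0.1, rng_seed = 121,
                    group_label = "cauda_mixed"))
)

gt_all <- NULL
for (study in names(studies)) {
  records <- unlist(lapply(studies[[study]], sample_population),
                    recursive = FALSE)
  gt <- ground_truth(records)
  gt$study <- study
  gt_all <- rbind(gt_all, gt)
  contours <- setNames(lapply(records, `[[`, "contour"),
                       vapply(records, `[[`, "", "specimen_id"))
  write_contour_csv(contours, sprintf("results/data/%s_contours.csv", study))
  cat(sprintf("study %-10s: %3d specimens in %d groups (%d abnormal)\n",
              study, length(records), length(studies[[study]]),
              sum(gt$is_abnormal)))
}
write.csv(gt_all, "results/data/ground_truth.csv", row.names = FALSE)
write.csv(gt_all[, c("specimen_id", "group_label")],
          "results/data/label_map.csv", row.names = FALSE)
cat("wrote results/data/{*_contours,ground_truth,label_map}.csv\n")
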