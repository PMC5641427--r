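#!/usr/bin/env Rscript
# Stage 3: elliptic Fourier descriptors and PCA.
#
# For the admixture study: estimate and normalize EFDs (N = 20, 77 free
# coefficients per head), run the two-pass abnormality filter (pass-1 PCA on
# everything, exclusion at PC1 > 0.55, pass-2 PCA on the remainder), and
# report how the filter's verdicts line up with the generator's ground
# truth. For the strain study: fit the pooled PCA, record contribution
# rates, factor loadings with biplot arrow lengths, and the mean +/- 2 SD
# shape outlines along PC1.
#
# Outputs under results/tables/: coefficients, abnormality audit,
# contribution rates, loadings, and PC1 shape panels.

suppressPackageStartupMessages(library(spermshape))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

label_map <- read.csv("results/data/label_map.csv")
gt <- read.csv("results/data/ground_truth.csv")

## ---- abnormality filter on the admixed cauda population --------------------
recs <- apply_label_map(read_contour_csv("results/data/admixture_contours.csv"),
                        label_map)
tab <- efd_table(recs, 20)
flt <- filter_abnormal(tab$matrix, threshold = 0.55)
truth <- gt$is_abnormal[match(rownames(tab$matrix), gt$specimen_id)]
audit <- data.frame(specimen_id = rownames(tab$matrix),
                    pass1_pc1 = flt$pass1_scores,
                    excluded = rownames(tab$matrix) %in% flt$abnormal_ids,
                    planted_abnormal = truth)
write.csv(audit, "results/tables/abnormality_audit.csv", row.names = FALSE)
cat(sprintf("abnormality filter: %d/%d planted outliers excluded, %d normals excluded\n",
            sum(audit$excluded & audit$planted_abnormal), sum(audit$planted_abnormal),
            sum(audit$excluded & !audit$planted_abnormal)))

## ---- pooled PCA of the two strains -----------------------------------------
recs <- apply_label_map(read_contour_csv("results/data/strain_contours.csv"),
                        label_map)
tab <- efd_table(recs, 20)
write.csv(coefficient_table(tab), "results/tables/strain_coefficients.csv",
          row.names = FALSE)
fit <- efd_pca(tab$matrix)
write.csv(data.frame(pc = seq_along(fit$eigenvalues),
                     eigenvalue = fit$eigenvalues,
                     contribution_rate = fit$contribution_rates),
          "results/tables/strain_contribution_rates.csv", row.names = FALSE)
cat(sprintf("PCA on %d specimens x %d coefficients; contribution rates: %s\n",
            fit$n_specimens, ncol(tab$matrix),
            paste(sprintf("PC%d %.1f%%", 1:3, 100 * fit$contribution_rates[1:3]),
                  collapse = ", ")))

L <- factor_loadings(fit, tab$matrix)
write.csv(L, "results/tables/strain_loadings.csv", row.names = FALSE)
top <- L[order(-abs(L$PC1)), ][1:5, ]
cat("largest |PC1| loadings:",
    paste(sprintf("%s %.2f", top$variable, top$PC1), collapse = ", "), "\n")
cat(sprintf("aspect-ratio dominance on PC1: %.1f-fold over the next coefficient\n",
            abs(L$PC1[L$variable == "d1"]) / max(abs(L$PC1[L$variable != "d1"]))))

panels <- NULL
for (k in c(-2, 0, 2)) {
  xy <- reconstruct_along_pc(fit, pc = 1, k = k, n_points = 180)
  panels <- rbind(panels, data.frame(k_sd = k, vertex = seq_len(nrow(xy)),
                                     x = xy[, 1], y = xy[, 2]))
}
write.csv(panels, "results/tables/strain_pc1_shapes.csv", row.names = FALSE)
cat("wrote mean and +/- 2 SD PC1 outlines (results/tables/strain_pc1_shapes.csv)\n")
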