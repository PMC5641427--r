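#!/usr/bin/env Rscript
# Stage 5: group comparisons.
#
# Strain study: percent difference of the bdf1 mean aspect ratio against the
# b6n reference, with the one-tailed pooled t-test (the F-test checks the
# homoscedasticity assumption, Kolmogorov-Smirnov the distributional
# contrast). Maturation study: the same summaries across caput/corpus/cauda
# plus the all-pairs Steel-Dwass table.
#
# Outputs: results/tables/stats_{strain,maturation}_{summary,tests}.csv.

suppressPackageStartupMessages(library(spermshape))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

refs <- c(strain = "b6n", maturation = "caput")
for (study in names(refs)) {
  m <- read.csv(sprintf("results/tables/measurements_%s.csv", study))
  cg <- compare_groups(m, reference_group = refs[[study]])
  write.csv(cg$summary, sprintf("results/tables/stats_%s_summary.csv", study),
            row.names = FALSE)
  write.csv(cg$tests, sprintf("results/tables/stats_%s_tests.csv", study),
            row.names = FALSE)
  cat(sprintf("== %s (reference: %s) ==\n", study, refs[[study]]))
  print(cg$summary[, c("group", "n", "mean", "cv_percent", "percent_diff_vs_ref")],
        digits = 3)
  show <- cg$tests[, c("group1", "group2", "test_name", "p_value",
                       "significance_label")]
  print(show, digits = 3)
}
cat("positive percent differences mean thinner heads than the reference group\n")
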