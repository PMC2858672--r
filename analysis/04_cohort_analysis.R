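#!/usr/bin/env Rscript
# Cohort comparison across normal (N), corresponding-normal (CN), and
# tumor (T) groups: per-group summaries with Mann-Whitney stars, the
# methylation-expression rank correlation, and ROC curves using
# hypomethylation as the positive signal.

suppressPackageStartupMessages(library(mspa))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

tab <- simulate_cohort(cohort_config(seed = seed))
write_tsv(tab, "results/cohort.tsv")

for (var in c("methylation", "expression")) {
  gs <- group_summary(tab, var)
  message(var, " by group:")
  print(gs$groups)
  print(gs$contrasts)
  write_tsv(gs$contrasts, paste0("results/cohort_", var, "_contrasts.tsv"))
}

corr <- methylation_expression_correlation(tab)
message(sprintf("methylation vs expression: Spearman rho = %.2f (%s, n = %d)",
                corr$rho, corr$sign, corr$n))

for (pair in list(c("N", "CN"), c("N", "T"), c("CN", "T"))) {
  roc <- roc_auc(tab$methylation[tab$group == pair[2]],
                 tab$methylation[tab$group == pair[1]], direction = "low")
  message(sprintf("ROC %s vs %s (low methylation = positive): AUC = %.2f",
                  pair[1], pair[2], roc$auc))
  write_tsv(roc$points,
            paste0("results/roc_", pair[1], "_vs_", pair[2], ".tsv"))
}
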