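#!/usr/bin/env Rscript
# M-SPA footprint inference: call methylation with clone QC, translate
# GpC calls to accessibility, segment protection patches, classify each
# molecule's promoter occupancy state, and score recovery against the
# simulator's ground truth. Expects results/dataset from 01.

suppressPackageStartupMessages(library(mspa))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1

cfg <- pipeline_config(seed = seed, k = 1)
res <- run_analyze(cfg, "results/dataset", out_dir = "results/footprints")

message("promoter state summary:")
print(res$state_summary)
message(sprintf("ground-truth recovery: %.1f%% of %d molecules",
                100 * res$recovery$accuracy, res$recovery$n))
message("a molecule as the assay sees it (GpC lollipop, first 3 clones):")
mat <- local({
  reads <- read_fasta("results/dataset/clones.fasta")
  suppressMessages(qc_clones(reads, l1_promoter_locus()))$matrix
})
writeLines(utils::head(render_lollipop(mat, class = "gpc"), 3))
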