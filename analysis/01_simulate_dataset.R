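#!/usr/bin/env Rscript
# Generate the synthetic single-molecule dataset: 200 bisulfite clone
# reads from a 50/50 tetra/dinucleosomal mixture over the default L1
# promoter amplicon, plus the ground-truth manifest and a three-group
# cohort table. Everything is seed-stamped and byte-reproducible.

suppressPackageStartupMessages(library(mspa))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1

cfg <- pipeline_config(seed = seed, k = 1)
paths <- run_simulate(cfg, "results/dataset")
locus <- l1_promoter_locus()

message("locus: ", locus$length, " bp; ",
        length(locus$site_map$cpg_sites), " CpG, ",
        length(locus$site_map$gpc_sites), " GpC, ",
        length(locus$site_map$excluded_sites), " excluded GpCpG sites")
message("wrote:")
for (p in paths) message("  ", p)
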