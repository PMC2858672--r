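#!/usr/bin/env Rscript
# Strand-level methylation statistics on a biphasic patient-like sample:
# per-site percent methylation, the fully-unmethylated-strand fraction
# (PUR), the strand-level histogram, and the concordance of two
# quantitative assays modelled as disjoint CpG panels of the same
# molecules.

suppressPackageStartupMessages(library(mspa))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

locus <- l1_promoter_locus()
# a tumor-bearing-bladder-like sample: half the strands fully methylated,
# half fully unmethylated
ds <- simulate_clone_set(locus, sim_config(
  n_molecules = 500, endogenous_mixture = 0.5, seed = seed))
mat <- call_matrix(ds$reads, locus)

pm <- percent_methylation(mat)
write_tsv(pm$per_site, "results/per_site_methylation.tsv")
message(sprintf("mean CpG methylation: %.1f%% over %d sites",
                pm$mean, nrow(pm$per_site)))

pur <- fully_unmethylated_fraction(mat, sites = locus$site_map$cpg_sites[1:2])
message(sprintf("PUR (2-CpG panel): %.1f%% | fully methylated: %.1f%% | intermediate: %.1f%%",
                pur$pur, pur$fully_methylated, pur$intermediate))

sd10 <- strand_distribution(mat, sites = locus$site_map$cpg_sites[1:10])
write_tsv(sd10$histogram, "results/strand_distribution.tsv")
message(sprintf("biphasic endpoints: %d strands at 0%%, %d at 100%% (of %d)",
                sd10$exact_0, sd10$exact_100, sd10$n))

# two-assay concordance across 40 simulated samples
set.seed(seed + 1)
panels <- list(locus$site_map$cpg_sites[1:2], locus$site_map$cpg_sites[3:6])
vals <- sapply(1:40, function(i) {
  w <- runif(1)
  m <- call_matrix(simulate_clone_set(locus, sim_config(
    n_molecules = 60, endogenous_mixture = w))$reads, locus)
  c(percent_methylation(m, sites = panels[[1]])$mean,
    percent_methylation(m, sites = panels[[2]])$mean)
})
message(sprintf("two-assay concordance (2-CpG vs 4-CpG panel): R = %.3f",
                assay_concordance(vals[1, ], vals[2, ])))
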