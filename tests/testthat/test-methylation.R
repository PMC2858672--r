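make_read <- function(locus, meth_sites = integer(0)) {
  # fully converted reference except Cs listed in meth_sites
  ch <- strsplit(locus$reference, "")[[1]]
  cs <- which(ch == "C")
  ch[setdiff(cs, meth_sites)] <- "T"
  paste(ch, collapse = "")
}

test_that("methylation calls read C as methylated, T as unmethylated", {
  lm <- default_locus
  conv <- make_read(lm)
  row_u <- call_methylation(conv, lm)
  expect_true(all(row_u == "U"))
  # informative columns are exactly the CpG+GpC sites, never excluded ones
  expect_setequal(as.integer(names(row_u)),
                  c(lm$site_map$cpg_sites, lm$site_map$gpc_sites))
  row_m <- call_methylation(lm$reference, lm)
  expect_true(all(row_m == "M"))
  # an N in the read gives a missing call
  nread <- conv
  site1 <- lm$site_map$cpg_sites[1]
  substr(nread, site1, site1) <- "N"
  expect_equal(unname(call_methylation(nread, lm)[as.character(site1)]), ".")
})

test_that("length mismatches and foreign clones are rejected", {
  lm <- default_locus
  expect_error(call_methylation("ACGT", lm), "length")
  foreign <- withr::with_seed(1, random_dna(lm$length))
  expect_error(call_methylation(foreign, lm), "foreign clone")
})

test_that("calls reproduce simulator ground truth at perfect conversion", {
  lm <- default_locus
  ds <- simulate_clone_set(lm, sim_config(n_molecules = 60,
                                          enzyme_efficiency = 1,
                                          conversion_rate = 1, seed = 12))
  mat <- call_matrix(ds$reads, lm)
  for (i in seq_along(ds$marks)) {
    expect_identical(unname(mat[i, ]),
                     unname(ds$marks[[i]][colnames(mat)]))
  }
})

test_that("clone QC removes unconverted clones, monotonically in the threshold", {
  lm <- default_locus
  ds <- simulate_clone_set(lm, sim_config(n_molecules = 40,
                                          conversion_rate = 1, seed = 13))
  reads <- ds$reads
  reads <- c(reads, unconverted = lm$reference) # a planted failed conversion
  res <- suppressMessages(qc_clones(reads, lm, min_conversion = 0.95))
  expect_false("unconverted" %in% rownames(res$matrix))
  expect_equal(nrow(res$matrix), 40)
  expect_equal(sum(!res$qc$pass), 1)
  # retained count is non-increasing as the threshold rises
  ds2 <- simulate_clone_set(lm, sim_config(n_molecules = 60,
                                           conversion_rate = 0.95,
                                           seed = 14))
  kept <- vapply(c(0, 0.8, 0.9, 0.95, 0.99), function(thr) {
    nrow(suppressMessages(qc_clones(ds2$reads, lm,
                                    min_conversion = thr))$matrix)
  }, 0)
  expect_true(all(diff(kept) <= 0))
  # every clone failing is an explicit error, not an empty result
  expect_error(suppressMessages(
    qc_clones(c(a = lm$reference, b = lm$reference), lm)), "fail")
})

test_that("percent methylation implements the methylated/(meth+unmeth) formula", {
  lm <- build_locus_model(paste(rep("ACGTT", 4), collapse = ""),
                          tss_sense = 1, tss_antisense = 20)
  # 10 clones, first CpG methylated in 8
  reads <- vapply(1:10, function(i) {
    sites <- if (i <= 8) lm$site_map$cpg_sites[1] else integer(0)
    make_read(lm, sites)
  }, "")
  names(reads) <- paste0("c", 1:10)
  pm <- percent_methylation(call_matrix(reads, lm))
  expect_equal(pm$per_site$percent[1], 80)
  expect_equal(pm$per_site$percent[2], 0)
  expect_equal(pm$mean, 20)
})

test_that("percent methylation is invariant to row and column order", {
  lm <- default_locus
  ds <- simulate_clone_set(lm, sim_config(n_molecules = 30, seed = 15))
  mat <- call_matrix(ds$reads, lm)
  ref <- percent_methylation(mat)
  perm <- mat[sample(nrow(mat)), sample(ncol(mat))]
  attr(perm, "site_class") <- attr(mat, "site_class")[colnames(perm)]
  class(perm) <- class(mat)
  expect_equal(percent_methylation(perm)$mean, ref$mean)
})

test_that("all-missing sites are flagged and excluded from the mean", {
  lm <- build_locus_model("ACGTACGT", tss_sense = 1, tss_antisense = 8)
  reads <- c(c1 = "ATGTANGT", c2 = "ACGTANGT") # site 6 unreadable
  mat <- call_matrix(reads, lm)
  expect_message(pm <- percent_methylation(mat), "zero informative")
  expect_true(pm$per_site$flagged[pm$per_site$site == 6])
  expect_equal(pm$mean, 50)
})

test_that("biphasic mixtures give calibrated means and PUR partitions", {
  lm <- default_locus
  w <- 0.5
  ds <- simulate_clone_set(lm, sim_config(
    n_molecules = 1000, endogenous_mixture = w, conversion_rate = 1,
    seed = 16))
  mat <- call_matrix(ds$reads, lm)
  expect_lt(abs(percent_methylation(mat)$mean - 100 * w),
            3 * sqrt(w * (1 - w) / 1000) * 100)
  f <- fully_unmethylated_fraction(mat)
  expect_lt(abs(f$pur - 50), 3 * sqrt(0.25 / 1000) * 100)
  # the three strand classes always partition
  expect_equal(f$pur + f$fully_methylated + f$intermediate, 100)
})

test_that("PUR handles degenerate matrices", {
  lm <- build_locus_model("ACGTACGT", tss_sense = 1, tss_antisense = 8)
  all_m <- call_matrix(c(a = "ACGTACGT", b = "ACGTACGT"), lm)
  expect_equal(fully_unmethylated_fraction(all_m)$pur, 0)
  mixed <- call_matrix(c(a = "ATGTATGT", b = "ACGTATGT", c = "ATGTATGT"),
                       lm)
  expect_equal(fully_unmethylated_fraction(mixed)$pur, 100 * 2 / 3,
               tolerance = 1e-10)
  # molecules with missing calls in the subset are dropped, all-drop errors
  nn <- call_matrix(c(a = "ANGTANGT"), lm)
  expect_error(suppressMessages(fully_unmethylated_fraction(nn)),
               "no molecules")
})

test_that("strand distributions expose biphasic mixtures at the endpoints", {
  lm <- default_locus
  all_m <- call_matrix(stats::setNames(rep(lm$reference, 5), paste0("c", 1:5)),
                       lm)
  sd_all <- strand_distribution(all_m)
  expect_equal(sd_all$exact_100, 5)
  expect_equal(sd_all$exact_0, 0)
  ds <- simulate_clone_set(lm, sim_config(
    n_molecules = 400, endogenous_mixture = 0.5, seed = 17))
  # a 10-CpG panel, the typical CpG count of a cloned bisulfite amplicon
  res <- strand_distribution(call_matrix(ds$reads, lm),
                             sites = lm$site_map$cpg_sites[1:10])
  expect_gte((res$exact_0 + res$exact_100) / res$n, 0.9)
})

test_that("uniform per-site states put the modal bin at 50%", {
  # 10 independent sites at p = 0.5: per-molecule percent ~ Binomial(10,
  # 0.5)/10, modal mass in the [50,60) bin
  lm <- build_locus_model(paste(rep("ACGTT", 10), collapse = ""),
                          tss_sense = 1, tss_antisense = 50)
  reads <- withr::with_seed(18, vapply(1:2000, function(i) {
    make_read(lm, lm$site_map$cpg_sites[runif(10) < 0.5])
  }, ""))
  names(reads) <- paste0("c", seq_along(reads))
  res <- strand_distribution(call_matrix(reads, lm))
  expect_equal(res$histogram$bin[which.max(res$histogram$count)], "[50,60)")
})

test_that("assay concordance behaves like a Pearson correlation", {
  x <- c(10, 40, 80, 95, 20)
  expect_equal(assay_concordance(x, x), 1)
  expect_equal(assay_concordance(x, mean(x) - (x - mean(x))), -1)
  expect_error(assay_concordance(x, rep(5, 5)), "zero variance")
  expect_error(assay_concordance(x, x[1:3]), "equal length")
  expect_error(assay_concordance(x[1:2], x[1:2]), "at least 3")
})

test_that("two site panels of the same samples agree strongly", {
  # per-sample percent methylation over two disjoint CpG panels of the
  # same molecules: both estimate the sample's mixture weight
  lm <- default_locus
  panels <- list(lm$site_map$cpg_sites[1:2], lm$site_map$cpg_sites[3:6])
  vals <- withr::with_seed(19, {
    sapply(1:40, function(i) {
      w <- runif(1)
      mat <- call_matrix(simulate_clone_set(lm, sim_config(
        n_molecules = 60, endogenous_mixture = w))$reads, lm)
      c(percent_methylation(mat, sites = panels[[1]])$mean,
        percent_methylation(mat, sites = panels[[2]])$mean)
    })
  })
  expect_gt(assay_concordance(vals[1, ], vals[2, ]), 0.8)
})

test_that("lollipop rendering mirrors the call matrix", {
  lm <- build_locus_model("ACGTACGT", tss_sense = 1, tss_antisense = 8)
  mat <- call_matrix(c(a = "ACGTATGT"), lm)
  expect_equal(unname(render_lollipop(mat)), "●○")
})
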