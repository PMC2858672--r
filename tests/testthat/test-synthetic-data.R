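test_that("molecule states carry the configured nucleosome geometry", {
  lm <- default_locus
  tetra <- simulate_molecules(lm, sim_config(
    n_molecules = 20, state_mixture = c(tetra = 1), seed = 1))
  expect_true(all(vapply(tetra, function(m) nrow(m$footprints), 0L) == 4))
  expect_true(all(vapply(tetra, function(m) all(m$endogenous_meth == "M"),
                         TRUE)))
  di <- simulate_molecules(lm, sim_config(
    n_molecules = 20, state_mixture = c(di = 1), seed = 1))
  expect_true(all(vapply(di, function(m) nrow(m$footprints), 0L) == 2))
  expect_true(all(vapply(di, function(m) all(m$endogenous_meth == "U"),
                         TRUE)))
  # di molecules leave the upstream windows of both TSSs footprint-free
  for (m in di) {
    fp <- m$footprints
    expect_false(any(fp$start <= lm$tss_sense - 1 &
                       fp$end >= lm$tss_sense - 147))
    expect_false(any(fp$start <= lm$tss_antisense + 147 &
                       fp$end >= lm$tss_antisense + 1))
  }
  open <- simulate_molecules(lm, sim_config(
    n_molecules = 5, state_mixture = c(open = 1), seed = 1))
  expect_true(all(vapply(open, function(m) nrow(m$footprints), 0L) == 0))
})

test_that("footprints never overlap and a short locus is rejected", {
  lm <- default_locus
  mols <- simulate_molecules(lm, sim_config(n_molecules = 30, seed = 4))
  for (m in mols) {
    fp <- m$footprints[order(m$footprints$start), ]
    if (nrow(fp) > 1) expect_true(all(diff(fp$start) > 147))
  }
  short <- build_locus_model(substr(lm$reference, 1, 400),
                             tss_sense = 50, tss_antisense = 363)
  expect_error(
    simulate_molecules(short, sim_config(n_molecules = 1,
                                         state_mixture = c(tetra = 1))),
    "locus too short")
})

test_that("state mixture is recovered within binomial bounds", {
  n <- 10000
  mols <- simulate_molecules(default_locus, sim_config(
    n_molecules = n, state_mixture = c(tetra = 0.5, di = 0.5), seed = 8))
  frac <- mean(vapply(mols, `[[`, "", "state_label") == "tetra")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("enzyme marks respect footprints and efficiency", {
  lm <- default_locus
  cfg1 <- sim_config(n_molecules = 1, state_mixture = c(open = 1),
                     enzyme_efficiency = 1)
  open_mol <- simulate_molecules(lm, cfg1)[[1]]
  marks <- simulate_enzyme_treatment(open_mol, lm, cfg1)
  cls <- attr(marks, "class_by_site")
  expect_true(all(marks[cls == "gpc"] == "M"))

  # tetra molecule: no GpC under a footprint is ever marked (hard zero)
  cfg2 <- sim_config(n_molecules = 40, state_mixture = c(tetra = 1),
                     enzyme_efficiency = 1, seed = 2)
  for (m in simulate_molecules(lm, cfg2)) {
    mk <- simulate_enzyme_treatment(m, lm, cfg2)
    covered <- as.integer(names(mk)) %in% unlist(lapply(
      seq_len(nrow(m$footprints)),
      function(i) m$footprints$start[i]:m$footprints$end[i]))
    expect_true(all(mk[covered & attr(mk, "class_by_site") == "gpc"] == "U"))
  }

  # marking rate matches efficiency on accessible sites
  cfg3 <- sim_config(n_molecules = 2000, state_mixture = c(open = 1),
                     enzyme_efficiency = 0.8, seed = 3)
  mols <- simulate_molecules(lm, cfg3)
  rate <- withr::with_seed(33, mean(vapply(mols, function(m) {
    mk <- simulate_enzyme_treatment(m, lm, sim_config(
      enzyme_efficiency = 0.8))
    mean(mk[attr(mk, "class_by_site") == "gpc"] == "M")
  }, 0)))
  n_draws <- 2000 * length(lm$site_map$gpc_sites)
  expect_lt(abs(rate - 0.8), 3 * sqrt(0.8 * 0.2 / n_draws))
})

test_that("bisulfite conversion protects methylated cytosines", {
  lm <- build_locus_model("ACGT", tss_sense = 1, tss_antisense = 4)
  mol_m <- structure(list(id = "m1", state_label = "tetra",
                          footprints = data.frame(start = integer(0),
                                                  end = integer(0),
                                                  role = character(0)),
                          endogenous_meth = c(`2` = "M")),
                     class = "molecule_state")
  cfg <- sim_config(conversion_rate = 1)
  marks_m <- c(`2` = "M")
  expect_equal(simulate_bisulfite_read(mol_m, marks_m, lm, cfg), "ACGT")
  marks_u <- c(`2` = "U")
  mol_u <- mol_m; mol_u$endogenous_meth <- c(`2` = "U")
  expect_equal(simulate_bisulfite_read(mol_u, marks_u, lm, cfg), "ATGT")
})

test_that("reads keep the reference length and convert fully at rate 1", {
  lm <- default_locus
  ds <- simulate_clone_set(lm, sim_config(
    n_molecules = 30, state_mixture = c(open = 1), enzyme_efficiency = 0,
    conversion_rate = 1, seed = 5))
  expect_true(all(nchar(ds$reads) == lm$length))
  # open + no enzyme + full conversion: no C anywhere
  expect_false(any(grepl("C", ds$reads, fixed = TRUE)))
})

test_that("the clone-set generator is deterministic under a seed", {
  cfg <- sim_config(n_molecules = 25, seed = 99)
  a <- simulate_clone_set(default_locus, cfg)
  b <- simulate_clone_set(default_locus, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("cohort simulation honors group means and coupling", {
  # zero-sd cohort collapses to group means
  cfg0 <- cohort_config(n = c(N = 5, CN = 5, T = 5),
                        meth_sd = c(N = 0, CN = 0, T = 0),
                        expr_sd = c(N = 0, CN = 0, T = 0), seed = 1)
  tab0 <- simulate_cohort(cfg0)
  expect_equal(unique(tab0$methylation[tab0$group == "N"]), 85)
  expect_equal(unique(tab0$expression[tab0$group == "T"]), 6)
  # group ordering in methylation with defaults
  tab <- simulate_cohort(cohort_config(n = c(N = 30, CN = 30, T = 30),
                                       seed = 2))
  mu <- tapply(tab$methylation, tab$group, mean)
  expect_true(mu[["N"]] > mu[["CN"]] && mu[["CN"]] > mu[["T"]])
  expect_true(all(tab$methylation >= 0 & tab$methylation <= 100))
  expect_true(all(tab$expression >= 0))
  # strong negative coupling shows in the rank correlation
  tabc <- simulate_cohort(cohort_config(coupling = -1, seed = 3))
  expect_lt(cor(tabc$methylation, tabc$expression, method = "spearman"), 0)
})

test_that("MNase fragments follow the linker-cut model", {
  lm <- default_locus
  tetra <- simulate_molecules(lm, sim_config(
    n_molecules = 10, state_mixture = c(tetra = 1), seed = 1))
  all_cut <- simulate_mnase(tetra, p_cut = 1)
  expect_equal(nrow(all_cut), 40)
  expect_true(all(all_cut$n_nucleosomes == 1))
  di <- simulate_molecules(lm, sim_config(
    n_molecules = 10, state_mixture = c(di = 1), seed = 1))
  uncut <- simulate_mnase(di, p_cut = 0)
  expect_true(all(uncut$n_nucleosomes == 2))
  # conservation: fragment nucleosome counts sum to input nucleosomes
  mix <- simulate_molecules(lm, sim_config(n_molecules = 200, seed = 6))
  fr <- simulate_mnase(mix, p_cut = 0.4, seed = 7)
  expect_equal(sum(fr$n_nucleosomes),
               sum(vapply(mix, function(m) nrow(m$footprints), 0L)))
})

test_that("MNase class frequencies match enumeration for p_cut = 0.5", {
  # 3 linkers, 8 equiprobable cut patterns: expected fragment-class
  # frequencies computed by exhaustive enumeration
  patterns <- expand.grid(c1 = 0:1, c2 = 0:1, c3 = 0:1)
  counts <- c(mono = 0, di = 0, tri = 0, tetra = 0)
  for (r in seq_len(nrow(patterns))) {
    cuts <- as.logical(patterns[r, ])
    sizes <- rle(cumsum(c(0, cuts)))$lengths
    for (s in sizes) counts[s] <- counts[s] + 1
  }
  expected <- counts / sum(counts)
  tetra <- simulate_molecules(default_locus, sim_config(
    n_molecules = 10000, state_mixture = c(tetra = 1), seed = 10))
  fr <- simulate_mnase(tetra, p_cut = 0.5, seed = 11)
  obs <- mnase_class_summary(fr)
  n <- nrow(fr)
  for (k in 1:4) {
    p <- expected[[k]]
    expect_lt(abs(obs$frequency[obs$n_nucleosomes == k] - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("synthetic genomes are deterministic with planted candidates", {
  g1 <- make_synthetic_genome(n_genes = 4, n_repeats = 8, seed = 5)
  g2 <- make_synthetic_genome(n_genes = 4, n_repeats = 8, seed = 5)
  expect_identical(g1, g2)
  expect_equal(sum(g1$manifest$is_candidate), 4)
  none <- make_synthetic_genome(n_genes = 3, n_repeats = 0, seed = 5)
  expect_equal(nrow(scan_candidate_asps(none$genes, none$repeats)), 0)
})
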