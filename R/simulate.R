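#' Simulation configuration for single-molecule M-SPA data
#'
#' Collects the free parameters of the generative model: the mixture of
#' promoter occupancy states, the GpC-methyltransferase marking
#' efficiency, the bisulfite conversion rate, and (optionally) a biphasic
#' endogenous CpG methylation mixture. One seed fixes all randomness.
#'
#' @param n_molecules Number of chromatin molecules (default 200, a
#'   typical clone-sequencing depth for a single locus).
#' @param state_mixture Named probabilities over `tetra`, `di`, `open`;
#'   must sum to 1. Default an equal tetra/di mixture, the two stable
#'   occupancy states of the L1 promoter.
#' @param enzyme_efficiency Probability that an accessible GpC is marked
#'   by the methyltransferase (default 0.85).
#' @param conversion_rate Probability that an unmethylated cytosine is
#'   bisulfite-converted to T (default 0.99).
#' @param endogenous_mixture Either `NULL` (default) — endogenous CpG
#'   methylation follows the chromatin state: tetra molecules fully
#'   methylated, di/open fully unmethylated — or a probability `w` that a
#'   molecule's strand is fully CpG-methylated (vs fully unmethylated),
#'   independent of state, modelling the biphasic strand mixture seen in
#'   patient bisulfite clones.
#' @param nucleosome_length Protected span per nucleosome core (147 bp).
#' @param linker Gap between a nucleosome edge and the adjacent TSS /
#'   neighbouring nucleosome (default 20 bp).
#' @param seed Integer seed, or `NULL` to use the ambient RNG state.
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(n_molecules = 200,
                       state_mixture = c(tetra = 0.5, di = 0.5, open = 0),
                       enzyme_efficiency = 0.85,
                       conversion_rate = 0.99,
                       endogenous_mixture = NULL,
                       nucleosome_length = 147,
                       linker = 20,
                       seed = NULL) {
  if (n_molecules < 0) stop("n_molecules must be >= 0", call. = FALSE)
  if (is.null(names(state_mixture)) ||
      !all(names(state_mixture) %in% c("tetra", "di", "open"))) {
    stop("state_mixture must be named with subset of tetra/di/open",
         call. = FALSE)
  }
  full <- c(tetra = 0, di = 0, open = 0)
  full[names(state_mixture)] <- state_mixture
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8) {
    stop("state_mixture probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  for (p in c(enzyme_efficiency, conversion_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(endogenous_mixture) &&
      (endogenous_mixture < 0 || endogenous_mixture > 1)) {
    stop("endogenous_mixture must lie in [0,1]", call. = FALSE)
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    state_mixture = full,
    enzyme_efficiency = enzyme_efficiency,
    conversion_rate = conversion_rate,
    endogenous_mixture = endogenous_mixture,
    nucleosome_length = as.integer(nucleosome_length),
    linker = as.integer(linker),
    seed = seed
  ), class = "sim_config")
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Nucleosome geometry for a state label on a locus. Tetra: a -1 and +1
# nucleosome flanking each TSS (+1s between the two start sites); di: the
# two +1 nucleosomes only; open: none.
state_footprints <- function(locus, state, nuc_len = 147, linker = 20) {
  ts <- locus$tss_sense; ta <- locus$tss_antisense
  plus1_s <- c(ts, ts + nuc_len - 1)
  plus1_a <- c(ta - nuc_len + 1, ta)
  minus1_s <- c(ts - linker - nuc_len, ts - linker - 1)
  minus1_a <- c(ta + linker + 1, ta + linker + nuc_len)
  if (plus1_a[1] <= plus1_s[2]) {
    stop("locus too short: the two +1 nucleosomes overlap; need ",
         "tss_antisense - tss_sense >= ", 2 * nuc_len - 1, call. = FALSE)
  }
  if (minus1_s[1] < 1 || minus1_a[2] > locus$length) {
    stop("locus too short: tetranucleosome span requires positions ",
         minus1_s[1], "-", minus1_a[2], " inside 1-", locus$length,
         call. = FALSE)
  }
  fp <- switch(state,
    tetra = rbind(minus1_s, plus1_s, plus1_a, minus1_a),
    di = rbind(plus1_s, plus1_a),
    open = matrix(numeric(0), ncol = 2)
  )
  role <- switch(state,
    tetra = c("-1_sense", "+1_sense", "+1_antisense", "-1_antisense"),
    di = c("+1_sense", "+1_antisense"),
    open = character(0)
  )
  data.frame(start = as.integer(fp[, 1]), end = as.integer(fp[, 2]),
             role = role, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate chromatin molecules over an L1 promoter locus
#'
#' Draws molecules from the configured occupancy-state mixture and places
#' their nucleosome footprints deterministically from the locus geometry.
#' Endogenous CpG methylation follows the state (tetra methylated, di and
#' open unmethylated) unless `cfg$endogenous_mixture` overrides it with an
#' independent biphasic strand mixture. Ground-truth labels are retained.
#'
#' @param locus A `locus_model`.
#' @param cfg A [sim_config()].
#' @return List of `molecule_state` objects, each with `id`,
#'   `state_label`, `footprints` (data frame start/end/role), and
#'   `endogenous_meth` (named `"M"`/`"U"` vector over CpG sites).
#' @export
simulate_molecules <- function(locus, cfg = sim_config()) {
  maybe_with_seed(cfg$seed, {
    # validate geometry up front even for n = 0
    for (st in names(cfg$state_mixture)[cfg$state_mixture > 0]) {
      if (st != "open") state_footprints(locus, st, cfg$nucleosome_length,
                                         cfg$linker)
    }
    n <- cfg$n_molecules
    states <- if (n > 0) {
      sample(names(cfg$state_mixture), n, replace = TRUE,
             prob = cfg$state_mixture)
    } else character(0)
    cpg <- locus$site_map$cpg_sites
    lapply(seq_len(n), function(i) {
      st <- states[[i]]
      fully_meth <- if (is.null(cfg$endogenous_mixture)) {
        st == "tetra"
      } else {
        stats::runif(1) < cfg$endogenous_mixture
      }
      meth <- stats::setNames(rep(if (fully_meth) "M" else "U", length(cpg)),
                              cpg)
      structure(list(
        id = sprintf("mol_%04d", i),
        state_label = st,
        footprints = state_footprints(locus, st, cfg$nucleosome_length,
                                      cfg$linker),
        endogenous_meth = meth
      ), class = "molecule_state")
    })
  })
}

in_any_footprint <- function(pos, footprints) {
  if (nrow(footprints) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) {
    any(p >= footprints$start & p <= footprints$end)
  }, logical(1))
}

#' Simulate GpC methyltransferase treatment of one molecule
#'
#' Each informative GpC outside every nucleosome footprint is marked with
#' probability `cfg$enzyme_efficiency`; GpCs under a footprint are never
#' marked. Endogenous CpG states are copied through unchanged; excluded
#' (GpCpG) sites carry no call. One uniform draw is spent per GpC site
#' regardless of accessibility, so runs with the same seed but different
#' efficiencies use nested mark sets.
#'
#' @param mol A `molecule_state`.
#' @param locus The `locus_model` the molecule was simulated on.
#' @param cfg A [sim_config()].
#' @return Named character vector over all informative sites (ascending),
#'   values `"M"`/`"U"`, with attribute `class_by_site` (`"cpg"`/`"gpc"`).
#' @export
simulate_enzyme_treatment <- function(mol, locus, cfg = sim_config()) {
  maybe_with_seed(cfg$seed, {
    gpc <- locus$site_map$gpc_sites
    u <- stats::runif(length(gpc))
    accessible <- !in_any_footprint(gpc, mol$footprints)
    gpc_state <- ifelse(accessible & u < cfg$enzyme_efficiency, "M", "U")
    sites <- informative_sites(locus)
    state <- character(nrow(sites))
    state[sites$class == "cpg"] <- unname(mol$endogenous_meth[
      as.character(sites$site[sites$class == "cpg"])])
    state[sites$class == "gpc"] <- gpc_state[match(
      sites$site[sites$class == "gpc"], gpc)]
    out <- stats::setNames(state, sites$site)
    attr(out, "class_by_site") <- stats::setNames(sites$class, sites$site)
    out
  })
}

#' Simulate a bisulfite-converted clone read
#'
#' Methylated cytosines (endogenous CpG or enzyme-marked GpC) remain C;
#' every other cytosine is converted to T with probability
#' `cfg$conversion_rate` (a failed conversion leaves C, the single noise
#' channel of the generator). Non-C bases are unchanged, so the read has
#' the reference length. Excluded GpCpG cytosines behave as CpGs of the
#' molecule's strand state and are additionally protected when marked by
#' the enzyme; they are never read by the caller.
#'
#' @param mol A `molecule_state`.
#' @param marks Mark map from [simulate_enzyme_treatment()].
#' @param locus The `locus_model`.
#' @param cfg A [sim_config()].
#' @return A single character string, the top-strand clone sequence.
#' @export
simulate_bisulfite_read <- function(mol, marks, locus, cfg = sim_config()) {
  maybe_with_seed(cfg$seed, {
    chars <- strsplit(locus$reference, "", fixed = TRUE)[[1]]
    c_pos <- which(chars == "C")
    meth <- rep(FALSE, length(chars))
    meth[as.integer(names(marks))] <- marks == "M"
    excl <- locus$site_map$excluded_sites
    if (length(excl)) {
      strand_m <- length(mol$endogenous_meth) > 0 &&
        all(mol$endogenous_meth == "M")
      if (strand_m) meth[excl] <- TRUE
      open_excl <- excl[!in_any_footprint(excl, mol$footprints)]
      if (length(open_excl)) {
        meth[open_excl] <- meth[open_excl] |
          (stats::runif(length(open_excl)) < cfg$enzyme_efficiency)
      }
    }
    # one draw per cytosine regardless of its state, so runs sharing a
    # seed are coupled (common random numbers) across parameter values
    u <- stats::runif(length(c_pos))
    convert <- c_pos[!meth[c_pos] & u < cfg$conversion_rate]
    chars[convert] <- "T"
    paste(chars, collapse = "")
  })
}

#' Simulate a complete M-SPA clone set with ground truth
#'
#' Runs the molecule, enzyme, and bisulfite stages under a single seed and
#' returns reads alongside the generative truth, for round-trip testing
#' and parameter-recovery experiments.
#'
#' @param locus A `locus_model`.
#' @param cfg A [sim_config()]; `cfg$seed` (if non-NULL) fixes the whole run.
#' @return List with `molecules`, `marks` (list of mark maps), `reads`
#'   (named character vector), and `truth` (tibble: id, state ground truth,
#'   endogenous strand class).
#' @export
simulate_clone_set <- function(locus, cfg = sim_config()) {
  maybe_with_seed(cfg$seed, {
    inner <- cfg
    inner$seed <- NULL
    molecules <- simulate_molecules(locus, inner)
    marks <- lapply(molecules, simulate_enzyme_treatment, locus = locus,
                    cfg = inner)
    reads <- vapply(seq_along(molecules), function(i) {
      simulate_bisulfite_read(molecules[[i]], marks[[i]], locus, inner)
    }, character(1))
    names(reads) <- vapply(molecules, `[[`, character(1), "id")
    truth <- tibble::tibble(
      id = names(reads),
      state = vapply(molecules, `[[`, character(1), "state_label"),
      strand_meth = vapply(molecules, function(m) {
        if (length(m$endogenous_meth) == 0) "none"
        else if (all(m$endogenous_meth == "M")) "fully_methylated"
        else "fully_unmethylated"
      }, character(1))
    )
    list(molecules = molecules, marks = marks, reads = reads, truth = truth)
  })
}

#' Simulate partial MNase digestion of molecules
#'
#' Cuts each inter-nucleosome linker independently with probability
#' `p_cut`; a fragment's class is the number of nucleosome cores it spans
#' (mono, di, tri, tetra, ...). Molecules without nucleosomes yield no
#' fragments.
#'
#' @param molecules List of `molecule_state`.
#' @param p_cut Per-linker cut probability in \[0,1\].
#' @param seed Optional seed.
#' @return Tibble with one row per fragment: `molecule`, `n_nucleosomes`.
#' @export
simulate_mnase <- function(molecules, p_cut, seed = NULL) {
  if (p_cut < 0 || p_cut > 1) stop("p_cut must lie in [0,1]", call. = FALSE)
  maybe_with_seed(seed, {
    rows <- lapply(molecules, function(mol) {
      m <- nrow(mol$footprints)
      if (m == 0L) return(NULL)
      cuts <- if (m > 1) stats::runif(m - 1) < p_cut else logical(0)
      # fragment sizes = run lengths between cuts
      grp <- cumsum(c(0L, as.integer(cuts)))
      sizes <- as.integer(table(grp))
      tibble::tibble(molecule = mol$id, n_nucleosomes = sizes)
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0L) {
      out <- tibble::tibble(molecule = character(0),
                            n_nucleosomes = integer(0))
    }
    out
  })
}

#' Summarise an MNase fragment population by nucleosome class
#'
#' @param fragments Output of [simulate_mnase()].
#' @return Tibble with `class` (mono/di/tri/tetra/5+...), `n_nucleosomes`,
#'   `count`, `frequency`.
#' @export
mnase_class_summary <- function(fragments) {
  lab <- function(k) {
    nm <- c("mono", "di", "tri", "tetra")
    ifelse(k <= 4, nm[k], paste0(k, "-mer"))
  }
  if (nrow(fragments) == 0L) {
    return(tibble::tibble(class = character(0), n_nucleosomes = integer(0),
                          count = integer(0), frequency = numeric(0)))
  }
  tab <- table(fragments$n_nucleosomes)
  k <- as.integer(names(tab))
  tibble::tibble(class = lab(k), n_nucleosomes = k,
                 count = as.integer(tab),
                 frequency = as.integer(tab) / nrow(fragments))
}
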