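#' Cohort simulation configuration
#'
#' Parameters for a synthetic three-group methylation/expression cohort
#' emulating the structure of patient bladder data: normal tissue from
#' cancer-free bladders (N, high methylation, low alternate-transcript
#' expression), histologically normal tissue from tumor-bearing bladders
#' (CN, intermediate/hypomethylated), and tumors (T, hypomethylated, high
#' expression). Defaults for group sizes follow the study design (19
#' normal donors) with CN/T cohorts of comparable size; means/sds are
#' chosen as values typical of locus-specific bisulfite assays.
#'
#' @param n Named group sizes, default `c(N = 19, CN = 24, T = 26)`.
#' @param meth_mean,meth_sd Named per-group methylation mean/sd on
#'   \[0,100\] percent.
#' @param expr_mean,expr_sd Named per-group relative expression mean/sd
#'   (arbitrary units relative to a housekeeping gene).
#' @param coupling Methylation-expression coupling coefficient in
#'   \[-1,1\]: the within-group correlation between a sample's methylation
#'   deviation and its expression deviation. Negative by construction of
#'   the biology (hypomethylation activates the promoter); default -0.8.
#' @param seed Integer seed or `NULL`.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n = c(N = 19, CN = 24, T = 26),
                          meth_mean = c(N = 85, CN = 50, T = 30),
                          meth_sd = c(N = 7, CN = 18, T = 15),
                          expr_mean = c(N = 1, CN = 3.5, T = 6),
                          expr_sd = c(N = 0.5, CN = 1.5, T = 2),
                          coupling = -0.8,
                          seed = NULL) {
  groups <- names(n)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("`n` must be a named vector of group sizes", call. = FALSE)
  }
  if (any(n < 0)) stop("group sizes must be >= 0", call. = FALSE)
  for (v in list(meth_mean, meth_sd, expr_mean, expr_sd)) {
    if (!all(groups %in% names(v))) {
      stop("all per-group parameters must name every group", call. = FALSE)
    }
  }
  if (any(meth_sd < 0) || any(expr_sd < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (coupling < -1 || coupling > 1) {
    stop("coupling must lie in [-1,1]", call. = FALSE)
  }
  structure(list(n = n, meth_mean = meth_mean, meth_sd = meth_sd,
                 expr_mean = expr_mean, expr_sd = expr_sd,
                 coupling = coupling, seed = seed),
            class = "cohort_config")
}

#' Simulate a per-sample cohort table
#'
#' Draws per-sample methylation (clipped to \[0,100\]) and expression
#' (truncated at 0) from per-group Gaussians. Within each group the
#' expression deviation is coupled to the methylation deviation with
#' correlation `cfg$coupling` (negative: lower methylation, higher
#' alternate-transcript expression).
#'
#' @param cfg A [cohort_config()].
#' @return Tibble with `sample`, `group`, `methylation`, `expression`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  maybe_with_seed(cfg$seed, {
    rows <- lapply(names(cfg$n), function(g) {
      ng <- cfg$n[[g]]
      if (ng == 0L) return(NULL)
      z1 <- stats::rnorm(ng)
      z2 <- stats::rnorm(ng)
      rho <- cfg$coupling
      meth <- cfg$meth_mean[[g]] + cfg$meth_sd[[g]] * z1
      expr <- cfg$expr_mean[[g]] +
        cfg$expr_sd[[g]] * (rho * z1 + sqrt(1 - rho^2) * z2)
      tibble::tibble(
        sample = sprintf("%s_%02d", g, seq_len(ng)),
        group = g,
        methylation = pmin(100, pmax(0, meth)),
        expression = pmax(0, expr)
      )
    })
    dplyr::bind_rows(rows)
  })
}
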