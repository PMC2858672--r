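#' Mann-Whitney U test
#'
#' Rank-sum test with mid-rank tie handling. `U` is reported for the
#' first group (number of pairs where `a` beats `b`, ties counted 0.5).
#' The two-sided p-value is computed by full enumeration of all
#' `choose(n1+n2, n1)` group labellings when `n1 + n2 <= 16` and the
#' pooled data carry no ties; otherwise by normal approximation with tie
#' correction and continuity correction. The method used is recorded.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return List with `U`, `p`, `method` (`"exact"` /
#'   `"normal-approximation"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && n1 + n2 <= 16) {
    u_all <- u_null_distribution(r, n1)
    lo <- min(u, n1 * n2 - u)
    hi <- n1 * n2 - lo
    p <- mean(u_all <= lo + 1e-9 | u_all >= hi - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal-approximation"
  }
  list(U = u, p = max(p, .Machine$double.xmin), method = method,
       n1 = n1, n2 = n2)
}

# All U values over every assignment of n1 of the pooled ranks to group a.
u_null_distribution <- function(ranks, n1) {
  idx <- utils::combn(length(ranks), n1)
  colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold and accumulates
#' (false-positive rate, true-positive rate) points; tied scores move
#' both coordinates at once, so the trapezoid AUC credits ties 0.5 —
#' making AUC exactly `U / (n1 * n2)` of the corresponding Mann-Whitney
#' statistic. `direction` declares which way the positive class scores:
#' for methylation variables the disease signal is hypomethylation, so
#' the default treats LOW scores as positive.
#'
#' @param scores_pos Scores of the positive class (e.g. tumors).
#' @param scores_neg Scores of the negative class.
#' @param direction `"low"` if low scores indicate the positive class
#'   (default), `"high"` otherwise.
#' @return List with `points` (tibble `fpr`, `tpr`, from (0,0) to (1,1)),
#'   `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores_pos, scores_neg, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("empty group", call. = FALSE)
  }
  sp <- as.numeric(scores_pos); sn <- as.numeric(scores_neg)
  if (direction == "low") { sp <- -sp; sn <- -sn }
  thr <- sort(unique(c(sp, sn)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn >= t), numeric(1))
  pts <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, tibble::tibble(fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc, direction = direction,
       n_pos = length(sp), n_neg = length(sn))
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Per-group summary with pairwise Mann-Whitney contrasts
#'
#' Summarises a cohort variable per group (n, mean, median — figure-style
#' horizontal lines mark the mean) and tests every group pair with
#' [mann_whitney_u()], assigning significance stars at the conventional
#' cutpoints (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05). Pairs
#' involving a single-sample group are skipped with a warning. No
#' multiple-testing correction is applied by default; `adjust =
#' "bonferroni"` is available.
#'
#' @param table Cohort tibble with `group` and the `variable` column.
#' @param variable Column to summarise (default `"methylation"`).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return List with `groups` (tibble: group, n, mean, median) and
#'   `contrasts` (tibble: group1, group2, U, p, method, stars).
#' @export
group_summary <- function(table, variable = "methylation",
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!variable %in% names(table)) {
    stop("no column `", variable, "` in the cohort table", call. = FALSE)
  }
  groups <- unique(table$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  x <- split(table[[variable]], factor(table$group, levels = groups))
  gs <- tibble::tibble(
    group = groups,
    n = unname(vapply(x, length, integer(1))),
    mean = unname(vapply(x, mean, numeric(1))),
    median = unname(vapply(x, stats::median, numeric(1)))
  )
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- x[[pr[1]]]; b <- x[[pr[2]]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("contrast ", pr[1], " vs ", pr[2],
              " skipped: single-sample group", call. = FALSE)
      return(NULL)
    }
    t <- mann_whitney_u(a, b)
    tibble::tibble(group1 = pr[1], group2 = pr[2], U = t$U, p = t$p,
                   method = t$method)
  })
  contrasts <- dplyr::bind_rows(rows)
  if (nrow(contrasts)) {
    if (adjust == "bonferroni") {
      contrasts$p <- pmin(1, contrasts$p * nrow(contrasts))
    }
    contrasts$stars <- p_stars(contrasts$p)
  }
  list(groups = gs, contrasts = contrasts)
}

#' Methylation-expression rank correlation
#'
#' Spearman rank correlation between per-sample methylation and
#' expression across the whole cohort, with its sign reported — the
#' biological expectation is negative (hypomethylated promoters express
#' the alternate transcript).
#'
#' @param table Cohort tibble with `methylation` and `expression`.
#' @return List with `rho`, `sign` (`"negative"`/`"positive"`/`"zero"`),
#'   `n`.
#' @export
methylation_expression_correlation <- function(table) {
  m <- table$methylation; e <- table$expression
  if (length(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(m) == 0 || stats::sd(e) == 0) {
    stop("correlation undefined: constant variable", call. = FALSE)
  }
  rho <- stats::cor(m, e, method = "spearman")
  list(rho = rho,
       sign = if (rho < 0) "negative" else if (rho > 0) "positive"
       else "zero",
       n = length(m))
}
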