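#' Call per-site methylation from one bisulfite clone read
#'
#' The clone must be a full-length ungapped amplicon of the locus. At
#' every informative site (CpG or GpC; GpCpG-excluded sites are skipped)
#' a retained C is called methylated, a converted T unmethylated, and any
#' other base missing. Clones whose non-site positions disagree with the
#' converted reference at more than `max_mismatch` are rejected as
#' foreign.
#'
#' @param read Clone sequence (same length as the locus reference).
#' @param locus A `locus_model`.
#' @param max_mismatch Maximum tolerated fraction of disagreeing non-site
#'   positions (default 0.10).
#' @return Named character vector over informative sites with values
#'   `"M"`, `"U"`, `"."` and attribute `class_by_site`.
#' @export
call_methylation <- function(read, locus, max_mismatch = 0.10) {
  read <- toupper(read)
  if (nchar(read) != locus$length) {
    stop("read length (", nchar(read), ") does not match locus length (",
         locus$length, ")", call. = FALSE)
  }
  ref <- strsplit(locus$reference, "", fixed = TRUE)[[1]]
  obs <- strsplit(read, "", fixed = TRUE)[[1]]
  sites <- informative_sites(locus)
  non_site <- setdiff(which(ref %in% c("A", "C", "G", "T")), sites$site)
  is_c <- ref[non_site] == "C"
  ok <- ifelse(is_c, obs[non_site] %in% c("C", "T"),
               obs[non_site] == ref[non_site])
  if (length(non_site) && mean(!ok) > max_mismatch) {
    stop(sprintf(
      "foreign clone: %.1f%% of non-site positions disagree with the converted reference",
      100 * mean(!ok)), call. = FALSE)
  }
  b <- obs[sites$site]
  call <- ifelse(b == "C", "M", ifelse(b == "T", "U", "."))
  out <- stats::setNames(call, sites$site)
  attr(out, "class_by_site") <- stats::setNames(sites$class, sites$site)
  out
}

#' Build a call matrix from clone reads
#'
#' @param reads Named character vector of clone sequences.
#' @param locus A `locus_model`.
#' @param max_mismatch Passed to [call_methylation()].
#' @return A `call_matrix`: character matrix (`"M"`/`"U"`/`"."`) with
#'   clone ids as rownames, site positions as colnames, and attribute
#'   `site_class`.
#' @export
call_matrix <- function(reads, locus, max_mismatch = 0.10) {
  if (is.null(names(reads)) || anyDuplicated(names(reads))) {
    stop("reads must carry unique names (clone ids)", call. = FALSE)
  }
  rows <- lapply(reads, call_methylation, locus = locus,
                 max_mismatch = max_mismatch)
  sites <- informative_sites(locus)
  mat <- do.call(rbind, lapply(rows, unname))
  if (is.null(mat)) mat <- matrix(character(0), nrow = 0,
                                  ncol = nrow(sites))
  dimnames(mat) <- list(names(reads), sites$site)
  structure(mat, site_class = stats::setNames(sites$class, sites$site),
            class = c("call_matrix", class(mat)))
}

site_class_of <- function(mat) attr(mat, "site_class")

# Column positions (as integers) of a call matrix.
matrix_sites <- function(mat) as.integer(colnames(mat))

# Resolve a site subset: NULL -> all columns of the given class filter.
resolve_sites <- function(mat, sites = NULL, class = c("all", "cpg", "gpc")) {
  class <- match.arg(class)
  cols <- matrix_sites(mat)
  keep <- if (class == "all") cols else cols[site_class_of(mat) == class]
  if (!is.null(sites)) keep <- intersect(keep, as.integer(sites))
  if (!length(keep)) stop("empty site subset", call. = FALSE)
  keep
}

#' Clone-level bisulfite conversion QC
#'
#' Conversion efficiency per clone is the fraction of cytosines outside
#' any CpG/GpC/GpCpG context (which carry no biological methylation) read
#' as T. Clones below `min_conversion` are removed and logged.
#'
#' @param reads Named clone sequences.
#' @param locus A `locus_model`.
#' @param min_conversion Minimum conversion efficiency (default 0.95).
#' @param max_mismatch Passed to [call_methylation()].
#' @return List with `matrix` (filtered `call_matrix`) and `qc` (tibble:
#'   clone, conversion, pass).
#' @export
qc_clones <- function(reads, locus, min_conversion = 0.95,
                      max_mismatch = 0.10) {
  if (min_conversion < 0 || min_conversion > 1) {
    stop("min_conversion must lie in [0,1]", call. = FALSE)
  }
  mat <- call_matrix(reads, locus, max_mismatch = max_mismatch)
  ref <- strsplit(locus$reference, "", fixed = TRUE)[[1]]
  sm <- locus$site_map
  other_c <- setdiff(which(ref == "C"),
                     c(sm$cpg_sites, sm$gpc_sites, sm$excluded_sites))
  conv <- vapply(reads, function(rd) {
    b <- strsplit(toupper(rd), "", fixed = TRUE)[[1]][other_c]
    if (!length(b)) return(NA_real_)
    mean(b == "T")
  }, numeric(1))
  pass <- !is.na(conv) & conv >= min_conversion
  qc <- tibble::tibble(clone = names(reads), conversion = unname(conv),
                       pass = unname(pass))
  if (!any(pass)) {
    stop("all ", length(reads), " clones fail conversion QC at threshold ",
         min_conversion, call. = FALSE)
  }
  n_drop <- sum(!pass)
  if (n_drop > 0) {
    message("qc_clones: removed ", n_drop, " of ", length(reads),
            " clones below conversion ", min_conversion)
  }
  kept <- mat[pass, , drop = FALSE]
  attr(kept, "site_class") <- site_class_of(mat)
  class(kept) <- class(mat)
  list(matrix = kept, qc = qc)
}

#' Percent methylation per site and over a site subset
#'
#' Per site, 100 x methylated / (methylated + unmethylated), ignoring
#' missing calls; the subset summary is the unweighted mean of per-site
#' values (matching assays that average a small CpG panel). Sites with
#' zero informative calls are flagged and excluded from the mean.
#'
#' @param mat A `call_matrix`.
#' @param sites Optional integer site subset (default: all columns after
#'   the `class` filter).
#' @param class Restrict to `"cpg"`, `"gpc"`, or `"all"` columns.
#' @return List with `per_site` (tibble: site, class, n_meth, n_unmeth,
#'   percent, flagged) and `mean` (unweighted mean over unflagged sites).
#' @export
percent_methylation <- function(mat, sites = NULL, class = "cpg") {
  keep <- resolve_sites(mat, sites, class)
  sub <- mat[, as.character(keep), drop = FALSE]
  n_m <- colSums(sub == "M")
  n_u <- colSums(sub == "U")
  pct <- ifelse(n_m + n_u > 0, 100 * n_m / (n_m + n_u), NA_real_)
  per_site <- tibble::tibble(
    site = keep,
    class = unname(site_class_of(mat)[as.character(keep)]),
    n_meth = unname(n_m), n_unmeth = unname(n_u),
    percent = unname(pct),
    flagged = unname(n_m + n_u == 0)
  )
  if (any(per_site$flagged)) {
    message("percent_methylation: ", sum(per_site$flagged),
            " site(s) with zero informative calls excluded from the mean")
  }
  list(per_site = per_site,
       mean = mean(per_site$percent[!per_site$flagged]))
}

#' Percent of fully unmethylated strands (PUR) over a site subset
#'
#' Molecules with any missing call in the subset are dropped (and
#' counted). Of the retained molecules, reports the percentage that are
#' unmethylated at every site — the fully-unmethylated-reference value —
#' together with the fully methylated and intermediate percentages
#' (the three sum to 100).
#'
#' @inheritParams percent_methylation
#' @return List with `pur`, `fully_methylated`, `intermediate`
#'   (percentages), `n_retained`, `n_dropped`.
#' @export
fully_unmethylated_fraction <- function(mat, sites = NULL, class = "cpg") {
  keep <- resolve_sites(mat, sites, class)
  sub <- mat[, as.character(keep), drop = FALSE]
  complete <- rowSums(sub == ".") == 0
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message("fully_unmethylated_fraction: dropped ", n_drop,
            " molecule(s) with missing calls in the subset")
  }
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no molecules with complete calls over the site subset",
         call. = FALSE)
  }
  all_u <- rowSums(sub == "U") == ncol(sub)
  all_m <- rowSums(sub == "M") == ncol(sub)
  list(pur = 100 * mean(all_u),
       fully_methylated = 100 * mean(all_m),
       intermediate = 100 * mean(!all_u & !all_m),
       n_retained = nrow(sub), n_dropped = n_drop)
}

#' Strand-level methylation distribution
#'
#' Per molecule, 100 x methylated / (methylated + unmethylated) over the
#' subset; binned in `bin_width`-percent bins with the exact-0 and
#' exact-100 masses reported separately, since biphasic mixtures
#' concentrate at the endpoints.
#'
#' @inheritParams percent_methylation
#' @param bin_width Histogram bin width in percent (default 10).
#' @return List with `per_molecule` (tibble: clone, percent), `histogram`
#'   (tibble: bin label, lower, upper, count), `exact_0`, `exact_100`
#'   (counts), `n`.
#' @export
strand_distribution <- function(mat, sites = NULL, class = "cpg",
                                bin_width = 10) {
  if (nrow(mat) < 1L) stop("need at least one molecule", call. = FALSE)
  keep <- resolve_sites(mat, sites, class)
  sub <- mat[, as.character(keep), drop = FALSE]
  n_m <- rowSums(sub == "M"); n_u <- rowSums(sub == "U")
  pct <- ifelse(n_m + n_u > 0, 100 * n_m / (n_m + n_u), NA_real_)
  per_molecule <- tibble::tibble(clone = rownames(sub), percent = unname(pct))
  ok <- !is.na(pct)
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  # [a,b) bins with the last bin closed so exact-100 strands are counted
  cut_idx <- cut(pct[ok], breaks = breaks, include.lowest = TRUE,
                 right = FALSE)
  hist <- tibble::tibble(
    bin = levels(cut_idx),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = as.integer(table(cut_idx))
  )
  list(per_molecule = per_molecule, histogram = hist,
       exact_0 = sum(pct[ok] == 0), exact_100 = sum(pct[ok] == 100),
       n = sum(ok))
}

#' Concordance between two quantitative methylation assays
#'
#' Pearson correlation between two per-sample percent-methylation
#' vectors, e.g. the same samples measured over two different CpG panels.
#'
#' @param values_a,values_b Numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @export
assay_concordance <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(values_a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("correlation undefined: zero variance in one assay", call. = FALSE)
  }
  stats::cor(values_a, values_b)
}

#' Lollipop-style text rendering of a call matrix
#'
#' One line per clone: filled circles for methylated sites, open circles
#' for unmethylated, `.` for missing — mirroring the figure convention of
#' single-molecule bisulfite panels.
#'
#' @param mat A `call_matrix`.
#' @param class Restrict to one site class or `"all"`.
#' @return Character vector, one element per clone (named).
#' @export
render_lollipop <- function(mat, class = "all") {
  keep <- resolve_sites(mat, NULL, class)
  sub <- mat[, as.character(keep), drop = FALSE]
  glyph <- matrix("." , nrow = nrow(sub), ncol = ncol(sub))
  glyph[sub == "M"] <- "●"
  glyph[sub == "U"] <- "○"
  stats::setNames(apply(glyph, 1, paste, collapse = ""), rownames(sub))
}
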