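#' Accessibility vector from a call-matrix row
#'
#' In an M-SPA experiment an enzyme-methylated GpC was accessible and an
#' unmethylated GpC was protected. CpG columns (endogenous methylation)
#' are dropped.
#'
#' @param row A named call vector (one `call_matrix` row via
#'   `mat[i, ]` keeps names) or a single-row matrix; must carry a
#'   `class_by_site`/`site_class` attribute or be accompanied by `locus`.
#' @param locus Optional `locus_model` used to identify GpC columns when
#'   the row carries no class attribute.
#' @return Tibble with `site` (ascending) and `call` in
#'   `accessible`/`protected`/`missing`.
#' @export
accessibility_calls <- function(row, locus = NULL) {
  if (is.matrix(row)) {
    cls <- site_class_of(row)
    row <- stats::setNames(row[1, ], colnames(row))
    attr(row, "class_by_site") <- cls
  }
  cls <- attr(row, "class_by_site")
  if (is.null(cls) && !is.null(locus)) {
    s <- informative_sites(locus)
    cls <- stats::setNames(s$class, s$site)
  }
  if (is.null(cls)) stop("row carries no site-class information", call. = FALSE)
  gpc <- names(row)[cls[names(row)] == "gpc"]
  if (!length(gpc)) {
    stop("no GpC columns: not an M-SPA experiment", call. = FALSE)
  }
  site <- as.integer(gpc)
  o <- order(site)
  call <- c(M = "accessible", U = "protected", "." = "missing")[row[gpc][o]]
  tibble::tibble(site = site[o], call = unname(call))
}

#' Call nucleosome footprints from an accessibility vector
#'
#' Maximal runs of protected GpC sites (missing calls are neutral: they
#' neither extend nor break a run; up to `k` isolated accessible calls
#' may be absorbed per patch) become footprints. A footprint's span
#' extends from the midpoint between its first protected site and the
#' previous accessible site (or the amplicon start) to the midpoint
#' between its last protected site and the next accessible site (or the
#' amplicon end). Spans within `nucleosome_range` bp are classified
#' `nucleosome`, shorter `sub-nucleosomal`, longer `super-nucleosomal`.
#'
#' @param vec Tibble from [accessibility_calls()].
#' @param amplicon_length Amplicon length in bp (span clamp).
#' @param k Maximum accessible calls absorbed per patch (default 0).
#' @param nucleosome_range Length window in bp for the nucleosome class
#'   (default `c(120, 200)`: core particle 147 bp plus resolution slack).
#' @return Tibble with `start`, `end`, `length`, `n_protected_sites`,
#'   `first_site`, `last_site`, `classification`; zero rows if no
#'   protected sites.
#' @export
call_footprints <- function(vec, amplicon_length, k = 0,
                            nucleosome_range = c(120, 200)) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), n_protected_sites = integer(0),
                          first_site = integer(0), last_site = integer(0),
                          classification = character(0))
  v <- vec[vec$call != "missing", , drop = FALSE]
  if (nrow(v) < 1L || !any(v$call == "protected")) return(empty)
  prot <- v$call == "protected"
  # protected runs over the informative (non-missing) sites
  r <- rle(prot)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.frame(start = idx_start[r$values], end = idx_end[r$values],
                     absorbed = 0L)
  # absorb <= k isolated accessible calls per patch (greedy, left to right)
  if (k > 0 && nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap >= 1L && merged$absorbed[nrow(merged)] + gap <= k) {
        merged$end[nrow(merged)] <- runs$end[i]
        merged$absorbed[nrow(merged)] <-
          merged$absorbed[nrow(merged)] + gap
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  acc_sites <- v$site[v$call == "accessible"]
  out <- lapply(seq_len(nrow(runs)), function(i) {
    first <- v$site[runs$start[i]]
    last <- v$site[runs$end[i]]
    prev_acc <- acc_sites[acc_sites < first]
    next_acc <- acc_sites[acc_sites > last]
    start <- if (length(prev_acc)) {
      as.integer(floor((max(prev_acc) + first) / 2))
    } else 1L
    end <- if (length(next_acc)) {
      as.integer(ceiling((last + min(next_acc)) / 2))
    } else as.integer(amplicon_length)
    len <- end - start + 1L
    cls <- if (len < nucleosome_range[1]) "sub-nucleosomal"
    else if (len > nucleosome_range[2]) "super-nucleosomal"
    else "nucleosome"
    n_prot <- sum(v$site >= first & v$site <= last & v$call == "protected")
    tibble::tibble(start = start, end = end, length = len,
                   n_protected_sites = n_prot,
                   first_site = first, last_site = last,
                   classification = cls)
  })
  dplyr::bind_rows(out)
}

# The four classification windows around the two TSSs: a `window`-bp
# span directly up- (-1) and downstream (+1) of each start site, in its
# transcription direction (sense rightward, antisense leftward).
promoter_windows <- function(locus, window = 147) {
  ts <- locus$tss_sense; ta <- locus$tss_antisense
  data.frame(
    name = c("minus1_sense", "plus1_sense", "plus1_antisense",
             "minus1_antisense"),
    start = c(ts - window, ts, ta - window + 1L, ta + 1L),
    end = c(ts - 1L, ts + window - 1L, ta, ta + window),
    stringsAsFactors = FALSE
  )
}

overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

#' Classify the promoter occupancy state of one molecule
#'
#' Applies a fixed rule set over the four 147 bp windows flanking the two
#' TSSs. The molecule is `tetranucleosomal` if >= `tetra_threshold` of
#' its informative GpC sites over the promoter span are protected, or if
#' all four windows are substantially covered by footprints (abutting
#' nucleosomes merge into a single patch when their linker carries no
#' marked GpC, so the global-protection rule is primary).
#' `dinucleosomal` requires a nucleosome-sized or larger footprint over
#' both +1 windows while both -1 windows contain at least one accessible
#' site and no substantial footprint — the nucleosome-free regions
#' upstream of both TSSs that mark the active promoter. `open` requires
#' the protected fraction to be at most `open_threshold`. Everything else
#' (including any window without informative GpC sites) is `other`.
#'
#' @param vec Accessibility tibble from [accessibility_calls()].
#' @param locus A `locus_model`.
#' @param footprints Optional precomputed [call_footprints()] output
#'   (computed from `vec` when `NULL`).
#' @param window Window size in bp (default 147).
#' @param tetra_threshold,open_threshold Protected-fraction cutoffs
#'   (defaults 0.9 and 0.1).
#' @param min_overlap Minimum footprint/window overlap in bp for a
#'   window to count as occupied (default 40; small sub-nucleosomal
#'   patches from isolated unmarked GpCs are ignored).
#' @param veto_cover Fraction of a -1 window that a footprint must cover
#'   to veto the nucleosome-free-region call (default 0.5). Vetoing is
#'   held to a stricter standard than claiming occupancy because span
#'   edges are uncertain by up to half an inter-GpC gap, so a genuine +1
#'   footprint can jut a few tens of bp past the TSS.
#' @param k,nucleosome_range Passed to [call_footprints()] when
#'   `footprints` is `NULL`.
#' @return List with `state`, `protected_fraction`, `evidence`
#'   (per-window tibble), and `footprints`.
#' @export
classify_promoter_state <- function(vec, locus, footprints = NULL,
                                    window = 147,
                                    tetra_threshold = 0.9,
                                    open_threshold = 0.1,
                                    min_overlap = 40, veto_cover = 0.5,
                                    k = 0, nucleosome_range = c(120, 200)) {
  if (is.null(footprints)) {
    footprints <- call_footprints(vec, locus$length, k = k,
                                  nucleosome_range = nucleosome_range)
  }
  win <- promoter_windows(locus, window)
  span <- c(min(win$start), max(win$end))
  v <- vec[vec$call != "missing" & vec$site >= span[1] &
             vec$site <= span[2], , drop = FALSE]
  occupied <- function(w_start, w_end, classes, min_ov) {
    if (nrow(footprints) == 0L) return(FALSE)
    ov <- overlap_len(footprints$start, footprints$end, w_start, w_end)
    any(ov >= min_ov & footprints$classification %in% classes)
  }
  big_classes <- c("nucleosome", "super-nucleosomal")
  veto_bp <- ceiling(veto_cover * window)
  evidence <- tibble::tibble(
    window = win$name, start = win$start, end = win$end,
    n_informative = vapply(seq_len(nrow(win)), function(i) {
      sum(v$site >= win$start[i] & v$site <= win$end[i])
    }, integer(1)),
    n_accessible = vapply(seq_len(nrow(win)), function(i) {
      sum(v$site >= win$start[i] & v$site <= win$end[i] &
            v$call == "accessible")
    }, integer(1)),
    footprinted = vapply(seq_len(nrow(win)), function(i) {
      occupied(win$start[i], win$end[i], big_classes, min_overlap)
    }, logical(1)),
    covered = vapply(seq_len(nrow(win)), function(i) {
      occupied(win$start[i], win$end[i], big_classes, veto_bp)
    }, logical(1))
  )
  prot_frac <- if (nrow(v)) mean(v$call == "protected") else NA_real_
  state <- if (any(evidence$n_informative == 0L) || is.na(prot_frac)) {
    "other"
  } else if (prot_frac >= tetra_threshold || all(evidence$covered)) {
    "tetranucleosomal"
  } else {
    plus1 <- evidence$window %in% c("plus1_sense", "plus1_antisense")
    minus1 <- evidence$window %in% c("minus1_sense", "minus1_antisense")
    di <- all(evidence$footprinted[plus1]) &&
      all(evidence$n_accessible[minus1] >= 1L) &&
      !any(evidence$covered[minus1])
    if (di) "dinucleosomal"
    else if (prot_frac <= open_threshold) "open"
    else "other"
  }
  if (any(evidence$n_informative == 0L)) {
    evidence$note <- ifelse(evidence$n_informative == 0L,
                            "uninformative window", "")
  }
  list(state = state, protected_fraction = prot_frac,
       evidence = evidence, footprints = footprints)
}

#' Per-site protection frequency across molecules
#'
#' @param mat A `call_matrix` from a GpC-treated experiment.
#' @return Tibble with `site`, `protected_frequency` (unmethylated GpC
#'   fraction among informative calls), `n_informative`; plus attribute
#'   `n_molecules`.
#' @export
occupancy_profile <- function(mat) {
  if (nrow(mat) < 1L) stop("need at least one molecule", call. = FALSE)
  keep <- resolve_sites(mat, NULL, "gpc")
  sub <- mat[, as.character(keep), drop = FALSE]
  n_p <- colSums(sub == "U"); n_a <- colSums(sub == "M")
  out <- tibble::tibble(
    site = keep,
    protected_frequency = ifelse(n_p + n_a > 0, n_p / (n_p + n_a),
                                 NA_real_),
    n_informative = unname(n_p + n_a)
  )
  attr(out, "n_molecules") <- nrow(mat)
  out
}

#' Classify every molecule of a call matrix
#'
#' @param mat A `call_matrix`.
#' @param locus A `locus_model`.
#' @param ... Passed to [classify_promoter_state()].
#' @return Tibble with `clone`, `state`, `protected_fraction`,
#'   `n_footprints`.
#' @export
classify_molecules <- function(mat, locus, ...) {
  rows <- lapply(rownames(mat), function(id) {
    rowv <- stats::setNames(mat[id, ], colnames(mat))
    attr(rowv, "class_by_site") <- site_class_of(mat)
    vec <- accessibility_calls(rowv)
    cl <- classify_promoter_state(vec, locus, ...)
    tibble::tibble(clone = id, state = cl$state,
                   protected_fraction = cl$protected_fraction,
                   n_footprints = nrow(cl$footprints))
  })
  dplyr::bind_rows(rows)
}

#' Population summary of promoter state calls
#'
#' @param states Character vector of states (or tibble with a `state`
#'   column).
#' @return Tibble with one row per state (all four always present):
#'   `state`, `n`, `fraction`.
#' @export
state_population_summary <- function(states) {
  if (is.data.frame(states)) states <- states$state
  lv <- c("tetranucleosomal", "dinucleosomal", "open", "other")
  n <- as.integer(table(factor(states, levels = lv)))
  tibble::tibble(state = lv, n = n,
                 fraction = if (length(states)) n / length(states) else
                   rep(0, 4L))
}
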