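#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names = record ids, the
#'   first whitespace-delimited token; full description in attribute
#'   `descriptions`). Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA `", path, "`: ",
                         conditionMessage(e), call. = FALSE)
                  })
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(as.character(set), ids)
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param sequences Named character vector; names become record ids and
#'   may contain description text after a space.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(sub("\\s.*$", "",
                                                     names(sequences)))) {
    stop("sequences must carry unique ids", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(unname(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a TSV table
#'
#' Header row required; `#`-prefixed lines (provenance headers) are
#' skipped; CRLF line endings are normalised; ragged rows are an error.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path, call. = FALSE)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) > 1L) {
    stop("ragged TSV: row(s) ",
         paste(utils::head(which(nfield != nfield[1]), 5), collapse = ", "),
         " have a different field count than the header", call. = FALSE)
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write a TSV table, optionally with a provenance header
#'
#' @param x Data frame.
#' @param path Output file.
#' @param provenance Optional named character vector written as
#'   `# key=value` comment lines before the header row.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an annotation table (1-based inclusive, or BED)
#'
#' The native format is a TSV with explicit 1-based inclusive columns
#' `chrom`, `start`, `end`, `strand`, `feature` (plus any extras). With
#' `bed = TRUE` a standard 0-based half-open BED (chrom, chromStart,
#' chromEnd, name, score, strand) is accepted and converted on read.
#'
#' @param path Annotation file.
#' @param bed Input is standard BED (default `FALSE`).
#' @return Tibble with 1-based inclusive `start`/`end`.
#' @export
read_annotations <- function(path, bed = FALSE) {
  if (!bed) {
    ann <- read_tsv(path)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(ann))) {
      stop("annotation TSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    return(ann)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)) + 1L,
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    feature = if (ncol >= 4) vapply(fields, `[[`, character(1), 4)
    else NA_character_,
    strand = if (ncol >= 6) vapply(fields, `[[`, character(1), 6)
    else "."
  )
}

#' Pipeline configuration
#'
#' Bundles and validates every tunable of the simulate/analyze pipeline.
#'
#' @param sim A [sim_config()].
#' @param cohort A [cohort_config()].
#' @param min_conversion Clone QC threshold in \[0,1\].
#' @param k,nucleosome_range,min_overlap,tetra_threshold,open_threshold
#'   Footprint/state parameters (see [call_footprints()] and
#'   [classify_promoter_state()]).
#' @param roc_direction `"low"` or `"high"` (see [roc_auc()]).
#' @param seed Master seed applied to both generators when they carry
#'   none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), cohort = cohort_config(),
                            min_conversion = 0.95, k = 0,
                            nucleosome_range = c(120, 200),
                            min_overlap = 40, tetra_threshold = 0.9,
                            open_threshold = 0.1,
                            roc_direction = "low", seed = 1) {
  if (min_conversion < 0 || min_conversion > 1) {
    stop("min_conversion must lie in [0,1]", call. = FALSE)
  }
  if (!roc_direction %in% c("low", "high")) {
    stop("roc_direction must be 'low' or 'high'", call. = FALSE)
  }
  if (tetra_threshold < 0 || tetra_threshold > 1 ||
      open_threshold < 0 || open_threshold > 1) {
    stop("state thresholds must lie in [0,1]", call. = FALSE)
  }
  if (length(nucleosome_range) != 2L ||
      nucleosome_range[1] > nucleosome_range[2]) {
    stop("nucleosome_range must be c(min, max)", call. = FALSE)
  }
  if (is.null(sim$seed)) sim$seed <- seed
  if (is.null(cohort$seed)) cohort$seed <- seed
  structure(list(sim = sim, cohort = cohort,
                 min_conversion = min_conversion, k = k,
                 nucleosome_range = nucleosome_range,
                 min_overlap = min_overlap,
                 tetra_threshold = tetra_threshold,
                 open_threshold = open_threshold,
                 roc_direction = roc_direction, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(cfg) substr(rlang::hash(unclass(cfg)), 1, 12)

provenance_of <- function(cfg) {
  c(package = "mspa",
    version = as.character(utils::packageVersion("mspa")),
    seed = as.character(cfg$seed),
    config_hash = config_hash(cfg))
}

#' Write a complete synthetic dataset to disk
#'
#' Simulates a clone set on the default L1 promoter locus and a cohort
#' table, and writes clone FASTA (ground-truth state in the description
#' line), ground-truth manifest, cohort table, and reference FASTA, all
#' stamped with the seed and config hash. Re-running with the same
#' config is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param locus A `locus_model` (default [l1_promoter_locus()]).
#' @return Named character vector of file paths, invisibly.
#' @export
run_simulate <- function(cfg = pipeline_config(), out_dir,
                         locus = l1_promoter_locus()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  prov <- provenance_of(cfg)
  ds <- simulate_clone_set(locus, cfg$sim)
  if (length(ds$reads) == 0L) {
    warning("n_molecules = 0: writing an empty clone FASTA", call. = FALSE)
  }
  clone_names <- if (length(ds$reads)) {
    paste0(names(ds$reads), " state=", ds$truth$state,
           " strand_meth=", ds$truth$strand_meth)
  } else character(0)
  paths <- c(
    clones = file.path(out_dir, "clones.fasta"),
    reference = file.path(out_dir, "reference.fasta"),
    truth = file.path(out_dir, "truth.tsv"),
    cohort = file.path(out_dir, "cohort.tsv"),
    config = file.path(out_dir, "config.tsv")
  )
  write_fasta(stats::setNames(ds$reads, clone_names), paths[["clones"]])
  write_fasta(stats::setNames(locus$reference, "reference"),
              paths[["reference"]])
  write_tsv(ds$truth, paths[["truth"]], provenance = prov)
  write_tsv(simulate_cohort(cfg$cohort), paths[["cohort"]],
            provenance = prov)
  write_tsv(tibble::tibble(key = names(prov), value = unname(prov)),
            paths[["config"]])
  invisible(paths)
}

#' Analyze a simulated (or real) clone dataset end to end
#'
#' Reads clones, calls methylation with QC, infers footprints and
#' promoter states, summarises occupancy and methylation, and — when a
#' ground-truth manifest is present — reports state-recovery accuracy.
#' Every output carries a provenance header (package version, seed,
#' config hash).
#'
#' @param cfg A [pipeline_config()].
#' @param data_dir Directory produced by [run_simulate()] (or laid out
#'   the same way).
#' @param out_dir Output directory (default `data_dir`).
#' @param locus A `locus_model` matching the reads.
#' @return List of result tibbles, invisibly; files on disk.
#' @export
run_analyze <- function(cfg = pipeline_config(), data_dir,
                        out_dir = data_dir,
                        locus = l1_promoter_locus()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prov <- provenance_of(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  reads <- stage("read_clones",
                 read_fasta(file.path(data_dir, "clones.fasta")))
  qc <- stage("qc_clones",
              qc_clones(reads, locus, min_conversion = cfg$min_conversion))
  mat <- qc$matrix
  calls_df <- tibble::as_tibble(as.data.frame(unclass(mat)),
                                .name_repair = "minimal")
  calls_df <- tibble::add_column(calls_df, clone = rownames(mat),
                                 .before = 1)
  states <- stage("classify", classify_molecules(
    mat, locus, k = cfg$k, nucleosome_range = cfg$nucleosome_range,
    min_overlap = cfg$min_overlap, tetra_threshold = cfg$tetra_threshold,
    open_threshold = cfg$open_threshold))
  summary <- state_population_summary(states)
  profile <- stage("occupancy", occupancy_profile(mat))
  meth <- stage("percent_methylation", percent_methylation(mat))
  fp_rows <- lapply(rownames(mat), function(id) {
    rowv <- stats::setNames(mat[id, ], colnames(mat))
    attr(rowv, "class_by_site") <- site_class_of(mat)
    fp <- call_footprints(accessibility_calls(rowv), locus$length,
                          k = cfg$k,
                          nucleosome_range = cfg$nucleosome_range)
    if (nrow(fp)) tibble::add_column(fp, clone = id, .before = 1) else NULL
  })
  footprints <- dplyr::bind_rows(fp_rows)
  results <- list(qc = qc$qc, calls = calls_df, states = states,
                  state_summary = summary, occupancy = profile,
                  per_site_methylation = meth$per_site,
                  footprints = footprints)
  truth_path <- file.path(data_dir, "truth.tsv")
  if (file.exists(truth_path)) {
    truth <- read_tsv(truth_path)
    lab <- c(tetra = "tetranucleosomal", di = "dinucleosomal",
             open = "open")
    joined <- dplyr::inner_join(states, truth, by = c(clone = "id"),
                                suffix = c("_call", "_true"))
    results$recovery <- tibble::tibble(
      n = nrow(joined),
      accuracy = mean(joined$state_call == lab[joined$state_true]))
  }
  out_files <- c(qc = "clone_qc.tsv", calls = "call_matrix.tsv",
                 states = "promoter_states.tsv",
                 state_summary = "state_summary.tsv",
                 occupancy = "occupancy_profile.tsv",
                 per_site_methylation = "percent_methylation.tsv",
                 footprints = "footprints.tsv",
                 recovery = "state_recovery.tsv")
  for (nm in names(out_files)) {
    if (!is.null(results[[nm]])) {
      write_tsv(results[[nm]], file.path(out_dir, out_files[[nm]]),
                provenance = prov)
    }
  }
  invisible(results)
}
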