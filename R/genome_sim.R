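#' Generate a synthetic annotated genome for promoter scanning
#'
#' Plants multi-exon genes on random strands along one synthetic
#' chromosome and then plants L1 repeats of known class: true candidates
#' (full-length, fully intronic, antisense to the host gene) and decoys
#' (sense-strand intronic, truncated, exon-overlapping, or intergenic).
#' A ground-truth manifest records each repeat's class, so the scanner
#' can be tested against construction.
#'
#' @param n_genes Number of genes (each 4 exons of 400 bp separated by
#'   9 kb introns).
#' @param n_repeats Number of L1 repeats to plant, cycled over the decoy
#'   classes with every other repeat a true candidate.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param full_length Length of a full-length L1 (default 6100 bp, just
#'   above the 6 kb full-length threshold).
#' @return List with `genes` (tibble: gene, chrom, start, end, strand —
#'   one row per exon), `repeats` (tibble: name, chrom, start, end,
#'   strand), `manifest` (tibble: name, class, is_candidate), `sequence`
#'   (the chromosome as one string), and `chrom_length`.
#' @export
make_synthetic_genome <- function(n_genes = 6, n_repeats = 10, seed = 1,
                                  full_length = 6100) {
  if (n_genes < 0 || n_repeats < 0) stop("counts must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    exon_len <- 400L; intron_len <- 9000L; gap <- 5000L
    gene_span <- 4L * exon_len + 3L * intron_len
    genes <- NULL
    gene_info <- list()
    cursor <- gap
    for (i in seq_len(n_genes)) {
      strand <- sample(c("+", "-"), 1)
      starts <- cursor + (0:3) * (exon_len + intron_len)
      genes <- rbind(genes, data.frame(
        gene = sprintf("gene_%02d", i), chrom = "chrS",
        start = starts, end = starts + exon_len - 1L,
        strand = strand, stringsAsFactors = FALSE))
      gene_info[[i]] <- list(name = sprintf("gene_%02d", i), strand = strand,
                             exon_starts = starts,
                             exon_ends = starts + exon_len - 1L)
      cursor <- cursor + gene_span + gap
    }
    chrom_length <- cursor + gap

    flip <- function(s) if (s == "+") "-" else "+"
    classes <- c("candidate", "sense_intronic", "candidate", "truncated",
                 "candidate", "exon_overlap", "candidate", "intergenic")
    reps <- list(); manifest <- list()
    for (j in seq_len(n_repeats)) {
      cls <- classes[((j - 1L) %% length(classes)) + 1L]
      if (n_genes == 0L && cls != "intergenic") cls <- "intergenic"
      gi <- if (n_genes > 0L) gene_info[[((j - 1L) %% n_genes) + 1L]] else NULL
      intron_pick <- sample(1:3, 1)
      len <- if (cls == "truncated") 800L else as.integer(full_length)
      if (cls == "intergenic" || is.null(gi)) {
        start <- chrom_length - gap + 100L
        if (start + len - 1L > chrom_length) chrom_length <- start + len + 100L
        strand <- sample(c("+", "-"), 1)
      } else {
        intron_start <- gi$exon_ends[intron_pick] + 1L
        intron_end <- gi$exon_starts[intron_pick + 1L] - 1L
        if (cls == "exon_overlap") {
          start <- gi$exon_starts[intron_pick + 1L] - len %/% 2L
        } else {
          start <- intron_start + sample.int(intron_end - intron_start -
                                               len, 1)
        }
        strand <- if (cls == "sense_intronic") gi$strand else flip(gi$strand)
      }
      name <- sprintf("L1_%02d", j)
      reps[[j]] <- data.frame(name = name, chrom = "chrS",
                              start = start, end = start + len - 1L,
                              strand = strand, stringsAsFactors = FALSE)
      manifest[[j]] <- data.frame(name = name, class = cls,
                                  is_candidate = cls == "candidate",
                                  stringsAsFactors = FALSE)
    }
    sequence <- paste(sample(c("A", "C", "G", "T"),
                             min(chrom_length, 20000L), replace = TRUE),
                      collapse = "")
    list(
      genes = tibble::as_tibble(genes %||% data.frame(
        gene = character(0), chrom = character(0), start = integer(0),
        end = integer(0), strand = character(0))),
      repeats = tibble::as_tibble(dplyr::bind_rows(reps)),
      manifest = tibble::as_tibble(dplyr::bind_rows(manifest)),
      sequence = sequence,
      chrom_length = chrom_length
    )
  })
}

#' Scan annotations for candidate antisense L1 promoters
#'
#' Returns exactly the L1 repeats that could drive an ectopic alternate
#' transcript of their host gene: full-length (>= `min_full_length`),
#' lying entirely within one intron (no exon overlap), and on the strand
#' opposite the host gene — so the L1 antisense promoter fires in the
#' host gene's sense direction.
#'
#' @param genes Tibble/data frame of exons: `gene`, `chrom`, `start`,
#'   `end`, `strand` (one row per exon; 1-based inclusive).
#' @param repeats Tibble/data frame of L1s: `name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param min_full_length Minimum L1 length in bp (default 6000, the
#'   full-length L1 size).
#' @return Tibble with one row per (candidate L1, host gene):
#'   `name`, `chrom`, `start`, `end`, `strand`, `host_gene`,
#'   `host_strand`, `transcript_direction` (sense with the host).
#' @export
scan_candidate_asps <- function(genes, repeats, min_full_length = 6000) {
  empty <- tibble::tibble(name = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), host_gene = character(0),
                          host_strand = character(0),
                          transcript_direction = character(0))
  if (is.null(repeats) || nrow(repeats) == 0L ||
      is.null(genes) || nrow(genes) == 0L) {
    return(empty)
  }
  hits <- list()
  for (g in unique(genes$gene)) {
    ex <- genes[genes$gene == g, ]
    ex <- ex[order(ex$start), ]
    strand <- ex$strand[[1]]
    chrom <- ex$chrom[[1]]
    if (nrow(ex) < 2L) next
    introns <- data.frame(start = ex$end[-nrow(ex)] + 1,
                          end = ex$start[-1] - 1)
    introns <- introns[introns$end >= introns$start, , drop = FALSE]
    for (k in seq_len(nrow(repeats))) {
      r <- repeats[k, ]
      if (r$chrom != chrom) next
      if (r$end - r$start + 1 < min_full_length) next
      if (r$strand == strand || r$strand == "." || strand == ".") next
      inside <- any(r$start >= introns$start & r$end <= introns$end)
      if (!inside) next
      host_str <- strand
      hits[[length(hits) + 1L]] <- tibble::tibble(
        name = r$name, chrom = r$chrom, start = r$start, end = r$end,
        strand = r$strand, host_gene = g, host_strand = host_str,
        transcript_direction = host_str)
    }
  }
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits)
}
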