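#' Genomic intervals (1-based, inclusive)
#'
#' Constructs a genomic interval in the 1-based inclusive coordinate style
#' used throughout the package (UCSC-legend style, e.g. `ch7:116364010-116364564`).
#'
#' @param chrom Chromosome (or amplicon) name.
#' @param start,end 1-based inclusive positions; `end >= start >= 1`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` object (named list).
#' @examples
#' iv <- genomic_interval("ch7", 116364010, 116364564)
#' interval_length(iv) # 555
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    stop("`chrom` must be a single non-empty string", call. = FALSE)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("`start` and `end` must be single non-missing numbers", call. = FALSE)
  }
  if (start < 1) stop("malformed interval: start < 1", call. = FALSE)
  if (end < start) stop("malformed interval: end < start", call. = FALSE)
  if (!strand %in% c("+", "-", ".")) {
    stop("`strand` must be one of '+', '-', '.'", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s), %d bp\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              x$strand, interval_length(x)))
  invisible(x)
}

#' Inclusive length of a genomic interval
#'
#' @param iv A [genomic_interval()].
#' @return Length in bp, `end - start + 1`.
#' @export
interval_length <- function(iv) {
  if (!inherits(iv, "genomic_interval")) {
    iv <- genomic_interval(iv$chrom %||% "chr", iv$start, iv$end)
  }
  as.integer(iv$end - iv$start + 1)
}

#' Classify cytosine site contexts on the top strand
#'
#' Every cytosine of the top strand is classified by its dinucleotide
#' context: a C both preceded and followed by G lies in a GpCpG context
#' where enzymatic GpC methylation and endogenous CpG methylation cannot
#' be distinguished, so both overlapping dinucleotide calls are dropped
#' and the position is recorded as excluded. A C followed (but not
#' preceded) by G is an informative CpG; a C preceded (but not followed)
#' by G is an informative GpC. An adjacent N voids the context: the site
#' receives no class.
#'
#' @param sequence Top-strand DNA string over `A,C,G,T,N` (case-insensitive).
#' @return A `site_map` object: list with ascending integer vectors
#'   `cpg_sites`, `gpc_sites`, `excluded_sites` (1-based positions of the C),
#'   plus `n_c`, the total cytosine count.
#' @examples
#' classify_sites("TGCGT") # excluded = 3
#' classify_sites("ACGT")  # cpg = 2
#' @export
classify_sites <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("sequence contains invalid characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(chars)
  is_c <- chars == "C"
  prv <- c("", chars[-n])
  nxt <- c(chars[-1], "")
  prv_g <- prv == "G"; nxt_g <- nxt == "G"
  prv_n <- prv == "N"; nxt_n <- nxt == "N"
  ambiguous <- is_c & (prv_n | nxt_n)
  excluded <- is_c & prv_g & nxt_g & !ambiguous
  cpg <- is_c & !prv_g & nxt_g & !ambiguous
  gpc <- is_c & prv_g & !nxt_g & !ambiguous
  structure(list(
    cpg_sites = which(cpg),
    gpc_sites = which(gpc),
    excluded_sites = which(excluded),
    n_c = sum(is_c)
  ), class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("site_map: %d CpG, %d GpC, %d excluded (GpCpG) of %d C\n",
              length(x$cpg_sites), length(x$gpc_sites),
              length(x$excluded_sites), x$n_c))
  invisible(x)
}

#' Build a locus model for a bidirectional L1 promoter amplicon
#'
#' Bundles the reference top-strand sequence, its informative-site map,
#' and the positions of the two transcription start sites: the L1 sense
#' TSS and the antisense-promoter (ASP) TSS facing it. All positions are
#' 1-based along the amplicon.
#'
#' @param reference Top-strand DNA of the amplicon.
#' @param tss_sense,tss_antisense TSS positions within the amplicon. The
#'   sense TSS transcribes toward increasing coordinates, the ASP TSS
#'   toward decreasing coordinates; `tss_sense < tss_antisense` so the two
#'   +1 nucleosomes fall between them.
#' @param interval Optional [genomic_interval()] giving the genomic span
#'   of the amplicon (metadata only; analysis uses amplicon coordinates).
#' @param l1_interval Optional [genomic_interval()] (amplicon coordinates)
#'   for the portion occupied by the L1.
#' @return A `locus_model` object.
#' @export
build_locus_model <- function(reference, tss_sense, tss_antisense,
                              interval = NULL, l1_interval = NULL) {
  site_map <- classify_sites(reference)
  len <- nchar(reference)
  for (nm in c("tss_sense", "tss_antisense")) {
    v <- get(nm)
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("missing TSS annotation: ", nm, call. = FALSE)
    }
    if (v < 1 || v > len) {
      stop(nm, " lies outside the reference (1-", len, ")", call. = FALSE)
    }
  }
  if (tss_sense == tss_antisense) {
    message("degenerate annotation: tss_sense == tss_antisense at ", tss_sense)
  } else if (tss_sense > tss_antisense) {
    stop("tss_sense must not lie downstream of tss_antisense", call. = FALSE)
  }
  if (!is.null(l1_interval)) {
    if (l1_interval$start < 1 || l1_interval$end > len) {
      stop("l1_interval lies outside the reference", call. = FALSE)
    }
  }
  structure(list(
    reference = toupper(reference),
    length = len,
    interval = interval,
    site_map = site_map,
    tss_sense = as.integer(tss_sense),
    tss_antisense = as.integer(tss_antisense),
    l1_interval = l1_interval
  ), class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("locus_model: %d bp amplicon, sense TSS %d, ASP TSS %d\n",
              x$length, x$tss_sense, x$tss_antisense))
  print(x$site_map)
  invisible(x)
}

# Informative sites of a locus, ascending, with their class.
informative_sites <- function(locus) {
  sm <- locus$site_map
  pos <- c(sm$cpg_sites, sm$gpc_sites)
  cls <- c(rep("cpg", length(sm$cpg_sites)), rep("gpc", length(sm$gpc_sites)))
  o <- order(pos)
  data.frame(site = pos[o], class = cls[o], stringsAsFactors = FALSE)
}

#' Default synthetic L1 promoter locus
#'
#' A deterministic 780 bp amplicon emulating the geometry of a
#' bidirectional L1 promoter: sense TSS at 249, ASP TSS at 562, leaving
#' room for two 147 bp +1 nucleosomes separated by a 20 bp linker between
#' the start sites and one -1 nucleosome outside each. The sequence is a
#' tiled 30-mer giving roughly one informative GpC every 15 bp (>= 8 per
#' 147 bp window), one CpG every 30 bp, and one excluded GpCpG site every
#' 30 bp, so that every classification window is informative. The TSS
#' positions are chosen so that each of the three inter-nucleosome
#' linkers of the tetranucleosomal state contains at least one
#' informative GpC — otherwise abutting protection patches could never be
#' separated, even by a perfect assay.
#'
#' @param n_units Number of 30 bp tile repeats (default 26, i.e. 780 bp).
#' @param tss_sense,tss_antisense TSS positions (defaults 249 and 562).
#' @return A `locus_model`.
#' @export
l1_promoter_locus <- function(n_units = 26, tss_sense = 249, tss_antisense = 562) {
  # per 30 bp: GpC at +3/+9, CpG at +14, GpCpG (excluded) at +21, and a
  # plain C at +27 whose conversion is the clone-QC readout
  unit <- "TGCATTAGCATTACGTATTGCGTATTCTTA"
  reference <- paste(rep(unit, n_units), collapse = "")
  build_locus_model(reference, tss_sense = tss_sense,
                    tss_antisense = tss_antisense,
                    interval = genomic_interval("synthetic_L1", 1,
                                                nchar(reference)))
}
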