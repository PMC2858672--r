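# Shared fixtures. The default locus is deterministic, so it is built once.
default_locus <- l1_promoter_locus()

state_label <- c(tetra = "tetranucleosomal", di = "dinucleosomal",
                 open = "open")

# Random DNA string (no N unless asked).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force site classifier: literal per-position re-derivation of the
# context rules, independent of the vectorised implementation.
brute_classify_sites <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  res <- list(cpg = integer(0), gpc = integer(0), excl = integer(0))
  for (i in seq_along(ch)) {
    if (ch[i] != "C") next
    p <- if (i > 1) ch[i - 1] else ""
    n <- if (i < length(ch)) ch[i + 1] else ""
    if (p == "N" || n == "N") next
    if (p == "G" && n == "G") res$excl <- c(res$excl, i)
    else if (n == "G") res$cpg <- c(res$cpg, i)
    else if (p == "G") res$gpc <- c(res$gpc, i)
  }
  res
}

# Independent oracle: two-sided permutation p by full enumeration of
# group labellings, counting tails by distance from the null mean.
brute_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force candidate-ASP filter over planted annotations.
brute_scan <- function(genes, repeats, min_len = 6000) {
  hits <- character(0)
  for (k in seq_len(nrow(repeats))) {
    r <- repeats[k, ]
    if (r$end - r$start + 1 < min_len) next
    for (g in unique(genes$gene)) {
      ex <- genes[genes$gene == g & genes$chrom == r$chrom, ]
      if (nrow(ex) < 2) next
      ex <- ex[order(ex$start), ]
      if (r$strand == ex$strand[1]) next
      found <- FALSE
      for (j in seq_len(nrow(ex) - 1)) {
        if (r$start > ex$end[j] && r$end < ex$start[j + 1]) found <- TRUE
      }
      if (found) hits <- c(hits, paste(r$name, g))
    }
  }
  sort(hits)
}
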