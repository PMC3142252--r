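## Independent oracles, deliberately written with none of the package's
## internals: naive k-mer scanning with a hand-rolled complement table,
## hypergeometric tail by exhaustive enumeration, and a hand-stepped string
## overlap for merge checks.

## naive reverse complement (no Biostrings)
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## naive canonical k-mer counts for a set of sequences: walk every offset,
## skip windows with non-ACGT letters, key by min(word, revcomp(word))
oracle_count_kmers <- function(seqs, k) {
  acc <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      rc <- oracle_revcomp(w)
      key <- if (w <= rc) w else rc
      prev <- if (is.null(acc[[key]])) 0L else acc[[key]]
      assign(key, prev + 1L, envir = acc)
    }
  }
  keys <- sort(ls(acc))
  stats::setNames(vapply(keys, function(k2) acc[[k2]], integer(1)), keys)
}

## exhaustive hypergeometric upper tail P(X >= k): enumerate all C(N, n)
## draws of n items from a universe where the first m are "special"
oracle_hyper_ge <- function(k, N, m, n) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= m)
  mean(overlaps >= k)
}

## hand-stepped overlap of two oriented strings: longest suffix(a)==prefix(b)
oracle_suffix_prefix <- function(a, b) {
  best <- 0L
  for (L in seq_len(min(nchar(a), nchar(b)) - 1L)) {
    if (substr(a, nchar(a) - L + 1L, nchar(a)) == substr(b, 1L, L)) best <- L
  }
  best
}

## random DNA string
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## tiny deterministic gene table builder for interval-rule tests
toy_genes <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, chrom = r$chrom %||% "c1", start = r$start,
               end = r$end, strand = r$strand %||% "+",
               class = r$class %||% "disease",
               stratum = r$stratum %||% "S1",
               tss = if (is.null(r$tss)) NA_integer_ else r$tss,
               stringsAsFactors = FALSE)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## subgenome-like object from raw character sequences (what count_oligomers
## and the screen accept)
as_seqs <- function(...) c(...)
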