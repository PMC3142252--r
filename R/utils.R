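#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet subseq
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#'   width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats prcomp phyper rpois runif cov
#' @importFrom utils read.delim write.table
NULL

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character strings (A/C/G/T plus
#' IUPAC ambiguity codes as handled by Biostrings).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a DNA word is the lexicographic minimum of the word
#' and its reverse complement, so that a k-mer and its reverse complement are
#' pooled under one key.
#'
#' @param x character vector of DNA words (pure A/C/G/T).
#' @return character vector of canonical forms.
#' @export
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## internal: stop() with a consistent error prefix
xp_stop <- function(...) stop(..., call. = FALSE)

## internal: condition-logged message, silenced via suppressMessages()
xp_log <- function(...) message("[xprio] ", ...)

## internal: Moore-Penrose pseudo-inverse via SVD (fallback for singular
## pooled covariances; avoids a MASS dependency)
pseudo_inverse <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
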