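## Oligomer discovery: canonical k-mer counting inside subgenome contigs,
## the two-criterion overrepresentation screen (count >= 10, frequency >= 5x
## the other subgenome), a fragment-shuffling permutation test, and greedy
## merging of overlapping oligomers.

#' Overrepresentation criteria
#'
#' Defaults follow the screening rules used throughout: an oligomer must occur
#' at least `min_count` times in the focal subgenome and at least `min_fold`
#' times more frequently than in the other subgenome; it is confirmed when it
#' qualifies in fewer than `max_perm_hits` of `perm_trials` random
#' reassignments of `fragment_bp` fragments (50/1000 corresponds to p < 0.05).
#'
#' @param min_count minimum focal occurrence count (default 10).
#' @param min_fold minimum frequency fold enrichment (default 5).
#' @param perm_trials number of permutation trials (default 1000).
#' @param max_perm_hits strict upper bound on qualifying trials for
#'   significance (default 50).
#' @param fragment_bp fragment size for the permutation pool (default 2000).
#' @param normalize `"length"` compares counts per base (subgenomes differ in
#'   size); `"count"` compares raw counts.
#' @return list of class `overrep_criteria`.
#' @export
overrep_criteria <- function(min_count = 10L, min_fold = 5, perm_trials = 1000L,
                             max_perm_hits = 50L, fragment_bp = 2000L,
                             normalize = c("length", "count")) {
  normalize <- match.arg(normalize)
  stopifnot(min_count > 0, min_fold > 0, perm_trials > 0, max_perm_hits > 0,
            fragment_bp > 0)
  if (max_perm_hits >= perm_trials)
    xp_stop("max_perm_hits must be smaller than perm_trials")
  structure(list(min_count = as.integer(min_count), min_fold = min_fold,
                 perm_trials = as.integer(perm_trials),
                 max_perm_hits = as.integer(max_perm_hits),
                 fragment_bp = as.integer(fragment_bp), normalize = normalize),
            class = "overrep_criteria")
}

## internal: character vector of contig sequences from flexible input
contig_seqs <- function(x) {
  if (inherits(x, "subgenome")) as.character(x$sequences)
  else if (inherits(x, "DNAStringSet")) as.character(x)
  else as.character(x)
}

## internal: canonical k-mer count table for one sequence (character scalar)
scan_canonical <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  win <- substring(seq, 1:(n - k + 1L), k:n)
  win <- win[!grepl("[^ACGT]", win)]
  if (!length(win)) return(integer(0))
  u <- unique(win)
  canon <- canonical_kmer(u)
  tab <- table(factor(canon[match(win, u)], levels = sort(unique(canon))))
  stats::setNames(as.integer(tab), names(tab))
}

## internal: sum named integer vectors
sum_counts <- function(lst) {
  lst <- lst[lengths(lst) > 0L]
  if (!length(lst)) return(integer(0))
  all_names <- unique(unlist(lapply(lst, names), use.names = FALSE))
  out <- stats::setNames(integer(length(all_names)), sort(all_names))
  for (v in lst) out[names(v)] <- out[names(v)] + v
  out
}

#' Count canonical k-mers in a subgenome
#'
#' Slides a window of width `k` within each contig independently (no window
#' spans a contig boundary); a k-mer and its reverse complement are pooled
#' under the canonical key; windows containing non-ACGT characters are
#' skipped. Exact matches only.
#'
#' @param x a `subgenome`, `DNAStringSet`, or character vector of sequences.
#' @param k word size (>= 1).
#' @return named integer vector, names sorted canonical k-mers.
#' @export
count_oligomers <- function(x, k) {
  stopifnot(is.numeric(k), k >= 1)
  k <- as.integer(k)
  seqs <- contig_seqs(x)
  if (!length(seqs)) xp_stop("empty subgenome")
  if (all(nchar(seqs) < k)) {
    warning("k = ", k, " exceeds every contig length; empty count map")
    return(stats::setNames(integer(0), character(0)))
  }
  sum_counts(lapply(seqs, scan_canonical, k = k))
}

## internal: counts of a fixed set of canonical oligomers (all same length)
## in one sequence
scan_targets <- function(seq, targets, k) {
  n <- nchar(seq)
  out <- integer(length(targets))
  if (n < k) return(out)
  win <- substring(seq, 1:(n - k + 1L), k:n)
  win <- win[!grepl("[^ACGT]", win)]
  if (!length(win)) return(out)
  u <- unique(win)
  canon <- canonical_kmer(u)
  hit <- match(canon[match(win, u)], targets)
  tabulate(hit[!is.na(hit)], nbins = length(targets))
}

#' Screen for overrepresented oligomers
#'
#' Retains canonical k-mers occurring at least `criteria$min_count` times in
#' the focal subgenome whose focal frequency is at least `criteria$min_fold`
#' times the frequency in the other subgenome. Frequencies are counts per base
#' of subgenome (or raw counts with `normalize = "count"`); k-mers absent from
#' the other subgenome have infinite fold and pass the fold criterion.
#'
#' @param focal,other `subgenome` objects (focal = the class screened for).
#' @param k word size.
#' @param criteria an [overrep_criteria()] object.
#' @return data.frame of class `oligomer_records`: `sequence`, `k`,
#'   `count_focal`, `count_other`, `freq_focal`, `freq_other` (per megabase),
#'   `fold`, `perm_hits`, `perm_trials`, `significant`.
#' @export
find_overrepresented <- function(focal, other, k, criteria = overrep_criteria()) {
  stopifnot(inherits(criteria, "overrep_criteria"))
  cf <- count_oligomers(focal, k)
  co <- count_oligomers(other, k)
  lf <- sum(nchar(contig_seqs(focal)))
  lo <- sum(nchar(contig_seqs(other)))
  cand <- names(cf)[cf >= criteria$min_count]
  n_other <- unname(co[cand]); n_other[is.na(n_other)] <- 0L
  n_focal <- unname(cf[cand])
  if (criteria$normalize == "length") {
    ff <- n_focal / lf; fo <- n_other / lo
  } else {
    ff <- n_focal; fo <- n_other
  }
  fold <- ifelse(fo > 0, ff / fo, Inf)
  keep <- fold >= criteria$min_fold
  nk <- sum(keep)
  out <- data.frame(
    sequence = cand[keep],
    k = rep.int(as.integer(k), nk),
    count_focal = n_focal[keep],
    count_other = n_other[keep],
    freq_focal = 1e6 * n_focal[keep] / lf,
    freq_other = 1e6 * n_other[keep] / lo,
    fold = fold[keep],
    perm_hits = rep.int(NA_integer_, nk),
    perm_trials = rep.int(NA_integer_, nk),
    significant = rep.int(NA, nk),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("oligomer_records", "data.frame")
  out
}

## internal: cut contig sequences into non-overlapping fragment_bp pieces;
## the terminal remainder of each contig is kept as a short fragment
fragment_pool <- function(seqs, fragment_bp) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    starts <- seq(1L, n, by = fragment_bp)
    substring(s, starts, pmin(starts + fragment_bp - 1L, n))
  }), use.names = FALSE)
}

#' Permutation test for overrepresented oligomers
#'
#' Pools the two subgenomes, cuts every contig into non-overlapping
#' `fragment_bp` fragments (terminal remainders kept), and in each trial
#' randomly assigns shuffled fragments to a pseudo-focal subgenome until its
#' size first reaches the true focal size, the remainder forming the
#' pseudo-other. Both screening criteria are re-applied in each trial;
#' `perm_hits` counts qualifying trials and a candidate is `significant` when
#' `perm_hits < criteria$max_perm_hits` (strict).
#'
#' @param focal,other the subgenomes the candidates were screened on.
#' @param candidates `oligomer_records` from [find_overrepresented()].
#' @param criteria the [overrep_criteria()] used for screening.
#' @param seed integer seed for the fragment shuffles (required: all
#'   stochastic steps in the package take explicit seeds).
#' @return the candidate records with `perm_hits`, `perm_trials` and
#'   `significant` filled in.
#' @export
permutation_test <- function(focal, other, candidates,
                             criteria = overrep_criteria(), seed) {
  stopifnot(inherits(criteria, "overrep_criteria"))
  if (missing(seed)) xp_stop("seed is required")
  if (!nrow(candidates)) {
    candidates$perm_trials <- integer(0)
    return(candidates)
  }
  k <- unique(candidates$k)
  if (length(k) != 1L)
    xp_stop("candidates must share one word size k")
  frags <- fragment_pool(c(contig_seqs(focal), contig_seqs(other)),
                         criteria$fragment_bp)
  if (length(frags) < 2L) xp_stop("pooled sequence shorter than 2 fragments")
  lens <- nchar(frags)
  lf_true <- sum(nchar(contig_seqs(focal)))
  targets <- candidates$sequence
  ## per-fragment counts of each candidate: one scan, then each trial is a
  ## subset sum
  fm <- vapply(frags, scan_targets, integer(length(targets)),
               targets = targets, k = k, USE.NAMES = FALSE)
  fm <- if (is.null(dim(fm))) matrix(fm, ncol = 1L) else t(fm)
  tot <- colSums(fm)
  tot_len <- sum(lens)

  set.seed(as.integer(seed))
  hits <- integer(length(targets))
  for (trial in seq_len(criteria$perm_trials)) {
    ord <- sample.int(length(frags))
    nf <- which(cumsum(lens[ord]) >= lf_true)[1L]
    if (is.na(nf)) nf <- length(frags) - 1L
    sel <- ord[seq_len(nf)]
    cf <- colSums(fm[sel, , drop = FALSE])
    co <- tot - cf
    lf <- sum(lens[sel]); lo <- tot_len - lf
    if (criteria$normalize == "length") {
      ff <- cf / lf; fo <- co / lo
    } else {
      ff <- cf; fo <- co
    }
    ok <- cf >= criteria$min_count &
      (co == 0L | ff >= criteria$min_fold * fo)
    hits <- hits + as.integer(ok)
  }
  candidates$perm_hits <- hits
  candidates$perm_trials <- criteria$perm_trials
  candidates$significant <- hits < criteria$max_perm_hits
  candidates
}

## internal: best merge of two canonical oligomers, reverse-complement aware.
## Returns NULL or list(ov, merged). Preference at equal overlap length:
## containment, then suffix(a)+prefix(b), then suffix(b)+prefix(a); original
## orientation of b before its reverse complement.
best_merge <- function(a, b, min_overlap) {
  na <- nchar(a)
  best <- NULL
  consider <- function(ov, merged) {
    if (is.null(best) || ov > best$ov) best <<- list(ov = ov, merged = merged)
  }
  for (bo in unique(c(b, revcomp(b)))) {
    nb <- nchar(bo)
    if (nb <= na && grepl(bo, a, fixed = TRUE)) { consider(nb, a); next }
    if (na < nb && grepl(a, bo, fixed = TRUE)) { consider(na, bo); next }
    Lmax <- min(na, nb) - 1L
    if (Lmax < max(1L, min_overlap)) next
    for (L in seq(Lmax, max(1L, min_overlap))) {
      hit <- FALSE
      if (substr(a, na - L + 1L, na) == substr(bo, 1L, L)) {
        consider(L, paste0(a, substr(bo, L + 1L, nb))); hit <- TRUE
      }
      if (substr(bo, nb - L + 1L, nb) == substr(a, 1L, L)) {
        consider(L, paste0(bo, substr(a, L + 1L, na))); hit <- TRUE
      }
      if (hit) break
    }
  }
  best
}

#' Merge overlapping oligomers into longer ones
#'
#' Greedy single-linkage assembly: two oligomers merge when one contains the
#' other or a suffix of one equals a prefix of the other (in either
#' orientation) over at least `min_overlap` bases. The longest available
#' overlap is merged first; ties are resolved by lexicographic order of the
#' pair. Iterates to a fixpoint; the result is deduplicated and idempotent.
#'
#' @param records `oligomer_records` data.frame (or character vector of
#'   canonical sequences).
#' @param min_overlap minimum overlap in bases; default `floor(min(k) / 2)`.
#' @return data.frame of class `oligomer_records` with columns `sequence`,
#'   `k` (merged length) and `members` (comma-separated input sequences);
#'   count/fold/permutation columns are `NA` for merged products, since they
#'   no longer refer to a single exact word.
#' @export
merge_oligomers <- function(records, min_overlap = NULL) {
  seqs <- if (is.data.frame(records)) records$sequence else as.character(records)
  seqs <- sort(unique(canonical_kmer(seqs)))
  if (is.null(min_overlap)) {
    if (!length(seqs)) min_overlap <- 1L
    else min_overlap <- max(1L, floor(min(nchar(seqs)) / 2))
  }
  members <- stats::setNames(as.list(seqs), seqs)

  repeat {
    n <- length(seqs)
    if (n < 2L) break
    top <- NULL
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      bm <- best_merge(seqs[i], seqs[j], min_overlap)
      if (!is.null(bm) && bm$ov >= min_overlap &&
          (is.null(top) || bm$ov > top$ov))
        top <- c(bm, list(i = i, j = j))
    }
    if (is.null(top)) break
    merged <- canonical_kmer(top$merged)
    mem <- sort(unique(c(members[[seqs[top$i]]], members[[seqs[top$j]]])))
    members[[seqs[top$i]]] <- NULL
    members[[seqs[top$j]]] <- NULL
    members[[merged]] <- sort(unique(c(members[[merged]], mem)))
    seqs <- sort(unique(c(seqs[-c(top$i, top$j)], merged)))
  }

  out <- data.frame(
    sequence = seqs,
    k = nchar(seqs),
    count_focal = NA_integer_, count_other = NA_integer_,
    freq_focal = NA_real_, freq_other = NA_real_, fold = NA_real_,
    perm_hits = NA_integer_, perm_trials = NA_integer_, significant = NA,
    members = vapply(seqs, function(s) paste(members[[s]], collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("oligomer_records", "data.frame")
  out
}
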