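## Annotation-based prioritization: the binary evaluation grid.
##
## Each curated annotation term carries the set of genes matching it. A gene's
## score is the number of terms whose list contains it; genes are ranked by
## descending score. Enrichment of a known disease-gene set in the top of the
## ranking is summarized by simple fractions and by a hypergeometric test.

TERM_CATEGORIES <- c("anatomical_site", "biological_process",
                     "phenotype", "animal_model")

#' Construct an annotation term
#'
#' @param name term label (nonempty string).
#' @param category one of `"anatomical_site"`, `"biological_process"`,
#'   `"phenotype"`, `"animal_model"`.
#' @param genes character vector of gene identifiers annotated with the term
#'   (may be empty: a term that matched nothing is legal).
#' @return an object of class `annotation_term`.
#' @export
annotation_term <- function(name, category, genes = character(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    xp_stop("term name must be a nonempty string")
  category <- match.arg(category, TERM_CATEGORIES)
  genes <- unique(as.character(genes))
  structure(list(name = name, category = category, genes = genes),
            class = "annotation_term")
}

#' @export
print.annotation_term <- function(x, ...) {
  cat(sprintf("<annotation_term> %s [%s]: %d gene(s)\n",
              x$name, x$category, length(x$genes)))
  invisible(x)
}

#' Build the binary evaluation grid
#'
#' Gene-by-term 0/1 matrix: entry (g, t) is 1 iff gene g appears in term t's
#' gene list. Per-gene scores are row sums; ranks are assigned by descending
#' score with ties broken lexicographically by gene identifier (stable, so
#' equal scores receive consecutive ranks).
#'
#' @param genes character vector of unique gene identifiers (the universe).
#' @param terms list of [annotation_term] objects with unique names.
#' @return object of class `binary_grid` with elements `genes`, `terms`,
#'   `categories`, `matrix`, `scores`, `ranks`.
#' @export
build_binary_grid <- function(genes, terms) {
  genes <- as.character(genes)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    xp_stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  stopifnot(all(vapply(terms, inherits, logical(1), "annotation_term")))
  tnames <- vapply(terms, `[[`, character(1), "name")
  dup <- tnames[duplicated(tnames)]
  if (length(dup))
    xp_stop("duplicate term name(s): ", paste(unique(dup), collapse = ", "))

  m <- vapply(terms, function(t) as.integer(genes %in% t$genes),
              integer(length(genes)))
  m <- matrix(as.integer(m), nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, tnames))
  scores <- as.integer(rowSums(m))
  names(scores) <- genes
  ord <- order(-scores, genes)
  ranks <- integer(length(genes))
  ranks[ord] <- seq_along(genes)
  names(ranks) <- genes

  structure(list(
    genes = genes,
    terms = tnames,
    categories = vapply(terms, `[[`, character(1), "category"),
    matrix = m,
    scores = scores,
    ranks = ranks
  ), class = "binary_grid")
}

#' @export
print.binary_grid <- function(x, ...) {
  cat(sprintf("<binary_grid> %d genes x %d terms; top score %s\n",
              length(x$genes), length(x$terms),
              if (length(x$scores)) max(x$scores) else NA))
  invisible(x)
}

#' Ranking table for a binary grid
#'
#' One row per gene: score, rank, per-category match counts, and a flag for
#' membership of a known disease-gene set. Rows are ordered by rank.
#'
#' @param grid a [build_binary_grid()] result.
#' @param known optional character vector of known disease gene ids.
#' @return data.frame.
#' @export
ranking_table <- function(grid, known = character(0)) {
  stopifnot(inherits(grid, "binary_grid"))
  percat <- sapply(TERM_CATEGORIES, function(cat) {
    cols <- which(grid$categories == cat)
    if (!length(cols)) return(integer(length(grid$genes)))
    as.integer(rowSums(grid$matrix[, cols, drop = FALSE]))
  })
  df <- data.frame(
    gene_id = grid$genes,
    score = unname(grid$scores),
    rank = unname(grid$ranks),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(percat))
  df$known = as.integer(df$gene_id %in% known)
  df[order(df$rank), , drop = FALSE]
}

#' Enrichment of a known gene set above a score threshold
#'
#' Compares the fraction of known disease genes among genes scoring at least
#' `threshold` with the fraction in the whole grid; `fold` is the ratio of
#' the two fractions.
#'
#' @param grid a `binary_grid`.
#' @param known character vector of known disease gene ids.
#' @param threshold minimum score (>= 0) to count as "top".
#' @return list of class `enrichment_summary` with fields `threshold`,
#'   `n_top`, `n_top_known`, `frac_top_known`, `n_all`, `n_all_known`,
#'   `frac_all_known`, `fold`.
#' @export
enrichment_summary <- function(grid, known, threshold) {
  stopifnot(inherits(grid, "binary_grid"))
  if (length(grid$genes) == 0L) xp_stop("empty grid")
  if (!is.numeric(threshold) || threshold < 0) xp_stop("threshold must be >= 0")
  known <- as.character(known)
  top <- grid$genes[grid$scores >= threshold]
  if (length(top) == 0L) xp_stop("no genes pass threshold ", threshold)
  n_top <- length(top)
  n_top_known <- sum(top %in% known)
  n_all <- length(grid$genes)
  n_all_known <- sum(grid$genes %in% known)
  frac_all_known <- n_all_known / n_all
  if (frac_all_known == 0)
    xp_stop("no known genes in grid: enrichment fold undefined")
  frac_top_known <- n_top_known / n_top
  structure(list(
    threshold = as.integer(threshold),
    n_top = n_top, n_top_known = n_top_known,
    frac_top_known = frac_top_known,
    n_all = n_all, n_all_known = n_all_known,
    frac_all_known = frac_all_known,
    fold = frac_top_known / frac_all_known
  ), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(
    "<enrichment_summary> score >= %d: %d/%d known (%.3f) vs %d/%d overall (%.3f); fold %.2f\n",
    x$threshold, x$n_top_known, x$n_top, x$frac_top_known,
    x$n_all_known, x$n_all, x$frac_all_known, x$fold))
  invisible(x)
}

#' Cumulative coverage of known genes along the ranking
#'
#' One row per distinct score level, from the highest level down. At level s,
#' `cumulative_known_coverage` is the fraction of known genes (restricted to
#' those present in the grid) with score >= s, and `pct_known_within_level`
#' the fraction of genes scoring exactly s that are known.
#'
#' @param grid a `binary_grid`.
#' @param known character vector of known disease gene ids; ids absent from
#'   the grid are dropped with a warning.
#' @return data.frame with columns `score_level`, `n_genes`, `n_known`,
#'   `cumulative_known_coverage`, `pct_known_within_level`.
#' @export
coverage_curve <- function(grid, known) {
  stopifnot(inherits(grid, "binary_grid"))
  known <- unique(as.character(known))
  missing <- setdiff(known, grid$genes)
  if (length(missing)) {
    warning(sprintf("%d known gene id(s) absent from grid dropped: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
    known <- intersect(known, grid$genes)
  }
  if (length(known) == 0L) xp_stop("no known genes present in grid")
  levels <- sort(unique(unname(grid$scores)), decreasing = TRUE)
  is_known <- grid$genes %in% known
  rows <- lapply(levels, function(s) {
    at <- grid$scores == s
    data.frame(
      score_level = s,
      n_genes = sum(at),
      n_known = sum(at & is_known),
      cumulative_known_coverage = sum(grid$scores[is_known] >= s) / length(known),
      pct_known_within_level = sum(at & is_known) / sum(at)
    )
  })
  do.call(rbind, rows)
}

#' Plot a coverage curve with dual axes
#'
#' Cumulative known-gene coverage from the lowest- to the highest-scoring
#' level (left axis, line) and the percentage of genes within each level
#' that are known (right axis, bars).
#'
#' @param cc a [coverage_curve()] result.
#' @param main plot title.
#' @return invisibly, `cc`.
#' @export
plot_coverage_curve <- function(cc, main = "Known-gene coverage by score level") {
  stopifnot(is.data.frame(cc), nrow(cc) > 0)
  cc <- cc[order(cc$score_level), , drop = FALSE]   # lowest to highest
  x <- seq_len(nrow(cc))
  op <- graphics::par(mar = c(4.5, 4.5, 2.5, 4.5))
  on.exit(graphics::par(op))
  graphics::barplot(100 * cc$pct_known_within_level,
                    names.arg = cc$score_level, col = "grey85",
                    border = NA, ylim = c(0, 100), axes = FALSE,
                    xlab = "score level", main = main)
  graphics::axis(4)
  graphics::mtext("% known within level", side = 4, line = 2.6)
  graphics::par(new = TRUE)
  bp_at <- seq(0.7, by = 1.2, length.out = nrow(cc))
  graphics::plot(bp_at, 100 * cc$cumulative_known_coverage, type = "b",
                 pch = 19, col = "steelblue4", ylim = c(0, 100),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2)
  graphics::mtext("cumulative % of known genes (score >= level)",
                  side = 2, line = 2.6)
  invisible(cc)
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability for the overlap of two gene sets of sizes `m` and
#' `n` drawn from a universe of `N` genes. With `strict = FALSE` (default)
#' the inclusive tail P(X >= k) is returned — the standard over-representation
#' convention. `strict = TRUE` returns P(X > k).
#'
#' @param k observed overlap.
#' @param N universe size.
#' @param m size of the first set.
#' @param n size of the second set.
#' @param strict exclude `k` itself from the tail.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_overlap <- function(k, N, m, n, strict = FALSE) {
  if (m > N || n > N) xp_stop("set sizes m, n must not exceed universe N")
  if (k < 0) xp_stop("overlap k must be >= 0")
  if (k > min(m, n)) xp_stop("overlap k cannot exceed min(m, n)")
  stats::phyper(k - 1L + as.integer(strict), m, N - m, n, lower.tail = FALSE)
}
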