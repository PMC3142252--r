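## Discriminant classification of genes from oligomer counts.
##
## The feature matrix counts each discovered oligomer (canonically, exact
## matches) in each gene's own upstream contig. Because the number of
## oligomers p typically exceeds the number of genes n, counts are first
## projected onto principal components retaining a set fraction of variance
## (capped at n - 2 components); a two-class linear discriminant with pooled
## covariance and empirical priors is fit in the reduced space. The tuning
## parameter tau is the posterior decision threshold for the disease class:
## a gene is called "disease" when P(disease | x) >= tau.

#' Build the gene-by-oligomer count feature matrix
#'
#' Counts every oligomer (and its reverse complement, exact matches) in each
#' gene's surviving upstream contig, using the same canonical scan as
#' [count_oligomers()]. Genes whose contig was discarded or that lack a TSS
#' are excluded and reported. Every source gene of a merged multi-gene contig
#' receives that contig's counts.
#'
#' @param genes validated gene table (with `tss`).
#' @param contig_set a `contig_set` from [build_contigs()].
#' @param oligomers character vector of oligomer sequences (the features), or
#'   an `oligomer_records` data.frame.
#' @param genome named `DNAStringSet`.
#' @return object of class `feature_matrix`: `counts` (genes x oligomers
#'   integer matrix), `labels` (factor disease/non_disease), `excluded`
#'   (data.frame `gene`, `reason`).
#' @export
build_feature_matrix <- function(genes, contig_set, oligomers, genome) {
  genes <- validate_gene_table(genes)
  seqs <- if (is.data.frame(oligomers)) oligomers$sequence
          else as.character(oligomers)
  if (!length(seqs)) xp_stop("oligomer list is empty")
  seqs <- unique(canonical_kmer(seqs))
  gr <- contig_set$contigs
  src <- strsplit(S4Vectors::mcols(gr)$source_genes, ",")
  gene2contig <- integer(nrow(genes))
  for (i in seq_along(src)) gene2contig[match(src[[i]], genes$id)] <- i

  has <- gene2contig > 0L
  excluded <- data.frame(gene = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (any(!has)) {
    reason <- ifelse(is.na(genes$tss[!has]), "no_tss", "contig_discarded")
    excluded <- data.frame(gene = genes$id[!has], reason = reason,
                           stringsAsFactors = FALSE)
  }
  kept <- genes[has, , drop = FALSE]
  sg <- compile_subgenome(gr, genome)
  cseqs <- as.character(sg$sequences)

  ## count per contig once, per oligomer length, then map to genes
  counts_by_contig <- matrix(0L, nrow = length(gr), ncol = length(seqs))
  for (k in unique(nchar(seqs))) {
    cols <- which(nchar(seqs) == k)
    m <- vapply(cseqs, scan_targets, integer(length(cols)),
                targets = seqs[cols], k = k, USE.NAMES = FALSE)
    counts_by_contig[, cols] <- if (is.null(dim(m))) matrix(m, ncol = 1L)
                                else t(m)
  }
  counts <- counts_by_contig[gene2contig[has], , drop = FALSE]
  dimnames(counts) <- list(kept$id, seqs)

  structure(list(
    counts = counts,
    labels = factor(kept$class, levels = c("disease", "non_disease")),
    excluded = excluded
  ), class = "feature_matrix")
}

#' Construct a feature matrix from a plain count matrix
#'
#' Mainly for tests and for re-loading serialized matrices.
#'
#' @param counts numeric matrix, genes x features, with dimnames.
#' @param labels factor or character of `disease`/`non_disease` per row.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(counts, labels) {
  stopifnot(is.matrix(counts), nrow(counts) == length(labels))
  structure(list(
    counts = counts,
    labels = factor(as.character(labels), levels = c("disease", "non_disease")),
    excluded = data.frame(gene = character(0), reason = character(0))
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d gene(s) x %d oligomer(s); %d disease / %d non_disease; %d excluded\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$labels == "disease"), sum(x$labels == "non_disease"),
              nrow(x$excluded)))
  invisible(x)
}

## internal: fit PCA + pooled-covariance LDA on a raw matrix
fit_lda_core <- function(X, y, variance_kept) {
  n <- nrow(X)
  if (any(table(y) < 1L)) xp_stop("both classes must be present")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (sum(ev) <= 0) xp_stop("zero-variance feature matrix")
  pos <- which(ev > 1e-12 * ev[1])
  q <- which(cumsum(ev[pos]) / sum(ev[pos]) >= variance_kept)[1L]
  if (is.na(q)) q <- length(pos)
  q <- max(1L, min(q, n - 2L, length(pos)))
  rot <- pr$rotation[, seq_len(q), drop = FALSE]
  Z <- pr$x[, seq_len(q), drop = FALSE]

  lev <- levels(y)
  means <- matrix(NA_real_, length(lev), q, dimnames = list(lev, NULL))
  for (cl in lev) means[cl, ] <- colMeans(Z[y == cl, , drop = FALSE])
  ## pooled covariance over classes with >= 2 members
  S <- matrix(0, q, q); dof <- 0L
  for (cl in lev) {
    Zc <- Z[y == cl, , drop = FALSE]
    if (nrow(Zc) >= 2L) {
      S <- S + (nrow(Zc) - 1L) * stats::cov(Zc)
      dof <- dof + nrow(Zc) - 1L
    }
  }
  if (dof == 0L) xp_stop("need at least one class with >= 2 members")
  S <- S / dof
  Sinv <- tryCatch(solve(S), error = function(e) pseudo_inverse(S))
  priors <- as.numeric(table(y)[lev]) / n
  list(center = pr$center, rotation = rot, means = means, Sinv = Sinv,
       priors = stats::setNames(priors, lev), q = q)
}

#' Train the LDA classifier
#'
#' Centers the counts, projects onto principal components retaining
#' `variance_kept` of total variance (at most n - 2 components), and fits a
#' two-class linear discriminant with pooled covariance and empirical class
#' priors in the reduced space. `tau` is stored as the posterior decision
#' threshold for the disease class.
#'
#' @param fm a `feature_matrix` (both classes with >= 2 genes).
#' @param tau decision threshold in (0, 1).
#' @param variance_kept fraction of variance retained by the PCA step.
#' @return object of class `lda_model`.
#' @export
train_lda <- function(fm, tau = 0.5, variance_kept = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!(tau > 0 && tau < 1)) xp_stop("tau must be in (0, 1)")
  if (any(table(fm$labels) < 2L))
    xp_stop("each class needs >= 2 genes to train")
  core <- fit_lda_core(fm$counts, fm$labels, variance_kept)
  structure(c(core, list(tau = tau, variance_kept = variance_kept,
                         features = colnames(fm$counts))),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d feature(s) -> %d component(s); priors %.2f/%.2f; tau = %.3g\n",
              length(x$features), x$q, x$priors[1], x$priors[2], x$tau))
  invisible(x)
}

## internal: disease posteriors for a raw count matrix under a fitted core
posterior_disease <- function(core, X) {
  Z <- sweep(X, 2L, core$center) %*% core$rotation
  lev <- rownames(core$means)
  disc <- vapply(seq_along(lev), function(i) {
    mu <- core$means[i, ]
    drop(Z %*% (core$Sinv %*% mu)) - 0.5 * drop(mu %*% core$Sinv %*% mu) +
      log(core$priors[i])
  }, numeric(nrow(Z)))
  disc <- matrix(disc, nrow = nrow(Z))
  m <- apply(disc, 1L, max)
  p <- exp(disc - m)
  p <- p / rowSums(p)
  p[, which(lev == "disease")]
}

#' Predict disease status with a trained model
#'
#' @param object an `lda_model`.
#' @param newdata a `feature_matrix` or count matrix whose columns must equal
#'   the model's features (in order); otherwise an error demands
#'   re-featurization.
#' @param ... unused.
#' @return data.frame with `gene`, `posterior_disease`, `predicted`.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$counts else newdata
  if (!identical(colnames(X), object$features))
    xp_stop("feature mismatch: re-featurize the input on the model's oligomer list")
  post <- posterior_disease(object, X)
  data.frame(
    gene = if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X),
    posterior_disease = post,
    predicted = factor(ifelse(post >= object$tau, "disease", "non_disease"),
                       levels = c("disease", "non_disease")),
    stringsAsFactors = FALSE
  )
}

## internal: leave-one-out disease posteriors (PCA refit in every fold);
## folds where the training data degenerates fall back to the prior
loocv_posteriors <- function(X, y, variance_kept) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    core <- tryCatch(fit_lda_core(Xi, yi, variance_kept),
                     error = function(e) NULL)
    if (is.null(core)) return(unname(mean(yi == "disease")))
    posterior_disease(core, X[i, , drop = FALSE])
  }, numeric(1))
}

## internal: per-class success rates from posteriors at threshold tau
cv_from_posteriors <- function(genes, y, post, tau) {
  pred <- factor(ifelse(post >= tau, "disease", "non_disease"),
                 levels = levels(y))
  sd_ <- 100 * mean(pred[y == "disease"] == "disease")
  sn <- 100 * mean(pred[y == "non_disease"] == "non_disease")
  structure(list(
    per_gene = data.frame(gene = genes, label = y, predicted = pred,
                          posterior_disease = post, stringsAsFactors = FALSE),
    success_disease = sd_,
    success_non_disease = sn,
    balanced_accuracy = (sd_ + sn) / 2,
    tau = tau
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> tau = %.3g: success disease %.1f%% (n=%d), non-disease %.1f%% (n=%d)\n",
              x$tau, x$success_disease, sum(x$per_gene$label == "disease"),
              x$success_non_disease, sum(x$per_gene$label == "non_disease")))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For every gene, the model (PCA included) is refit on the remaining genes
#' and the held-out gene is predicted; per-class success percentages are
#' aggregated. A fold whose training data degenerates (a class left with no
#' member after zero-variance filtering) is predicted from the class prior.
#'
#' @param fm a `feature_matrix` with >= 3 genes and >= 2 per class.
#' @param tau posterior decision threshold in (0, 1).
#' @param variance_kept PCA variance fraction.
#' @return object of class `cv_result` with `per_gene`, `success_disease`,
#'   `success_non_disease`, `balanced_accuracy`, `tau`.
#' @export
loocv <- function(fm, tau = 0.5, variance_kept = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$counts) < 3L) xp_stop("need >= 3 genes for LOOCV")
  if (any(table(fm$labels) < 2L)) xp_stop("each class needs >= 2 genes")
  if (!(tau > 0 && tau < 1)) xp_stop("tau must be in (0, 1)")
  post <- loocv_posteriors(fm$counts, fm$labels, variance_kept)
  cv_from_posteriors(rownames(fm$counts), fm$labels, post, tau)
}

#' Sweep the decision threshold tau
#'
#' Leave-one-out posteriors are computed once; each tau in the grid is then a
#' thresholding of the same posteriors (mathematically identical to running
#' [loocv()] per tau, since tau does not enter the fit). The optimum maximizes
#' balanced accuracy, ties resolved toward the larger tau.
#'
#' @param fm a `feature_matrix`.
#' @param grid numeric vector of thresholds, all in (0, 1).
#' @param variance_kept PCA variance fraction.
#' @return list with `table` (data.frame `tau`, `success_disease`,
#'   `success_non_disease`, `balanced_accuracy`), `optimum` (the selected
#'   tau), and `results` (list of `cv_result`, one per tau).
#' @export
sweep_tau <- function(fm, grid = seq(0.05, 0.95, by = 0.05),
                      variance_kept = 0.95) {
  if (!length(grid)) xp_stop("empty tau grid")
  if (any(grid <= 0 | grid >= 1)) xp_stop("tau grid must lie in (0, 1)")
  stopifnot(inherits(fm, "feature_matrix"))
  post <- loocv_posteriors(fm$counts, fm$labels, variance_kept)
  results <- lapply(grid, function(tau)
    cv_from_posteriors(rownames(fm$counts), fm$labels, post, tau))
  tab <- data.frame(
    tau = grid,
    success_disease = vapply(results, `[[`, numeric(1), "success_disease"),
    success_non_disease = vapply(results, `[[`, numeric(1), "success_non_disease"),
    balanced_accuracy = vapply(results, `[[`, numeric(1), "balanced_accuracy")
  )
  best <- max(which(tab$balanced_accuracy == max(tab$balanced_accuracy)))
  list(table = tab, optimum = grid[best], results = results)
}

#' Predict a foreign gene set with a trained classifier
#'
#' No retraining: the model trained on one stratum scores genes from another.
#' The foreign feature matrix must be featurized on the model's own oligomer
#' list.
#'
#' @param model an `lda_model`.
#' @param fm_other a `feature_matrix` on the same features.
#' @return a `cv_result`-shaped report (per-gene predictions and per-class
#'   success rates on the foreign set).
#' @export
cross_predict <- function(model, fm_other) {
  stopifnot(inherits(model, "lda_model"), inherits(fm_other, "feature_matrix"))
  pred <- predict(model, fm_other)
  cv_from_posteriors(pred$gene, fm_other$labels, pred$posterior_disease,
                     model$tau)
}

#' Combine annotation ranking with sequence-based classification
#'
#' Per gene: annotation score, exclusion reason if the sequence route could
#' not assess it, the predicted label at each distance (X = disease signature,
#' NX = non-disease), whether the calls agree with prior knowledge
#' ("correct"), and a candidate flag for genes not previously associated with
#' the disease that are nevertheless called X at two or more distances.
#'
#' @param ranking data.frame from [ranking_table()] (needs `gene_id`, `score`,
#'   `known`).
#' @param predictions data.frame with columns `gene`, `distance_kb`,
#'   `predicted` (levels disease/non_disease), concatenated over distances
#'   (e.g. `cv$per_gene` augmented with a `distance_kb` column).
#' @param exclusions optional data.frame `gene`, `reason`.
#' @param min_score annotation score cut-off defining the high-ranking set.
#' @return data.frame, one row per high-ranking gene.
#' @export
combined_report <- function(ranking, predictions, exclusions = NULL,
                            min_score = 10L) {
  stopifnot(all(c("gene_id", "score", "known") %in% names(ranking)),
            all(c("gene", "distance_kb", "predicted") %in% names(predictions)))
  top <- ranking[ranking$score >= min_score, , drop = FALSE]
  dists <- sort(unique(predictions$distance_kb))
  out <- data.frame(gene_id = top$gene_id, score = top$score,
                    known = top$known, stringsAsFactors = FALSE)
  out$excluded_reason <- ""
  if (!is.null(exclusions) && nrow(exclusions)) {
    m <- match(out$gene_id, exclusions$gene)
    out$excluded_reason <- ifelse(is.na(m), "", exclusions$reason[m])
  }
  calls <- matrix(NA_character_, nrow(out), length(dists),
                  dimnames = list(NULL, paste0("call_", dists, "kb")))
  for (j in seq_along(dists)) {
    p <- predictions[predictions$distance_kb == dists[j], , drop = FALSE]
    m <- match(out$gene_id, p$gene)
    calls[, j] <- ifelse(is.na(m), NA_character_,
                         ifelse(p$predicted[m] == "disease", "X", "NX"))
  }
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
  n_x <- rowSums(calls == "X", na.rm = TRUE)
  n_called <- rowSums(!is.na(calls))
  ## "correctly classified": every available call matches prior knowledge
  expected <- ifelse(out$known == 1L, "X", "NX")
  out$correct <- n_called > 0 &
    rowSums(calls == expected, na.rm = TRUE) == n_called
  out$candidate <- out$known == 0L & n_x >= 2L
  out
}
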