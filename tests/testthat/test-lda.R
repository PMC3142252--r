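## Feature matrix construction, the PCA+LDA classifier, LOOCV, the tau sweep,
## cross-stratum prediction and the combined report.

## simulated Gaussian count-like matrix with a class mean shift
gauss_fm <- function(n1, n2, p, shift, seed, sd = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p, shift, sd), n1),
             matrix(rnorm(n2 * p, 0, sd), n2))
  dimnames(X) <- list(sprintf("g%03d", seq_len(n1 + n2)),
                      sprintf("f%02d", seq_len(p)))
  feature_matrix(X, rep(c("disease", "non_disease"), c(n1, n2)))
}

test_that("feature matrix counts planted oligomers in each gene's contig", {
  set.seed(3)
  chrom <- rand_dna(60000)
  motif <- "TGCATTAGGCAT"
  ## plant 7 copies upstream of gene a (contig [17500, 19500))
  for (a in seq(17600, 19300, length.out = 7))
    substr(chrom, round(a), round(a) + 11) <- motif
  genome <- Biostrings::DNAStringSet(chrom); names(genome) <- "c1"
  g <- toy_genes(
    list(id = "a", start = 20000, end = 22000, tss = 19500),
    list(id = "b", start = 40000, end = 42000, tss = 39500,
         class = "non_disease"),
    list(id = "c", start = 50000, end = 52000))   # no TSS -> excluded
  cs <- build_contigs(g, 2)
  absent <- "ACACACACACAC"
  fm <- build_feature_matrix(g, cs, c(motif, absent), genome)
  expect_equal(unname(fm$counts["a", canonical_kmer(motif)]), 7L)
  ## absent oligomer: all-zero column retained
  expect_true(canonical_kmer(absent) %in% colnames(fm$counts))
  expect_equal(sum(fm$counts[, canonical_kmer(absent)]), 0L)
  expect_equal(fm$excluded$gene, "c")
  expect_equal(fm$excluded$reason, "no_tss")

  ## merged multi-gene contig: every source gene gets the contig's counts
  g2 <- toy_genes(list(id = "a", start = 20000, end = 22000, tss = 19500),
                  list(id = "b", start = 24000, end = 26000, tss = 23500))
  cs2 <- build_contigs(g2, 10)
  expect_equal(length(cs2$contigs), 1L)
  fm2 <- build_feature_matrix(g2, cs2, motif, genome)
  expect_equal(fm2$counts["a", ], fm2$counts["b", ])
})

test_that("training errors on degenerate inputs and separates clean data", {
  fm <- gauss_fm(10, 12, 5, shift = 6, seed = 1)
  model <- train_lda(fm, tau = 0.5)
  pred <- predict(model, fm)
  expect_equal(as.character(pred$predicted),
               as.character(fm$labels))              # resubstitution 100%
  expect_true(all(pred$posterior_disease >= 0 & pred$posterior_disease <= 1))

  ## duplicating every sample leaves class means unchanged
  fm2 <- feature_matrix(rbind(fm$counts, fm$counts),
                        rep(as.character(fm$labels), 2))
  m2 <- train_lda(fm2, tau = 0.5)
  expect_equal(m2$means, model$means, tolerance = 1e-8)

  one <- feature_matrix(fm$counts[1:3, ], c("disease", rep("non_disease", 2)))
  expect_error(train_lda(one), ">= 2 genes")
  flat <- feature_matrix(matrix(1, 6, 3,
                                dimnames = list(letters[1:6], LETTERS[1:3])),
                         rep(c("disease", "non_disease"), 3))
  expect_error(train_lda(flat), "zero-variance")
  expect_error(train_lda(fm, tau = 1.2), "tau must be")
})

test_that("with n > p and all variance kept, LDA matches the closed form", {
  ## two features, class means (2,0) and (0,0), equal spherical covariance,
  ## equal priors: the boundary is x1 = 1 and the posterior is a logistic in
  ## x1 alone
  ## symmetric 4-point template with sample covariance exactly I2
  cc <- sqrt(3 / 2)
  tmpl <- rbind(c(cc, 0), c(-cc, 0), c(0, cc), c(0, -cc))
  X <- rbind(sweep(tmpl, 2, c(2, 0), "+"), tmpl)
  dimnames(X) <- list(sprintf("g%02d", 1:8), c("x1", "x2"))
  fm <- feature_matrix(X, rep(c("disease", "non_disease"), each = 4))
  model <- train_lda(fm, tau = 0.5, variance_kept = 1)
  probe <- matrix(c(1, 0,   1, 5,   1.01, 0,   0.99, 0), 4, 2, byrow = TRUE,
                  dimnames = list(NULL, c("x1", "x2")))
  pred <- predict(model, probe)
  expect_equal(pred$posterior_disease[1], 0.5, tolerance = 1e-6)
  expect_equal(pred$posterior_disease[2], 0.5, tolerance = 1e-6)  # x2 irrelevant
  expect_equal(as.character(pred$predicted[3:4]), c("disease", "non_disease"))
})

test_that("LOOCV is perfect on separable data and invariant to ordering", {
  fm <- gauss_fm(8, 10, 6, shift = 8, seed = 2)
  cv <- loocv(fm, tau = 0.5)
  expect_equal(cv$success_disease, 100)
  expect_equal(cv$success_non_disease, 100)

  ## permuting gene order and feature order changes nothing
  set.seed(4)
  gi <- sample(nrow(fm$counts)); fi <- sample(ncol(fm$counts))
  fmp <- feature_matrix(fm$counts[gi, fi], as.character(fm$labels)[gi])
  cvp <- loocv(fmp, tau = 0.5)
  expect_equal(cvp$success_disease, cv$success_disease)
  expect_equal(cvp$success_non_disease, cv$success_non_disease)
  expect_equal(cvp$per_gene$posterior_disease[order(cvp$per_gene$gene)],
               cv$per_gene$posterior_disease[order(cv$per_gene$gene)],
               tolerance = 1e-8)

  expect_error(loocv(gauss_fm(1, 2, 3, 1, 1)), ">= 2 genes|>= 3 genes")
})

test_that("tau is a decision threshold: extremes and monotonicity", {
  fm <- gauss_fm(6, 9, 4, shift = 1, seed = 5)   # overlapping classes
  sw <- sweep_tau(fm, grid = c(1e-10, seq(0.1, 0.9, 0.2), 1 - 1e-10))
  tab <- sw$table
  ## tau -> 0: everything called disease; tau -> 1: nothing is
  expect_equal(tab$success_disease[1], 100)
  expect_equal(tab$success_non_disease[1], 0)
  expect_equal(tab$success_disease[nrow(tab)], 0)
  expect_equal(tab$success_non_disease[nrow(tab)], 100)
  ## thresholding is monotone by construction
  expect_true(all(diff(tab$success_disease) <= 1e-9))
  expect_true(all(diff(tab$success_non_disease) >= -1e-9))
  ## the ROC staircase (sensitivity vs 100 - specificity) is monotone
  fpr <- 100 - tab$success_non_disease
  expect_true(all(diff(fpr) <= 1e-9))

  ## ties in balanced accuracy resolve to the larger tau
  fme <- gauss_fm(8, 10, 6, shift = 8, seed = 2)
  swe <- sweep_tau(fme, grid = seq(0.1, 0.9, 0.1))
  expect_equal(swe$table$balanced_accuracy[swe$table$tau == swe$optimum], 100)
  expect_equal(swe$optimum,
               max(swe$table$tau[swe$table$balanced_accuracy == 100]))
  expect_error(sweep_tau(fme, numeric(0)), "empty")
  expect_error(sweep_tau(fme, c(0.5, 1.5)), "in \\(0, 1\\)")
})

test_that("cross prediction refuses mismatched features and handles degenerate input", {
  fm <- gauss_fm(8, 10, 6, shift = 8, seed = 6)
  model <- train_lda(fm, tau = 0.5)
  ## train = predict set: equals resubstitution
  cp <- cross_predict(model, fm)
  resub <- predict(model, fm)
  expect_equal(cp$per_gene$posterior_disease, resub$posterior_disease)

  bad <- fm; colnames(bad$counts)[1] <- "other_feature"
  expect_error(cross_predict(model, bad), "re-featurize")

  ## all-zero foreign counts: every gene gets the majority-prior class
  zero <- feature_matrix(matrix(0, 5, 6,
                                dimnames = list(paste0("z", 1:5),
                                                colnames(fm$counts))),
                         c("disease", "disease", rep("non_disease", 3)))
  cpz <- cross_predict(model, zero)
  expect_equal(length(unique(as.character(cpz$per_gene$predicted))), 1L)
})

test_that("combined report flags candidates and exclusions per the definitions", {
  ranking <- data.frame(gene_id = c("MA", "KN", "NT", "LOW"),
                        score = c(12L, 15L, 11L, 4L),
                        known = c(0L, 1L, 0L, 0L))
  preds <- rbind(
    data.frame(gene = c("MA", "KN"), distance_kb = 10,
               predicted = c("non_disease", "disease")),
    data.frame(gene = c("MA", "KN"), distance_kb = 50,
               predicted = c("disease", "disease")),
    data.frame(gene = c("MA", "KN"), distance_kb = 100,
               predicted = c("disease", "disease")))
  excl <- data.frame(gene = "NT", reason = "no_tss")
  rep_ <- combined_report(ranking, preds, excl, min_score = 10)
  expect_equal(nrow(rep_), 3L)            # LOW filtered by min_score
  ma <- rep_[rep_$gene_id == "MA", ]
  ## non-disease gene called X at two distances: the candidate pattern
  expect_equal(unlist(ma[, c("call_10kb", "call_50kb", "call_100kb")],
                      use.names = FALSE), c("NX", "X", "X"))
  expect_true(ma$candidate)
  expect_false(ma$correct)
  kn <- rep_[rep_$gene_id == "KN", ]
  expect_true(kn$correct)                 # known disease gene, X throughout
  expect_false(kn$candidate)
  nt <- rep_[rep_$gene_id == "NT", ]
  expect_equal(nt$excluded_reason, "no_tss")
  expect_true(is.na(nt$call_10kb))
})
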