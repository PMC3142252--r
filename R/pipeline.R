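## End-to-end orchestration of the sequence-based route, and the package CLI.

#' Run the sequence-based prioritization pipeline on one stratum
#'
#' Recovers representative TSSs from tag clusters, builds the disease and
#' non-disease subgenomes at one upstream distance, screens k-mers for
#' overrepresentation in both directions, confirms them by the permutation
#' test, builds the gene-by-oligomer feature matrix from the significant
#' oligomers of both profiles, and evaluates an LDA classifier by
#' leave-one-out cross-validation over a tau grid.
#'
#' @param genes gene table (tss may be NA; recovered from `tss_clusters`).
#' @param genome named `DNAStringSet`.
#' @param tss_clusters tag-cluster data.frame, or `NULL` if `genes$tss` is
#'   already populated.
#' @param distance_kb upstream distance (kilobases).
#' @param k oligomer size (default 12, the most productive size).
#' @param criteria an [overrep_criteria()].
#' @param seed integer seed for the permutation test.
#' @param stratum stratum label to analyze, or `NULL` for all genes.
#' @param tau_grid thresholds for [sweep_tau()].
#' @param variance_kept PCA variance fraction.
#' @param merge merge overlapping significant oligomers into longer ones
#'   before featurization.
#' @return list with `genes` (TSS-annotated), `subgenomes`, `oligomers`
#'   (screened records for both profiles, permutation columns filled),
#'   `features`, `fm`, `sweep`, `cv` (the `cv_result` at the optimal tau) and
#'   `model` (trained on all genes at the optimal tau).
#' @export
run_motif_pipeline <- function(genes, genome, tss_clusters = NULL,
                               distance_kb = 10, k = 12L,
                               criteria = overrep_criteria(), seed = 1L,
                               stratum = NULL,
                               tau_grid = seq(0.05, 0.95, by = 0.05),
                               variance_kept = 0.95, merge = FALSE) {
  genes <- validate_gene_table(genes)
  if (!is.null(tss_clusters)) genes <- assign_tss(genes, tss_clusters)
  sg <- build_subgenomes(genes, genome, distance_kb, stratum = stratum)

  screen <- function(focal, other) {
    cand <- find_overrepresented(focal, other, k, criteria)
    permutation_test(focal, other, cand, criteria, seed = seed)
  }
  olig_d <- screen(sg$disease, sg$non_disease)
  olig_n <- screen(sg$non_disease, sg$disease)
  olig_d$profile <- rep("disease", nrow(olig_d))
  olig_n$profile <- rep("non_disease", nrow(olig_n))
  oligomers <- rbind(olig_d, olig_n)

  feats <- oligomers$sequence[oligomers$significant]
  if (merge && length(feats)) feats <- merge_oligomers(feats)$sequence
  if (!length(feats))
    return(list(genes = genes, subgenomes = sg, oligomers = oligomers,
                features = character(0), fm = NULL, sweep = NULL, cv = NULL,
                model = NULL))

  fm <- build_feature_matrix(genes[if (is.null(stratum)) TRUE
                                   else genes$stratum == stratum, ,
                                   drop = FALSE],
                             sg$contig_set, feats, genome)
  sw <- sweep_tau(fm, tau_grid, variance_kept)
  cv <- sw$results[[which(tau_grid == sw$optimum)[1]]]
  model <- train_lda(fm, tau = sw$optimum, variance_kept = variance_kept)
  list(genes = genes, subgenomes = sg, oligomers = oligomers,
       features = feats, fm = fm, sweep = sw, cv = cv, model = model)
}

#' Leave-one-out cross-validation with nested oligomer discovery
#'
#' The default pipeline discovers oligomers once, on all genes, and then
#' cross-validates the classifier — mirroring the reference procedure, but
#' optimistic because the held-out gene's sequence contributed to feature
#' selection. This variant moves discovery inside the loop: for every fold
#' the held-out gene is removed, subgenomes are rebuilt, the
#' overrepresentation screen is re-run on the remaining genes only, and the
#' held-out gene is featurized on the fold's own oligomer list. The
#' permutation confirmation is skipped inside folds by default
#' (`perm_trials = NULL`) since re-running it per fold multiplies cost
#' without changing the screen's retained set much; pass a trial count to
#' enable it.
#'
#' @param genes gene table with `tss` populated.
#' @param genome named `DNAStringSet`.
#' @param distance_kb upstream distance.
#' @param k oligomer size.
#' @param criteria an [overrep_criteria()].
#' @param tau posterior decision threshold.
#' @param variance_kept PCA variance fraction.
#' @param stratum stratum to analyze, or `NULL`.
#' @param perm_trials `NULL` to skip the in-fold permutation test, or a
#'   trial count (the in-fold significance threshold scales as 5% of it).
#' @param seed seed for in-fold permutation tests (unused when skipped).
#' @return a `cv_result`; genes with no surviving contig in the full data
#'   are excluded up front (as in the default route).
#' @export
loocv_nested <- function(genes, genome, distance_kb = 10, k = 12L,
                         criteria = overrep_criteria(), tau = 0.5,
                         variance_kept = 0.95, stratum = NULL,
                         perm_trials = NULL, seed = 1L) {
  genes <- validate_gene_table(genes)
  if (!is.null(stratum)) genes <- genes[genes$stratum == stratum, , drop = FALSE]
  full <- build_subgenomes(genes, genome, distance_kb)
  src <- unlist(strsplit(S4Vectors::mcols(full$contig_set$contigs)$source_genes,
                         ","))
  eligible <- genes[genes$id %in% src, , drop = FALSE]
  if (nrow(eligible) < 3L) xp_stop("need >= 3 genes with surviving contigs")

  post <- vapply(seq_len(nrow(eligible)), function(i) {
    held <- eligible$id[i]
    rest <- genes[genes$id != held, , drop = FALSE]
    sg <- build_subgenomes(rest, genome, distance_kb)
    feats <- character(0)
    for (dirn in 1:2) {
      f <- if (dirn == 1) sg$disease else sg$non_disease
      o <- if (dirn == 1) sg$non_disease else sg$disease
      if (f$total_length == 0 || o$total_length == 0) next
      cand <- find_overrepresented(f, o, k, criteria)
      if (!is.null(perm_trials) && nrow(cand)) {
        crit_in <- overrep_criteria(
          min_count = criteria$min_count, min_fold = criteria$min_fold,
          perm_trials = perm_trials,
          max_perm_hits = max(1L, as.integer(0.05 * perm_trials)),
          fragment_bp = criteria$fragment_bp, normalize = criteria$normalize)
        cand <- permutation_test(f, o, cand, crit_in, seed = seed + i)
        cand <- cand[cand$significant, , drop = FALSE]
      }
      feats <- c(feats, cand$sequence)
    }
    feats <- unique(feats)
    if (!length(feats)) return(unname(mean(rest$class == "disease")))
    fm_tr <- build_feature_matrix(rest, sg$contig_set, feats, genome)
    if (any(table(fm_tr$labels) < 2L))
      return(unname(mean(rest$class == "disease")))
    model <- train_lda(fm_tr, tau = tau, variance_kept = variance_kept)
    ## featurize the held-out gene on the fold's oligomer list, using the
    ## full-data contig set (its own contig must not depend on itself being
    ## excluded)
    fm_all <- build_feature_matrix(genes, full$contig_set, feats, genome)
    predict(model, fm_all$counts[held, , drop = FALSE])$posterior_disease
  }, numeric(1))

  cv_from_posteriors(eligible$id,
                     factor(eligible$class,
                            levels = c("disease", "non_disease")),
                     post, tau)
}

#' Read and validate a pipeline configuration file
#'
#' A single declarative JSON document holding shared pipeline settings:
#' `distances_kb` (numeric vector), `kmer_sizes` (vector over 8..24),
#' `criteria` (fields of [overrep_criteria()]), `lda` (`tau_grid`,
#' `variance_kept`), `seed`, and `paths` (named file paths, all of which
#' must exist at validation time). Every CLI subcommand accepts `--config`;
#' explicit command-line options win over config values.
#'
#' @param path JSON file.
#' @return validated list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) xp_stop("config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$distances_kb) && any(cfg$distances_kb <= 0))
    xp_stop("config: distances_kb must be positive")
  if (!is.null(cfg$kmer_sizes) && any(cfg$kmer_sizes < 1))
    xp_stop("config: kmer_sizes must be >= 1")
  if (!is.null(cfg$criteria))
    cfg$criteria <- do.call(overrep_criteria, cfg$criteria)
  if (!is.null(cfg$lda$tau_grid) &&
      any(cfg$lda$tau_grid <= 0 | cfg$lda$tau_grid >= 1))
    xp_stop("config: tau_grid must lie in (0, 1)")
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) xp_stop("config: path does not exist: ", p)
  structure(cfg, class = "pipeline_config")
}

## ---------------------------------------------------------------------------
## Command-line interface: xprio <subcommand> --key value ...
## Subcommands: simulate, rank-annotations, build-subgenomes, find-oligomers,
## sweep-tau, combine. Installed as inst/cli/xprio.R.

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--"))
      xp_stop("unexpected argument: ", args[i])
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss)) xp_stop("missing required option(s): --",
                            paste(miss, collapse = " --"))
}

#' Command-line entry point
#'
#' Dispatches `xprio <subcommand> --key value ...`. See the README for the
#' subcommand reference. Intended to be called from the installed script
#' `inst/cli/xprio.R`; exported so that `Rscript -e 'xprio::xprio_cli()'`
#' works too.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return invisibly, the main result object of the subcommand.
#' @export
xprio_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    xp_stop("usage: xprio <simulate|rank-annotations|build-subgenomes|",
            "find-oligomers|sweep-tau|combine> --key value ...")
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L])

  ## --config supplies defaults; explicit options win
  if (!is.null(opts$config)) {
    cfg <- read_pipeline_config(opts$config)
    fill <- function(key, val) {
      if (is.null(opts[[key]]) && !is.null(val))
        opts[[key]] <<- if (is.numeric(val) && length(val) > 1L)
          paste(val, collapse = ",") else val
    }
    fill("seed", cfg$seed)
    fill("distances", cfg$distances_kb)
    fill("k", cfg$kmer_sizes[1L])
    if (!is.null(cfg$criteria)) {
      fill("min-count", cfg$criteria$min_count)
      fill("min-fold", cfg$criteria$min_fold)
      fill("perm", cfg$criteria$perm_trials)
      fill("max-perm-hits", cfg$criteria$max_perm_hits)
    }
    fill("variance", cfg$lda$variance_kept)
    if (is.null(opts$grid) && !is.null(cfg$lda$tau_grid))
      opts$grid <- paste(cfg$lda$tau_grid, collapse = ",")
    opts$config <- NULL
  }

  if (cmd == "simulate") {
    cli_need(opts, c("preset", "seed", "out-dir"))
    sim <- simulate_dataset(regime_preset(opts$preset,
                                          seed = as.integer(opts$seed)))
    write_sim_dataset(sim, opts[["out-dir"]])
    xp_log("simulated dataset written to ", opts[["out-dir"]])
    return(invisible(sim))
  }

  if (cmd == "rank-annotations") {
    cli_need(opts, c("genes", "terms", "out"))
    gene_ids <- readLines(opts$genes)
    terms <- read_term_lists(opts$terms)
    known <- if (!is.null(opts$known)) readLines(opts$known) else character(0)
    grid <- build_binary_grid(gene_ids, terms)
    write_tsv(ranking_table(grid, known), opts$out)
    if (!is.null(opts$threshold) && length(known))
      print(enrichment_summary(grid, known, as.integer(opts$threshold)))
    return(invisible(grid))
  }

  if (cmd == "build-subgenomes") {
    cli_need(opts, c("genes", "tss-clusters", "fasta", "distances", "out-dir"))
    genes <- assign_tss(read_gene_table(opts$genes),
                        read_tag_clusters(opts[["tss-clusters"]]))
    genome <- read_fasta(opts$fasta)
    dir.create(opts[["out-dir"]], showWarnings = FALSE, recursive = TRUE)
    for (d in as.numeric(strsplit(opts$distances, ",")[[1]])) {
      for (s in unique(genes$stratum)) {
        sg <- build_subgenomes(genes, genome, d, stratum = s)
        for (prof in c("disease", "non_disease")) {
          stem <- file.path(opts[["out-dir"]], sprintf("%s_%s_%gkb", prof, s, d))
          write_fasta(sg[[prof]]$sequences, paste0(stem, ".fa"))
        }
        write_contigs_bed(sg$contig_set,
                          file.path(opts[["out-dir"]],
                                    sprintf("contigs_%s_%gkb.bed", s, d)))
      }
    }
    return(invisible(NULL))
  }

  if (cmd == "find-oligomers") {
    cli_need(opts, c("focal", "other", "k", "seed", "out"))
    focal <- read_fasta(opts$focal); other <- read_fasta(opts$other)
    crit <- overrep_criteria(
      min_count = as.integer(opts[["min-count"]] %||% 10L),
      min_fold = as.numeric(opts[["min-fold"]] %||% 5),
      perm_trials = as.integer(opts$perm %||% 1000L),
      max_perm_hits = as.integer(opts[["max-perm-hits"]] %||%
                                   (0.05 * as.integer(opts$perm %||% 1000L))))
    rec <- find_overrepresented(focal, other, as.integer(opts$k), crit)
    rec <- permutation_test(focal, other, rec, crit,
                            seed = as.integer(opts$seed))
    write_oligomer_records(rec, opts$out)
    return(invisible(rec))
  }

  if (cmd == "sweep-tau") {
    cli_need(opts, c("features", "labels", "out"))
    counts <- as.matrix(utils::read.delim(opts$features, row.names = 1L,
                                          check.names = FALSE))
    labels <- utils::read.delim(opts$labels)
    fm <- feature_matrix(counts, labels$class[match(rownames(counts),
                                                    labels$id)])
    grid <- if (!is.null(opts$grid)) {
      if (grepl(":", opts$grid)) {
        gg <- as.numeric(strsplit(opts$grid, ":")[[1]])
        seq(gg[1], gg[2], by = gg[3])
      } else as.numeric(strsplit(opts$grid, ",")[[1]])
    } else seq(0.05, 0.95, by = 0.05)
    sw <- sweep_tau(fm, grid,
                    variance_kept = as.numeric(opts$variance %||% 0.95))
    write_tsv(sw$table, opts$out)
    xp_log("optimal tau = ", sw$optimum)
    return(invisible(sw))
  }

  if (cmd == "combine") {
    cli_need(opts, c("ranking", "cv", "out"))
    ranking <- utils::read.delim(opts$ranking)
    preds <- utils::read.delim(opts$cv)
    excl <- if (!is.null(opts$exclusions)) utils::read.delim(opts$exclusions)
    rep_ <- combined_report(ranking, preds, excl,
                            min_score = as.integer(opts[["min-score"]] %||% 10L))
    write_tsv(rep_, opts$out)
    return(invisible(rep_))
  }

  xp_stop("unknown subcommand: ", cmd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
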