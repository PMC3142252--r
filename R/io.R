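## Readers and writers for every interchange format the pipeline touches.
## TSV with documented headers everywhere; BED is strictly 0-based half-open;
## FASTA is written at 60 columns. All writers are deterministic given
## identical inputs (stable column order, fixed number formatting).

## internal: deterministic TSV writer
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, need) {
  if (!file.exists(path)) xp_stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) xp_stop(path, " missing column(s): ",
                            paste(miss, collapse = ", "))
  df
}

#' Read / write a gene table
#'
#' TSV schema: `id`, `chrom`, `start`, `end`, `strand`, `class`, `stratum`,
#' optional `tss` (NA allowed). Coordinates are 0-based half-open. Malformed
#' rows are reported with their line numbers.
#'
#' @param path file path.
#' @return validated gene table data.frame.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_checked(path, c("id", "chrom", "start", "end", "strand",
                                 "class", "stratum"))
  if (!is.null(df$tss)) df$tss <- suppressWarnings(as.integer(df$tss))
  validate_gene_table(df)
}

#' @rdname read_gene_table
#' @param genes validated gene table.
#' @export
write_gene_table <- function(genes, path) {
  write_tsv(validate_gene_table(genes), path)
}

#' Read / write TSS tag clusters
#'
#' TSV schema: `chrom`, `start`, `end`, `strand`, `tag_count`
#' (0-based half-open; `tag_count >= 1`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tag_clusters <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "strand", "tag_count"))
  bad <- which(df$end <= df$start)
  if (length(bad)) xp_stop("end <= start at line(s): ", paste(bad, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) xp_stop("unknown strand at line(s): ", paste(bad, collapse = ", "))
  bad <- which(df$tag_count < 1L)
  if (length(bad)) xp_stop("tag_count < 1 at line(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_tag_clusters
#' @param clusters tag-cluster data.frame.
#' @export
write_tag_clusters <- function(clusters, path) write_tsv(clusters, path)

#' Read / write annotation-term lists
#'
#' TSV schema: `term`, `category`, `gene_id` — one row per term-gene pair.
#' A term with no genes may be declared with an empty `gene_id`.
#'
#' @param path file path.
#' @return list of [annotation_term()] objects.
#' @export
read_term_lists <- function(path) {
  df <- read_tsv_checked(path, c("term", "category", "gene_id"))
  terms <- lapply(split(df, factor(df$term, levels = unique(df$term))),
                  function(d) {
    g <- d$gene_id[!is.na(d$gene_id) & nzchar(d$gene_id)]
    annotation_term(d$term[1], d$category[1], g)
  })
  unname(terms)
}

#' @rdname read_term_lists
#' @param terms list of `annotation_term` objects.
#' @export
write_term_lists <- function(terms, path) {
  rows <- lapply(terms, function(t) {
    g <- if (length(t$genes)) t$genes else ""
    data.frame(term = t$name, category = t$category, gene_id = g,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read / write FASTA
#'
#' Thin Biostrings wrappers; written at 60 columns.
#'
#' @param path file path.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs named `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write contigs as BED6
#'
#' Name column is `profile:gene1;gene2;...`; score is 0 and strand `.`
#' (merged contigs can combine genes from both strands; counting is
#' canonical, so strand is immaterial).
#'
#' @param contig_set a `contig_set`.
#' @param path file path.
#' @export
write_contigs_bed <- function(contig_set, path) {
  gr <- contig_set$contigs
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = paste0(S4Vectors::mcols(gr)$profile, ":",
                  gsub(",", ";", S4Vectors::mcols(gr)$source_genes)),
    score = 0L,
    strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write oligomer records
#' @param records `oligomer_records` data.frame.
#' @param path file path.
#' @export
write_oligomer_records <- function(records, path) {
  df <- as.data.frame(records)
  df$fold <- ifelse(is.finite(df$fold), formatC(df$fold, digits = 6, format = "g"),
                    "Inf")
  write_tsv(df, path)
}

#' Serialize / restore an LDA model as JSON
#'
#' Versioned plain-text document holding the PCA center and basis, class
#' means, inverse pooled covariance, priors, tau and the feature list.
#'
#' @param model an `lda_model`.
#' @param path file path.
#' @export
write_lda_model <- function(model, path) {
  doc <- list(
    format = "xprio_lda_model", version = 1L,
    center = unname(model$center),
    rotation = model$rotation,
    means = model$means,
    Sinv = model$Sinv,
    priors = as.list(model$priors),
    tau = model$tau,
    variance_kept = model$variance_kept,
    q = model$q,
    features = model$features
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "xprio_lda_model"))
    xp_stop(path, " is not an xprio LDA model document")
  lev <- names(doc$priors)
  m <- list(center = doc$center,
            rotation = matrix(unlist(doc$rotation), ncol = doc$q),
            means = matrix(unlist(doc$means), nrow = length(lev),
                           dimnames = list(lev, NULL)),
            Sinv = matrix(unlist(doc$Sinv), ncol = doc$q),
            priors = unlist(doc$priors),
            tau = doc$tau, variance_kept = doc$variance_kept,
            q = doc$q, features = doc$features)
  class(m) <- "lda_model"
  m
}

#' Write a simulated dataset to a directory
#'
#' Writes `genome.fa`, `genes.tsv`, `tss_clusters.tsv`, `terms.tsv`,
#' `known.txt` and `ground_truth.json`.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_tag_clusters(sim$tss_clusters, file.path(dir, "tss_clusters.tsv"))
  write_term_lists(sim$terms, file.path(dir, "terms.tsv"))
  writeLines(sim$known, file.path(dir, "known.txt"))
  jsonlite::write_json(list(
    true_tss = as.list(sim$truth$true_tss),
    plants = sim$truth$plants,
    seed = sim$config$seed
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
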