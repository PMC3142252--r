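## Genome model: representative TSS selection from tag clusters, and
## construction of class-labeled upstream "contigs" pooled into "subgenomes".
##
## All coordinates are 0-based half-open (BED convention). A gene's coding
## start is its 5' body edge: `start` on the plus strand, `end - 1` on the
## minus strand. The representative TSS of a tag cluster is the cluster's 5'
## edge in transcript orientation.

#' Validate a gene table
#'
#' The gene table is the pipeline's central input: one row per gene with
#' columns `id`, `chrom`, `start`, `end`, `strand` (+/-), `class`
#' (`disease`/`non_disease`), `stratum` (free label, e.g. XAR/XCR) and
#' optional `tss` (0-based coordinate, NA when unknown).
#'
#' @param df data.frame to validate.
#' @return the validated data.frame (with a `tss` column added if missing).
#' @export
validate_gene_table <- function(df) {
  need <- c("id", "chrom", "start", "end", "strand", "class", "stratum")
  miss <- setdiff(need, names(df))
  if (length(miss)) xp_stop("gene table missing column(s): ",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    xp_stop("duplicate gene id(s): ",
            paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad)) xp_stop("end <= start at line(s): ",
                           paste(bad, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) xp_stop("unknown strand at line(s): ",
                           paste(bad, collapse = ", "))
  bad <- which(!df$class %in% c("disease", "non_disease"))
  if (length(bad)) xp_stop("class must be disease/non_disease at line(s): ",
                           paste(bad, collapse = ", "))
  if (is.null(df$tss)) df$tss <- NA_integer_
  ## a known TSS must lie 5' of the coding start on the gene's strand
  has <- !is.na(df$tss)
  bad <- which(has & ((df$strand == "+" & df$tss >= df$start) |
                      (df$strand == "-" & df$tss <= df$end - 1)))
  if (length(bad)) xp_stop("tss not 5' of coding start at line(s): ",
                           paste(bad, collapse = ", "))
  df
}

#' Coding start coordinate of each gene
#' @param genes validated gene table.
#' @return integer vector (0-based).
#' @export
coding_start <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Select the representative TSS for one gene
#'
#' Applies, in order: keep tag clusters on the gene's strand; keep clusters
#' entirely 5' of the coding start; drop single-tag clusters; optionally drop
#' clusters not overlapping any supporting cDNA/EST 5'-end interval; then pick
#' the cluster with the highest tag count, breaking ties by proximity of the
#' cluster's 5' edge to the coding start. Returns `NA` when no cluster
#' survives (a valid outcome).
#'
#' @param gene one-row gene table (or list with the same fields).
#' @param clusters data.frame of tag clusters with columns `chrom`, `start`,
#'   `end`, `strand`, `tag_count`.
#' @param evidence_intervals optional data.frame with `chrom`, `start`, `end`;
#'   clusters must overlap at least one interval to survive.
#' @param max_distance maximal distance (bases) between the cluster's 5' edge
#'   and the coding start for the cluster to be considered the gene's own.
#'   On a multi-gene chromosome an unbounded 5'-upstream rule would let a
#'   gene claim any other gene's far-upstream clusters; 5 kb reflects how
#'   close 5'-capture clusters sit to their gene.
#' @return a single 0-based coordinate, or `NA_integer_`.
#' @export
select_representative_tss <- function(gene, clusters, evidence_intervals = NULL,
                                      max_distance = 5000L) {
  cs <- if (gene$strand == "+") gene$start else gene$end - 1L
  cl <- clusters[clusters$chrom == gene$chrom & clusters$strand == gene$strand, ,
                 drop = FALSE]
  cl <- if (gene$strand == "+") cl[cl$end <= cs & cl$start >= cs - max_distance, ,
                                   drop = FALSE]
        else cl[cl$start > cs & cl$end - 1L <= cs + max_distance, , drop = FALSE]
  cl <- cl[cl$tag_count >= 2L, , drop = FALSE]
  if (!is.null(evidence_intervals) && nrow(cl)) {
    ev <- evidence_intervals[evidence_intervals$chrom == gene$chrom, , drop = FALSE]
    keep <- vapply(seq_len(nrow(cl)), function(i) {
      any(cl$start[i] < ev$end & ev$start < cl$end[i])
    }, logical(1))
    cl <- cl[keep, , drop = FALSE]
  }
  if (!nrow(cl)) return(NA_integer_)
  ## representative position: 5' edge of the cluster in transcript orientation
  pos <- if (gene$strand == "+") cl$start else cl$end - 1L
  ord <- order(-cl$tag_count, abs(pos - cs), pos)
  as.integer(pos[ord[1L]])
}

#' Fill the `tss` column of a gene table from tag clusters
#'
#' @param genes validated gene table.
#' @param clusters tag-cluster data.frame (see [select_representative_tss()]).
#' @param evidence_intervals optional supporting intervals.
#' @param max_distance see [select_representative_tss()].
#' @return gene table with `tss` populated (NA where no cluster survives).
#' @export
assign_tss <- function(genes, clusters, evidence_intervals = NULL,
                       max_distance = 5000L) {
  genes <- validate_gene_table(genes)
  genes$tss <- vapply(seq_len(nrow(genes)), function(i) {
    select_representative_tss(genes[i, ], clusters, evidence_intervals,
                              max_distance)
  }, integer(1))
  n_missing <- sum(is.na(genes$tss))
  if (n_missing) xp_log(n_missing, " gene(s) without a representative TSS")
  genes
}

## internal: widest available gene extent, for the opposite-profile body rule
gene_body_ranges <- function(genes) {
  lo <- pmin(genes$start, ifelse(is.na(genes$tss), genes$start, genes$tss))
  hi <- pmax(genes$end, ifelse(is.na(genes$tss), genes$end, genes$tss + 1L))
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(lo + 1L, hi),
                         profile = genes$class)
}

#' Build class-labeled upstream contigs
#'
#' Each gene with a TSS yields the interval of `distance_kb` kilobases
#' immediately 5' of its TSS (both sides of the TSS when
#' `include_downstream = TRUE`), clamped to chromosome bounds. Then,
#' iteratively: (a) overlapping contigs sharing a profile are merged; (b) both
#' members of any overlapping opposite-profile contig pair are discarded;
#' (c) a contig overlapping the body of any opposite-profile gene is
#' discarded. "Overlap" means at least one shared base.
#'
#' @param genes validated gene table with `tss` populated.
#' @param distance_kb upstream distance in kilobases (> 0).
#' @param include_downstream extend the same distance 3' of the TSS as well.
#' @param chrom_lengths named integer vector of chromosome lengths used for
#'   clamping (optional; upstream of coordinate 0 is always clamped).
#' @return list of class `contig_set`: `contigs` (a GRanges with metadata
#'   columns `profile` and `source_genes`, comma-separated) and `rejects`
#'   (data.frame `gene`, `reason`).
#' @export
build_contigs <- function(genes, distance_kb, include_downstream = FALSE,
                          chrom_lengths = NULL) {
  genes <- validate_gene_table(genes)
  if (!is.numeric(distance_kb) || distance_kb <= 0)
    xp_stop("distance_kb must be > 0")
  d <- as.integer(round(distance_kb * 1000))

  rejects <- data.frame(gene = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  no_tss <- is.na(genes$tss)
  if (any(no_tss))
    rejects <- rbind(rejects, data.frame(gene = genes$id[no_tss],
                                         reason = "no_tss"))
  g <- genes[!no_tss, , drop = FALSE]
  if (!nrow(g))
    return(structure(list(contigs = GenomicRanges::GRanges(),
                          rejects = rejects), class = "contig_set"))

  ## raw interval per gene, 0-based half-open [lo, hi)
  plus <- g$strand == "+"
  lo <- ifelse(plus, g$tss - d, g$tss + 1L)
  hi <- ifelse(plus, g$tss, g$tss + 1L + d)
  if (include_downstream) {
    lo <- ifelse(plus, g$tss - d, g$tss + 1L - d)
    hi <- ifelse(plus, g$tss + d, g$tss + 1L + d)
  }
  lo <- pmax(lo, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[as.character(g$chrom)])
    hi <- pmin(hi, ifelse(is.na(lim), hi, lim))
  }
  keep <- hi > lo
  if (any(!keep))
    rejects <- rbind(rejects, data.frame(gene = g$id[!keep],
                                         reason = "empty_interval"))
  g <- g[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]

  raw <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(lo + 1L, hi))
  ## (a) merge same-profile overlaps, tracking source genes
  merged <- list()
  for (prof in unique(g$class)) {
    sel <- g$class == prof
    red <- GenomicRanges::reduce(raw[sel], with.revmap = TRUE)
    ids <- g$id[sel]
    src <- vapply(S4Vectors::mcols(red)$revmap, function(ix)
      paste(sort(ids[ix]), collapse = ","), character(1))
    S4Vectors::mcols(red) <- NULL
    S4Vectors::mcols(red)$profile <- prof
    S4Vectors::mcols(red)$source_genes <- src
    merged[[prof]] <- red
  }
  contigs <- do.call(c, unname(merged))

  ## (b) discard both members of every overlapping opposite-profile pair
  prof <- S4Vectors::mcols(contigs)$profile
  hits <- GenomicRanges::findOverlaps(contigs, contigs)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  opp <- prof[qh] != prof[sh]
  drop_b <- unique(c(qh[opp], sh[opp]))
  if (length(drop_b)) {
    for (i in drop_b)
      rejects <- rbind(rejects, data.frame(
        gene = strsplit(S4Vectors::mcols(contigs)$source_genes[i], ",")[[1]],
        reason = "opposite_profile_contig_overlap"))
    contigs <- contigs[-drop_b]
  }

  ## (c) discard contigs overlapping an opposite-profile gene body
  if (length(contigs)) {
    bodies <- gene_body_ranges(genes)
    hits <- GenomicRanges::findOverlaps(contigs, bodies)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    opp <- S4Vectors::mcols(contigs)$profile[qh] != S4Vectors::mcols(bodies)$profile[sh]
    drop_c <- unique(qh[opp])
    if (length(drop_c)) {
      for (i in drop_c)
        rejects <- rbind(rejects, data.frame(
          gene = strsplit(S4Vectors::mcols(contigs)$source_genes[i], ",")[[1]],
          reason = "opposite_profile_gene_body_overlap"))
      contigs <- contigs[-drop_c]
    }
  }

  contigs <- GenomicRanges::sort(contigs)
  structure(list(contigs = contigs, rejects = rejects), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contig(s), %d rejected gene record(s)\n",
              length(x$contigs), nrow(x$rejects)))
  invisible(x)
}

#' Compile a subgenome from contigs
#'
#' Extracts contig sequences (reference strand, no reverse-complementing:
#' downstream k-mer counting is canonical, so orientation is immaterial) and
#' records the total length.
#'
#' @param contigs GRanges of contigs (all of one profile), or a `contig_set`
#'   whose contigs will be filtered by `profile`.
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @param label list with `class`, `stratum`, `distance_kb` describing the
#'   cell this subgenome belongs to.
#' @param profile when `contigs` is a `contig_set`, which profile to keep.
#' @return object of class `subgenome`: `label`, `contigs`, `sequences`
#'   (DNAStringSet named by coordinates), `total_length`.
#' @export
compile_subgenome <- function(contigs, genome, label = list(),
                              profile = NULL) {
  if (inherits(contigs, "contig_set")) {
    gr <- contigs$contigs
    if (!is.null(profile)) gr <- gr[S4Vectors::mcols(gr)$profile == profile]
  } else gr <- contigs
  if (length(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    bad <- !(chrom %in% names(genome))
    if (any(bad)) xp_stop("contig on unknown chromosome: ", chrom[which(bad)[1]])
    over <- GenomicRanges::end(gr) >
      Biostrings::width(genome)[match(chrom, names(genome))]
    if (any(over))
      xp_stop("contig out of sequence range: ",
              paste0(chrom[which(over)[1]], ":",
                     GenomicRanges::start(gr)[which(over)[1]] - 1L, "-",
                     GenomicRanges::end(gr)[which(over)[1]]))
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
      as.character(Biostrings::subseq(genome[[chrom[i]]],
                                      GenomicRanges::start(gr)[i],
                                      GenomicRanges::end(gr)[i]))
    }, character(1)))
    names(seqs) <- paste0(chrom, ":", GenomicRanges::start(gr) - 1L, "-",
                          GenomicRanges::end(gr))
  } else seqs <- Biostrings::DNAStringSet()
  structure(list(label = label, contigs = gr, sequences = seqs,
                 total_length = sum(Biostrings::width(seqs))),
            class = "subgenome")
}

#' @export
print.subgenome <- function(x, ...) {
  lab <- paste(unlist(x$label), collapse = "/")
  cat(sprintf("<subgenome> %s: %d contig(s), %d bp\n",
              if (nzchar(lab)) lab else "(unlabeled)",
              length(x$contigs), x$total_length))
  invisible(x)
}

#' Build the disease and non-disease subgenomes for one stratum and distance
#'
#' Convenience wrapper: subsets the gene table to one stratum (strata are
#' analyzed separately throughout), builds contigs at the given distance and
#' compiles one subgenome per profile.
#'
#' @param genes validated gene table with `tss` populated.
#' @param genome named `DNAStringSet`.
#' @param distance_kb upstream distance in kilobases.
#' @param stratum stratum label to subset on, or `NULL` for all genes.
#' @param include_downstream see [build_contigs()].
#' @return list with `disease` and `non_disease` subgenomes, plus the
#'   underlying `contig_set`.
#' @export
build_subgenomes <- function(genes, genome, distance_kb, stratum = NULL,
                             include_downstream = FALSE) {
  genes <- validate_gene_table(genes)
  if (!is.null(stratum)) genes <- genes[genes$stratum == stratum, , drop = FALSE]
  cl <- stats::setNames(Biostrings::width(genome), names(genome))
  cs <- build_contigs(genes, distance_kb, include_downstream, chrom_lengths = cl)
  mk <- function(prof) compile_subgenome(
    cs, genome, profile = prof,
    label = list(class = prof, stratum = if (is.null(stratum)) "all" else stratum,
                 distance_kb = distance_kb))
  list(disease = mk("disease"), non_disease = mk("non_disease"),
       contig_set = cs)
}
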