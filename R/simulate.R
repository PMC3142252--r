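## Synthetic datasets with known ground truth: a random chromosome at a set
## GC content, gene models on alternating strands with guaranteed intergenic
## spacing, TSS tag clusters (a high-tag representative plus decoys that the
## selection rules must reject), class-specific motifs planted by overwriting
## upstream sequence, and annotation-term lists with configurable overlap
## with the disease gene set.

#' Simulation configuration
#'
#' Defaults describe a desk-scale chromosome: GC 0.40 (the human X is
#' GC-poor), 2 kb gene bodies, a 500 bp gap between the TSS and the coding
#' start, and at least 12 kb between neighboring gene bodies so that 10 kb
#' upstream contigs sometimes — but not always — collide and exercise the
#' merge/discard rules.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @param chrom_length chromosome length in bases.
#' @param gc_content GC fraction in (0, 1).
#' @param n_disease,n_non_disease class sizes (>= 2 each).
#' @param strata_fractions named numeric vector of stratum fractions summing
#'   to 1; strata are laid out as contiguous blocks along the chromosome
#'   (mirroring evolutionary strata).
#' @param planted_motifs list of `list(sequence=, class=, rate=)`: each motif
#'   is planted Poisson(`rate`) times per target-class gene, by overwriting
#'   sequence (coordinates stay stable) at non-overlapping positions inside
#'   the gene's upstream planting window.
#' @param term_config list `n_terms`, `p_match_disease`, `p_match_background`:
#'   term membership is Bernoulli per gene.
#' @param tss_jitter maximal absolute displacement of the observed tag
#'   cluster from the true TSS, in bases.
#' @param min_intergenic minimal gap between neighboring gene bodies.
#' @param gene_length gene body length.
#' @param tss_offset distance from the TSS to the coding start.
#' @param plant_window_bp width of the upstream window motifs are planted in.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 1e6L,
                       gc_content = 0.40,
                       n_disease = 10L,
                       n_non_disease = 20L,
                       strata_fractions = c(XAR = 0.35, XCR = 0.65),
                       planted_motifs = list(),
                       term_config = list(n_terms = 40L,
                                          p_match_disease = 0.5,
                                          p_match_background = 0.15),
                       tss_jitter = 25L,
                       min_intergenic = 12000L,
                       gene_length = 2000L,
                       tss_offset = 500L,
                       plant_window_bp = 5000L) {
  stopifnot(gc_content > 0, gc_content < 1,
            n_disease >= 2, n_non_disease >= 2,
            abs(sum(strata_fractions) - 1) < 1e-8,
            term_config$p_match_disease >= 0, term_config$p_match_disease <= 1,
            term_config$p_match_background >= 0,
            term_config$p_match_background <= 1)
  for (pm in planted_motifs)
    stopifnot(is.character(pm$sequence), pm$class %in% c("disease", "non_disease"),
              pm$rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Preset configurations
#'
#' `paper_like_XAR` and `paper_like_XCR` reuse the reference class sizes of
#' the two X-chromosome evolutionary strata in large X-linked intellectual
#' disability surveys (25 vs 110 and 56 vs 376 genes) at 1:10 linear scale
#' (10 kb contigs standing in for the 100 kb analysis on a megabase-scale
#' synthetic chromosome), with strong class-specific planted motifs. `null` is a small balanced configuration with no planted signal
#' and equal term-match probabilities, for calibration tests.
#'
#' @param name one of `"paper_like_XAR"`, `"paper_like_XCR"`, `"null"`.
#' @param seed seed stored in the config.
#' @return a `sim_config`.
#' @export
regime_preset <- function(name = c("paper_like_XAR", "paper_like_XCR", "null"),
                          seed = 1L) {
  name <- match.arg(name)
  ## disease motifs at rate 12 per gene each. "Strong" planting must hold per
  ## gene, not merely for the pooled subgenome: pooled-covariance LDA with
  ## empirical priors places its boundary near half the typical disease
  ## count, so the per-gene Poisson draw must sit above that with high
  ## probability (P(Pois(24) <= 12) ~ 0.5%). See the methods vignette.
  motifs <- list(
    list(sequence = "TGCATTAGGCAT", class = "disease", rate = 12),
    list(sequence = "CCGATAACGTTG", class = "disease", rate = 12),
    list(sequence = "AGGTTGACCTAA", class = "non_disease", rate = 1.5)
  )
  switch(name,
    paper_like_XAR = sim_config(
      seed = seed, chrom_length = 4200000L,
      n_disease = 25L, n_non_disease = 110L,
      strata_fractions = c(XAR = 1),
      planted_motifs = motifs,
      min_intergenic = 24000L,
      plant_window_bp = 8000L),
    paper_like_XCR = sim_config(
      seed = seed, chrom_length = 13500000L,
      n_disease = 56L, n_non_disease = 376L,
      strata_fractions = c(XCR = 1),
      planted_motifs = motifs,
      min_intergenic = 24000L,
      plant_window_bp = 8000L),
    null = sim_config(
      seed = seed, chrom_length = 220000L,
      n_disease = 12L, n_non_disease = 12L,
      strata_fractions = c(ALL = 1),
      planted_motifs = list(),
      term_config = list(n_terms = 40L, p_match_disease = 0.2,
                         p_match_background = 0.2),
      min_intergenic = 7000L, gene_length = 800L,
      plant_window_bp = 3000L)
  )
}

#' Simulate a full dataset
#'
#' Generates chromosome sequence, gene table, TSS tag clusters (one
#' representative cluster with >= 2 tags per gene plus single-tag and
#' wrong-strand decoys), planted motifs and annotation-term lists, together
#' with complete ground truth. Deterministic given the config (same seed,
#' byte-identical outputs).
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `genome` (DNAStringSet, chromosome
#'   `chrS`), `genes` (gene table, `tss` NA — the pipeline recovers it),
#'   `tss_clusters`, `terms` (list of [annotation_term()]), `known`
#'   (disease gene ids), `truth` (true TSSs, planted motif positions, term
#'   membership matrix).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))
  n <- cfg$n_disease + cfg$n_non_disease
  edge_pad <- cfg$tss_offset + cfg$tss_jitter + cfg$plant_window_bp + 100L
  slot <- (cfg$chrom_length - 2L * edge_pad) %/% n
  need <- cfg$gene_length + cfg$min_intergenic
  if (slot < need)
    xp_stop("chromosome too short for ", n, " genes: need at least ",
            n * need + 2L * edge_pad, " bases")
  slack2 <- (slot - need) %/% 2L

  ## base sequence at the requested GC
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  bases <- sample(names(p), cfg$chrom_length, replace = TRUE, prob = p)

  ## gene placement: evenly spaced slots, offsets bounded so that spacing
  ## can never drop below min_intergenic; strands alternate
  offs <- if (slack2 > 0) sample.int(slack2 + 1L, n, replace = TRUE) - 1L
          else integer(n)
  starts <- edge_pad + (seq_len(n) - 1L) * slot + offs
  ends <- starts + cfg$gene_length
  strand <- rep(c("+", "-"), length.out = n)
  ids <- sprintf("G%03d", seq_len(n))
  cls <- rep("non_disease", n)
  cls[sample.int(n, cfg$n_disease)] <- "disease"
  block <- rep(names(cfg$strata_fractions),
               times = diff(round(c(0, cumsum(cfg$strata_fractions)) * n)))
  stratum <- block[seq_len(n)]

  true_tss <- ifelse(strand == "+", starts - cfg$tss_offset,
                     ends - 1L + cfg$tss_offset)

  ## plant motifs by overwriting upstream sequence on non-overlapping slots
  plants <- list()
  if (length(cfg$planted_motifs)) {
    maxlen <- max(vapply(cfg$planted_motifs, function(m) nchar(m$sequence),
                         integer(1)))
    for (gi in seq_len(n)) {
      w0 <- if (strand[gi] == "+") true_tss[gi] - cfg$plant_window_bp
            else true_tss[gi] + 1L
      w1 <- w0 + cfg$plant_window_bp   # [w0, w1) 0-based
      slots <- seq(w0, w1 - maxlen, by = maxlen)
      pool <- sample(slots)
      for (m in cfg$planted_motifs) {
        if (m$class != cls[gi]) next
        npos <- min(stats::rpois(1L, m$rate), length(pool))
        if (npos == 0L) next
        at <- pool[seq_len(npos)]
        pool <- pool[-seq_len(npos)]
        for (a in at) {
          mb <- strsplit(m$sequence, "")[[1]]
          bases[(a + 1L):(a + length(mb))] <- mb
          plants[[length(plants) + 1L]] <-
            data.frame(motif = m$sequence, gene = ids[gi], position = a)
        }
      }
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants)
            else data.frame(motif = character(0), gene = character(0),
                            position = integer(0))

  ## TSS tag clusters: representative (tags 10..30, jittered), a weaker
  ## competitor (tags 2..9), a single-tag decoy, and a wrong-strand decoy
  mk_cluster <- function(chrom, pos5, strand, width, tags) {
    if (strand == "+") data.frame(chrom = chrom, start = pos5,
                                  end = pos5 + width, strand = strand,
                                  tag_count = tags)
    else data.frame(chrom = chrom, start = pos5 - width + 1L,
                    end = pos5 + 1L, strand = strand, tag_count = tags)
  }
  cl <- list()
  for (gi in seq_len(n)) {
    jit <- sample(seq(-cfg$tss_jitter, cfg$tss_jitter), 1L)
    obs <- true_tss[gi] + if (strand[gi] == "+") -abs(jit) else abs(jit)
    cl[[length(cl) + 1L]] <- mk_cluster("chrS", obs, strand[gi],
                                        sample(5:20, 1L), sample(10:30, 1L))
    far <- if (strand[gi] == "+") obs - sample(500:1500, 1L)
           else obs + sample(500:1500, 1L)
    cl[[length(cl) + 1L]] <- mk_cluster("chrS", far, strand[gi],
                                        sample(5:20, 1L), sample(2:9, 1L))
    far1 <- if (strand[gi] == "+") obs - sample(1600:2500, 1L)
            else obs + sample(1600:2500, 1L)
    cl[[length(cl) + 1L]] <- mk_cluster("chrS", far1, strand[gi],
                                        sample(5:20, 1L), 1L)
    cl[[length(cl) + 1L]] <- mk_cluster("chrS", obs - 50L,
                                        if (strand[gi] == "+") "-" else "+",
                                        sample(5:20, 1L), sample(2:9, 1L))
  }
  tss_clusters <- do.call(rbind, cl)

  ## annotation terms: Bernoulli membership per gene
  tc <- cfg$term_config
  cats <- rep(TERM_CATEGORIES, length.out = tc$n_terms)
  membership <- matrix(FALSE, n, tc$n_terms,
                       dimnames = list(ids, sprintf("T%02d", seq_len(tc$n_terms))))
  pr_match <- ifelse(cls == "disease", tc$p_match_disease, tc$p_match_background)
  for (j in seq_len(tc$n_terms))
    membership[, j] <- stats::runif(n) < pr_match
  terms <- lapply(seq_len(tc$n_terms), function(j)
    annotation_term(colnames(membership)[j], cats[j], ids[membership[, j]]))

  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrS"

  genes <- data.frame(id = ids, chrom = "chrS", start = starts, end = ends,
                      strand = strand, class = cls, stratum = stratum,
                      tss = NA_integer_, stringsAsFactors = FALSE)

  structure(list(
    config = cfg,
    genome = genome,
    genes = genes,
    tss_clusters = tss_clusters,
    terms = terms,
    known = ids[cls == "disease"],
    truth = list(true_tss = stats::setNames(true_tss, ids),
                 plants = plants, membership = membership)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d bp chromosome; %d genes (%d disease); %d planted motif occurrence(s); %d terms\n",
              sum(Biostrings::width(x$genome)), nrow(x$genes), length(x$known),
              nrow(x$truth$plants), length(x$terms)))
  invisible(x)
}
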