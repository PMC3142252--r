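## Contig construction rules on hand-built interval fixtures, TSS selection,
## and subgenome compilation.

clusters_df <- function(...) {
  do.call(rbind, lapply(list(...), function(r)
    data.frame(chrom = r$chrom %||% "c1", start = r$start, end = r$end,
               strand = r$strand %||% "+", tag_count = r$tags)))
}

test_that("representative TSS selection applies the rules in order", {
  gene <- list(id = "g", chrom = "c1", strand = "+", start = 10000L,
               end = 12000L)

  ## highest tag count wins
  cl <- clusters_df(list(start = 9000, end = 9020, tags = 5),
                    list(start = 8000, end = 8020, tags = 9))
  expect_equal(select_representative_tss(gene, cl), 8000L)

  ## tie on tags: closest to the coding start wins
  cl <- clusters_df(list(start = 9700, end = 9720, tags = 5),
                    list(start = 8800, end = 8820, tags = 5))
  expect_equal(select_representative_tss(gene, cl), 9700L)

  ## single-tag clusters are excluded -> none survives
  cl <- clusters_df(list(start = 9000, end = 9020, tags = 1))
  expect_true(is.na(select_representative_tss(gene, cl)))

  ## wrong strand and downstream clusters are filtered out
  cl <- clusters_df(list(start = 9000, end = 9020, tags = 5, strand = "-"),
                    list(start = 10500, end = 10520, tags = 9))
  expect_true(is.na(select_representative_tss(gene, cl)))

  ## evidence intervals: clusters without cDNA/EST support are dropped
  cl <- clusters_df(list(start = 9000, end = 9020, tags = 9),
                    list(start = 9500, end = 9520, tags = 5))
  ev <- data.frame(chrom = "c1", start = 9490, end = 9530)
  expect_equal(select_representative_tss(gene, cl, ev), 9500L)

  ## minus-strand gene: clusters must lie 3' of end-1 in genome coordinates
  gm <- list(id = "g", chrom = "c1", strand = "-", start = 10000L,
             end = 12000L)
  cl <- clusters_df(list(start = 12500, end = 12520, tags = 4, strand = "-"))
  expect_equal(select_representative_tss(gm, cl), 12519L)
})

test_that("same-profile overlapping contigs merge into one larger contig", {
  ## two + strand genes with TSSs 6 kb apart, 10 kb distance -> 16 kb merge
  g <- toy_genes(list(id = "a", start = 30000, end = 32000, tss = 29500),
                 list(id = "b", start = 36000, end = 38000, tss = 35500))
  cs <- build_contigs(g, 10)
  expect_equal(length(cs$contigs), 1L)
  expect_equal(GenomicRanges::width(cs$contigs), 16000L)
  expect_equal(GenomicRanges::start(cs$contigs) - 1L, 19500L)
  expect_equal(S4Vectors::mcols(cs$contigs)$source_genes, "a,b")
})

test_that("opposite-profile contig overlap discards both contigs", {
  g <- toy_genes(list(id = "a", start = 30000, end = 32000, tss = 29500,
                      class = "disease"),
                 list(id = "b", start = 36000, end = 38000, tss = 35500,
                      class = "non_disease"))
  cs <- build_contigs(g, 10)
  expect_equal(length(cs$contigs), 0L)
  expect_setequal(cs$rejects$gene, c("a", "b"))
  expect_true(all(cs$rejects$reason == "opposite_profile_contig_overlap"))
})

test_that("a contig overlapping an opposite-profile gene body is discarded", {
  ## disease contig upstream of gene a runs into non-disease gene c's body;
  ## c itself has no TSS so only rule (c) can fire
  g <- toy_genes(list(id = "a", start = 30000, end = 32000, tss = 29500,
                      class = "disease"),
                 list(id = "c", start = 21000, end = 24000,
                      class = "non_disease"))
  cs <- build_contigs(g, 10)
  expect_equal(length(cs$contigs), 0L)
  expect_true("opposite_profile_gene_body_overlap" %in% cs$rejects$reason)
  expect_true("no_tss" %in% cs$rejects$reason)
})

test_that("contigs are clamped at chromosome bounds", {
  g <- toy_genes(list(id = "a", start = 3500, end = 5500, tss = 3000))
  cs <- build_contigs(g, 10)
  expect_equal(GenomicRanges::start(cs$contigs) - 1L, 0L)
  expect_equal(GenomicRanges::end(cs$contigs), 3000L)

  ## right clamp via chrom_lengths, minus strand
  gm <- toy_genes(list(id = "m", start = 1000, end = 3000, strand = "-",
                       tss = 3500))
  cs2 <- build_contigs(gm, 10, chrom_lengths = c(c1 = 6000L))
  expect_equal(GenomicRanges::end(cs2$contigs), 6000L)
})

test_that("include_downstream extends the interval on both sides of the TSS", {
  g <- toy_genes(list(id = "a", start = 50000, end = 52000, tss = 49500))
  cs <- build_contigs(g, 5, include_downstream = TRUE)
  expect_equal(GenomicRanges::width(cs$contigs), 10000L)
  expect_equal(GenomicRanges::start(cs$contigs) - 1L, 44500L)
})

test_that("merge/discard is order-independent and never leaves conflicts", {
  set.seed(99)
  for (rep in 1:8) {
    n <- 14
    starts <- sort(sample(seq(20000, 400000, by = 100), n))
    g <- do.call(toy_genes, lapply(seq_len(n), function(i)
      list(id = sprintf("g%02d", i), start = starts[i],
           end = starts[i] + 1500,
           strand = sample(c("+", "-"), 1),
           class = sample(c("disease", "non_disease"), 1),
           tss = if (runif(1) < 0.9) 0L else NA_integer_)))
    g$tss <- ifelse(is.na(g$tss), NA_integer_,
                    ifelse(g$strand == "+", g$start - 400L, g$end + 399L))
    cs1 <- build_contigs(g, 8)
    cs2 <- build_contigs(g[sample(n), , drop = FALSE], 8)
    expect_equal(as.data.frame(cs1$contigs), as.data.frame(cs2$contigs))

    ## no surviving contig overlaps an opposite-profile contig or gene body
    gr <- cs1$contigs
    if (length(gr) > 1) {
      prof <- S4Vectors::mcols(gr)$profile
      hits <- GenomicRanges::findOverlaps(gr, gr)
      opp <- prof[S4Vectors::queryHits(hits)] != prof[S4Vectors::subjectHits(hits)]
      expect_false(any(opp))
    }
    if (length(gr)) {
      bodies <- GenomicRanges::GRanges(g$chrom,
                                       IRanges::IRanges(g$start + 1L, g$end))
      hits <- GenomicRanges::findOverlaps(gr, bodies)
      opp <- S4Vectors::mcols(gr)$profile[S4Vectors::queryHits(hits)] !=
        g$class[S4Vectors::subjectHits(hits)]
      expect_false(any(opp))
      ## total never exceeds the raw per-gene allotment
      expect_lte(sum(GenomicRanges::width(gr)), sum(!is.na(g$tss)) * 8000)
    }
  }
})

test_that("an isolated gene yields exactly its full-length contig", {
  g <- toy_genes(list(id = "a", start = 500000, end = 502000, tss = 499500),
                 list(id = "b", start = 900000, end = 902000, tss = 899500,
                      class = "non_disease"))
  cs <- build_contigs(g, 50)
  expect_equal(length(cs$contigs), 2L)
  expect_true(all(GenomicRanges::width(cs$contigs) == 50000L))
})

test_that("subgenome compilation extracts the planted slice and totals", {
  set.seed(5)
  chrom <- rand_dna(30000)
  genome <- Biostrings::DNAStringSet(chrom); names(genome) <- "c1"
  g <- toy_genes(list(id = "a", start = 12000, end = 14000, tss = 11500),
                 list(id = "b", start = 25000, end = 27000, tss = 24500))
  cs <- build_contigs(g, 2)
  sg <- compile_subgenome(cs, genome, profile = "disease",
                          label = list(class = "disease", stratum = "S1",
                                       distance_kb = 2))
  expect_equal(sg$total_length, 4000L)
  ## round trip against the generator's ground truth slice
  expect_equal(as.character(sg$sequences[[1]]), substr(chrom, 9501, 11500))
  expect_equal(as.character(sg$sequences[[2]]), substr(chrom, 22501, 24500))

  ## 3 kb + 5 kb same-label contigs -> total 8 kb
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 10001),
                                                      c(3000, 15000)))
  S4Vectors::mcols(gr)$profile <- "disease"
  S4Vectors::mcols(gr)$source_genes <- c("x", "y")
  expect_equal(compile_subgenome(gr, genome)$total_length, 8000L)

  ## out-of-range contig errors with its coordinates
  bad <- GenomicRanges::GRanges("c1", IRanges::IRanges(29000, 31000))
  S4Vectors::mcols(bad)$profile <- "disease"
  S4Vectors::mcols(bad)$source_genes <- "x"
  expect_error(compile_subgenome(bad, genome), "out of sequence range")
})

test_that("gene table validation reports offending rows", {
  g <- toy_genes(list(id = "a", start = 100, end = 50))
  expect_error(validate_gene_table(g), "end <= start")
  g <- toy_genes(list(id = "a", start = 100, end = 500))
  g$strand <- "*"
  expect_error(validate_gene_table(g), "unknown strand")
  g <- toy_genes(list(id = "a", start = 100, end = 500, tss = 250))
  expect_error(validate_gene_table(g), "not 5'")
})
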