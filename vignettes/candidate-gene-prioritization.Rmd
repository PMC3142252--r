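---
title: "Candidate gene prioritization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate gene prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`xprio` implements a two-pronged prioritization of disease candidate genes on
a chromosome, of the kind used for heterogeneous X-linked disorders where a
subset of causative genes is already known. The two prongs are deliberately
orthogonal: one uses curated functional annotation, the other only genomic
sequence upstream of transcription start sites (TSSs). This vignette explains
the models and procedures, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the method description left the design open.

## 1. Annotation route: the binary evaluation grid

Curated annotation terms (grouped into four categories: anatomical site,
biological process, phenotype, animal-model homology) each carry the list of
genes annotated with that term. The *binary evaluation grid* is the gene ×
term 0/1 membership matrix; a gene's score is its row sum and genes are
ranked by descending score. All terms weigh equally; no category takes
precedence. The package reports per-category match counts alongside the
total, but they do not enter the score.

Two quantities summarize how well the ranking concentrates a set of *known*
disease genes:

* `enrichment_summary()` — at a score threshold \(t\), the fraction of known
  genes among genes scoring \(\ge t\), the corresponding fraction in the whole
  universe, and their ratio (*fold*). With \(t = 0\) the fold is exactly 1.
* `coverage_curve()` — per score level, the cumulative fraction of known
  genes at or above the level and the fraction of genes at exactly that level
  that are known (the two axes of the classic coverage figure).

The overlap between two gene sets of sizes \(m\) and \(n\) in a universe of
\(N\) genes is tested with the hypergeometric upper tail.
`hypergeometric_overlap()` defaults to the inclusive tail \(P(X \ge k)\), the
standard over-representation convention. The strict tail \(P(X > k)\) is
available via `strict = TRUE`; the two differ by the point mass at \(k\), and
analyses in the literature are not always explicit about which they use, so both
are first-class and the choice is printed in the documentation rather than
hidden.

Tie-breaking in ranks is a stable sort with ties broken lexicographically by
gene identifier; equal scores therefore receive consecutive ranks and the
ranking is reproducible across platforms. Known genes absent from the grid
(curated lists and gene universes rarely come from the same source) are
dropped from coverage computations with a warning rather than an error.

## 2. Sequence route: subgenomes of upstream contigs

### Representative TSS selection

TSS evidence arrives as strand-specific tag clusters (5'-capture data) with
tag counts. For each gene the representative TSS is chosen by, in order:

1. keep clusters on the gene's strand;
2. keep clusters entirely 5' of the coding start;
3. drop single-tag clusters (unreliable singletons);
4. optionally, drop clusters not overlapping any supporting cDNA/EST 5'-end
   interval;
5. pick the highest tag count; ties go to the cluster closest to the coding
   start.

Absence of a surviving cluster is a valid outcome: the gene is excluded from
the sequence route and reported, not errored. One parameter here is ours
rather than inherited: `max_distance` (default 5 kb) bounds how far 5' of
the coding start a cluster may sit and still be claimed by the gene. On a
multi-gene chromosome an unbounded "anywhere 5'" rule lets a gene claim
another gene's clusters tens of kilobases away — with many genes per
chromosome the highest-count cluster upstream is almost surely someone
else's. Five kilobases reflects how close 5'-capture clusters sit to their
genes; the parameter is exposed for unusual geometries.

The representative coordinate is the cluster's 5' edge in transcript
orientation.

### Contigs and subgenomes

Each gene with a TSS contributes the interval `distance_kb` immediately 5'
of its TSS ("contig"), clamped at chromosome bounds; distances of 5, 10, 50
and 100 kb are conventional. Three rules then resolve collisions:

(a) overlapping contigs of the same profile (disease/non-disease) merge into
one larger contig; (b) overlapping contigs of *opposite* profiles are both
discarded; (c) a contig overlapping the gene body of any opposite-profile
gene is discarded. "Overlap" is one shared base. Rules run in the order
(a), (b), (c) on post-merge contigs; a merged multi-gene contig that
conflicts is discarded whole and all member genes are reported. The rules
are order-independent in the input gene list (property-tested), and the
surviving contig set provably contains no opposite-profile conflicts.

Contig sequences are extracted from the reference strand without
reverse-complementing minus-strand genes: all downstream counting is
canonical (a k-mer pools with its reverse complement), so orientation is
immaterial. Coordinates are 0-based half-open throughout, with BED as the
interchange format. An `include_downstream` flag widens the interval to both
sides of the TSS (a variant worth checking and usually dropped when it adds nothing);
it is off by default.

A *subgenome* is the pooled contig set for one (profile, stratum, distance)
cell. Strata (e.g. evolutionarily young vs ancestral chromosome regions) are
always analyzed separately.

### Oligomer screening

`count_oligomers()` slides a window of width *k* within each contig
independently (no window spans a contig boundary), skips windows containing
non-ACGT characters, and pools a word with its reverse complement under the
lexicographically smaller of the two (the *canonical* form). Exact matches
only. Word sizes 8–24 are supported; 12 is the default analysis size — in this setting it is typically the
most productive, smaller words saturating and larger ones going sparse.

An oligomer is *overrepresented* in the focal subgenome when it occurs at
least `min_count` times (default 10) **and** at least `min_fold` times
(default 5) more frequently there than in the other subgenome. Frequencies
are counts per base of subgenome, because subgenomes differ in size and a
raw-count ratio would conflate enrichment with length; `normalize = "count"`
switches to raw counts for sensitivity analysis. An oligomer absent from the
other subgenome has infinite fold and passes the fold criterion.

### The permutation test, and what it does and does not control

The screen's significance check pools both subgenomes, cuts every contig
into non-overlapping 2 kb fragments (the terminal remainder of each contig
is kept — discarding it would bias pseudo-subgenome composition), shuffles
the fragments with a seeded generator, fills a pseudo-focal subgenome until
it first reaches the true focal size, and re-applies both screening criteria.
Over `perm_trials` trials (default 1000), a candidate qualifying in fewer
than `max_perm_hits` trials (default 50, i.e. <5%) is flagged significant.
Size matching is by first-crossing because exact equality is generally
impossible; the empirical proportion is used without continuity correction.

It is important to be clear about what this procedure establishes. For an
oligomer whose apparent enrichment is carried by one or two fragments — a
tandem or interspersed repeat cluster — a random split lands those fragments
in the pseudo-focal subgenome with probability of order one-half, the
candidate re-qualifies frequently, and it is correctly *rejected*. That is
the procedure's real function. What it does **not** do is control the false
discovery rate among screened candidates on exchangeable (no-signal) data:
the permutation p-value is computed only for oligomers that already passed
the count/fold screen on the real labels, and conditioning on that selection
picks exactly the dispersed-noise words that random splits almost never
re-qualify. On label-exchangeable synthetic data essentially *every*
screened candidate is flagged significant (the package's acceptance suite
measures this fraction at ~0.95–1.0 and deliberately keeps the original
calibration assertion red rather than weakening it). A green "significant"
flag therefore means "not explained by a few fragments", not "unlikely under
the null hypothesis of no class difference". Downstream of the screen, the
classifier's cross-validated accuracy — not the permutation flag — is the
evidence that the oligomer set carries class signal.

### Merging

Overlapping oligomers (across distances or sizes) can be merged into longer
ones: greedy single-linkage assembly, merging the longest available
suffix–prefix overlap or containment first (reverse-complement aware), ties
resolved lexicographically, iterated to a fixpoint. The minimum overlap
defaults to half the shortest word, the description of "overlapping" being
otherwise open. Merged products no longer refer to a single exact word, so
their count/fold/permutation fields are set to `NA` rather than fabricated.

## 3. Classification: PCA + LDA with a posterior threshold τ

The feature matrix counts every retained oligomer (canonically, exactly) in
each gene's own contig; all source genes of a merged contig receive that
contig's counts. Genes without a surviving contig are excluded and reported
with a reason (`no_tss` or `contig_discarded`), so exclusion accounting
is always explicit.

Because the number of oligomers \(p\) typically exceeds the number of genes
\(n\), counts are first centered and projected onto principal components
retaining `variance_kept` of the variance (default 0.95), capped at
\(n - 2\) components; a two-class linear discriminant with pooled covariance
and *empirical* class priors is then fit in the reduced space. A singular
pooled covariance falls back to a pseudo-inverse. The tuning parameter τ is
implemented as the posterior decision threshold for the disease class: a
gene is called disease when \(P(\text{disease} \mid x) \ge \tau\). The
method this reconstructs never pins τ down; a threshold interpretation is
consistent with the smooth trade-off between class-wise success rates the
procedure exhibits and with standard ROC tooling, and it is a *documented
choice of this package*, not an inherited definition. Sweeping τ
only re-thresholds fixed leave-one-out posteriors, so `sweep_tau()` computes
the cross-validation once; the selected optimum maximizes balanced accuracy
(optimality being otherwise undefined for this procedure), ties going to
the larger τ.

Leave-one-out cross-validation refits everything — PCA included — inside
each fold. Refitting the PCA per fold is not the only defensible choice,
but refitting is the choice that avoids information leaking from the held-out
gene into the basis. Feature *selection* (oligomer discovery), however, is
performed outside the LOOCV loop by default, as such analyses are usually
run; this makes LOOCV success rates optimistic with respect
to discovery, which users should keep in mind when reading the numbers.

Cross-stratum prediction (`cross_predict()`) applies a trained classifier to
a foreign gene set re-featurized on the model's own oligomer list, with no
retraining — the probe for whether the oligomer sets of different strata
carry interchangeable signal (typically they do not: strata differ in
repeat content and base composition).

One assumption deserves emphasis: LDA pools the class covariances. Motif
count features violate this — the class carrying a motif has Poisson-scale
variance while the other class sits at zero with almost none — so the
decision boundary lands near *half* the typical carrier count rather than
near zero. Genes whose count draw falls toward half the class-typical value
are genuinely ambiguous to this classifier even when the class difference is
obvious by eye. This is visible in the synthetic calibration below and is a
property of the method itself, faithfully reproduced.

`combined_report()` joins the two routes: for every gene above an annotation
score cut-off it reports the score, the sequence-route exclusion reason if
any, the per-distance call (X/NX), whether all available calls agree with
prior knowledge ("correctly classified"), and a candidate flag for genes
*not* previously associated with the disease that are nevertheless called X
at two or more distances — the short-list this kind of combined analysis
exists to produce.

## 4. The synthetic-data generator

`simulate_dataset()` produces a fully specified world: an iid chromosome at
a set GC content (default 0.40 — the human X is GC-poor), gene bodies of
2 kb placed on alternating strands in evenly spaced slots with bounded
random offsets (so a minimum intergenic gap is *guaranteed*, not merely
expected), a TSS 500 bp 5' of each coding start, and per gene: one
representative tag cluster (tags 10–30) jittered up to `tss_jitter` bases 5'
of the true TSS, a weaker competitor cluster (tags 2–9), a single-tag decoy
and a wrong-strand decoy — so the selection rules are exercised on every
dataset by default. Class-specific motifs are planted by *overwriting*
sequence (insertion would shift all downstream coordinates) at
Poisson-distributed counts per gene on non-overlapping slots inside the
upstream planting window. Annotation-term membership is Bernoulli per gene
with separate probabilities for disease and background genes. Everything is
driven by one seed; identical configs give byte-identical outputs.

Presets:

* `null` — 12 vs 12 genes, no planted motifs, equal term probabilities, a
  220 kb chromosome; the calibration world.
* `paper_like_XAR` / `paper_like_XCR` — class sizes of the reference
  X-linked regime (25 vs 110 and 56 vs 376 genes per stratum) at 1:10 linear scale: 10 kb contigs on a 4.2 Mb
  (13.5 Mb) chromosome stand in for the 100 kb analysis, keeping desk-scale
  runtimes. The intergenic gap (24 kb) exceeds twice the contig span, so all
  genes reach the classifier — matching the reference 100 kb regime, where by
  construction every classified gene *had* a clean full-length contig. Two
  disease motifs are planted at rate 12 per gene each (~3 copies/kb of
  window) and one non-disease motif at rate 1.5. The disease rate is set so
  that "strong signal" holds *per gene*: with 24 expected copies,
  \(P(\text{Pois}(24) \le 12) \approx 0.5\%\), so a gene falling into the
  pooled-LDA boundary zone described above is a rare event rather than an
  every-dataset occurrence.

What the generator does *not* emulate: isochore and repeat structure (real
X-chromosome subgenomes are ~97% interspersed elements at the discovered
oligomers — iid background has no repeats at all), realistic TSS cluster
shape, overlapping genes and nested transcripts, and evolutionary strata
beyond contiguous block labels. A green test on this world therefore
establishes the *machinery* (rules, counting, statistics, determinism), not
performance on real genomes.

## 5. Numerical and procedural choices

* Coordinates 0-based half-open everywhere; BED and TSV schemas documented
  in the reader/writer help pages; FASTA written at 60 columns; writers are
  deterministic byte-for-byte.
* All stochastic operations take an explicit integer seed; there is no
  hidden global-RNG dependence between pipeline stages.
* The hypergeometric test validates \(m, n \le N\) and
  \(k \le \min(m, n)\); enrichment with a zero known-fraction denominator is
  an error, not `NaN`.
* Ranks break ties lexicographically; oligomer merging breaks equal-overlap
  ties lexicographically; τ selection breaks ties upward. Every tie rule is
  deterministic and tested.
* Degenerate LOOCV folds (a class reduced below fitting size) fall back to
  the prior rather than aborting the whole cross-validation.
* `min_overlap` for oligomer merging defaults to half the shortest word;
  fragment remainders are kept in the permutation pool; pseudo-subgenome
  size matching is by first-crossing.

## 6. Known limitations

* The permutation flag is not a calibrated post-selection p-value (see §2);
  treat it as a repeat-concentration filter.
* LOOCV optimism from out-of-loop feature selection is inherited from the
  original procedure by default.
* The τ interpretation (posterior threshold) is a reasoned reconstruction,
  not an inherited definition.
* The generator's iid background understates the multiple-testing burden a
  repeat-rich genome imposes on the screen.
* Headline numbers that depend on the real genome, real TSS data and
  curated gene lists (oligomer totals such as 268/584, the specific success
  tables) are out of reach of a synthetic world by design; the package
  reproduces the *procedures* and the purely analytic quantities
  (hypergeometric overlap, enrichment arithmetic) exactly.
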