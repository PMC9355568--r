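---
title: "Screening for convergent gene loss with phylogeny-aware association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for convergent gene loss with phylogeny-aware association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convloss)
```

## The screening problem

When a lineage stops relying on a trait — vision in subterranean or
echolocating mammals being the canonical case — purifying selection on genes
serving that trait relaxes, and gene-inactivating mutations drift to
fixation. Because this happens independently in every lineage that lost the
trait, genes whose decay *tracks the phenotype across many origins* are
strong candidates for a functional role in it. `convloss` implements this
screen end to end: lesion detection in codon alignments, a per-gene
intactness statistic, phylogeny-aware association against a binary or
continuous phenotype, false-discovery-rate control with a convergence
filter, and parsimony mapping of the loss events.

## From alignments to %intact

A gene in one species is summarized by the **maximum percent of its reading
frame that remains intact** (%intact). `detect_mutations()` scans a
codon-aware pairwise alignment for five lesion classes: frameshifting
insertions and deletions (a contiguous indel run whose *net* length is not a
multiple of three), premature stop codons (in-frame `TAA`/`TAG`/`TGA` before
the terminal codon — the terminal stop, or a stop created in the final
codon, is never premature), mutated splice-site dinucleotides (canonical
`GT` donor / `AG` acceptor; `GC` donors are tolerated by default since they
occur in functional genes), and deletions of whole exons or the entire gene.

`percent_intact()` then treats every mutation span and every maximal run of
assembly-absent codons as a breakpoint and reports the longest breakpoint-free
stretch of codons as a percentage of the coding length. Coordinates are
0-based, half-open, in codon units throughout; a nucleotide lesion is
snapped to the codon containing its first affected base. Two conventions
deserve emphasis:

* **Missing is not lost.** Codons without assembly coverage reduce the
  intact stretch and the present fraction, but are never called as
  mutations. A gene with less than 50% of its coding sequence present is
  classified `missing` outright.
* **Longest clean stretch.** With breakpoints at codons 200 and 700 of a
  1000-codon gene the clean stretches are 200, 499 and 299 codons, so
  %intact is 49.9 — the breakpoint codons themselves count as broken.

`classify_status()` applies the standard thresholds: `lost` below 60%
intact, `intact` at or above 90%, `uncertain` between, `missing` below 50%
presence. All three are arguments, not constants. A second, transcript-level
classifier (`classify_transcript_central80()`) mirrors orthology-annotation
practice: a transcript is only condemned (`potentially_lost`) by a lesion
overlapping the central 80% of its codons, so terminal sloppiness in
alignments does not create false losses. We deliberately do *not*
down-weight terminal lesions inside `percent_intact()` itself; the
central-80% rule is confined to the transcript classifier.

## Phenotype assignment and independent lineages

`classify_by_acuity()` thresholds a visual-acuity table (cycles/degree;
default threshold 1): species below the threshold are foreground
(trait-loss), the rest background, species without a value are excluded.
Functionally blind species without measurements must be flagged
`assumed_zero` explicitly — the biological judgment stays in the input, not
in code. Where both behavioral and anatomical estimates exist, the table is
expected to carry the behavioral one (it is the more accurate measurement);
the package uses the table as given. `classify_by_signature()` offers a
molecular alternative: foreground species are those that have lost at least
`min_lost` (default 5) of a user-supplied marker gene set.

"Independent lineages" is operationalized as the **maximal monophyletic
clades whose leaves are all foreground** (`partition_lineages()`): two
foreground species share a lineage exactly when no background species sits
on the path between them. This is an interpretation — trait-loss counting
could also be done by ancestral reconstruction — but it is deterministic,
topology-invariant, and on the bundled 49-mammal reconstruction yields the
expected seven lineages (four subterranean singletons, one three-bat clade,
the mouse, and the vole + deer-mouse pair, which the high-acuity rat cannot
join).

## The association model

For each gene, the screen regresses %intact on the foreground indicator by
**phylogenetic generalized least squares** under a Brownian-motion
covariance: `V[i, j]` is the shared root-to-tip path length of species `i`
and `j` on the tree pruned to the species with data for that gene. The fit
is solved by Cholesky whitening (`V = R'R`; both sides are transformed by
`R^-T` and passed to QR least squares), which is numerically equivalent to
the closed-form GLS solution but stable and, because genes sharing a
missingness pattern share a factorization, fast enough for genome-scale
matrices. The slope's t statistic uses `n - 2` degrees of freedom; the
default alternative is one-sided (`less`), because the screen targets genes
*preferentially lost* — hence with depressed %intact — in the foreground.
Sidedness is an argument. A continuous mode (e.g. `log10` acuity as the
predictor) is provided but off by default; the primary screen is binary.

Design choices worth knowing:

* **Raw %intact is the response.** No phylogenetic normalization or
  transformation is applied to the response beyond the GLS covariance.
* **Plain Brownian covariance.** No Pagel's λ or other covariance scaling
  is estimated; this matches the cited GLS formulation and keeps per-gene
  fits deterministic. It is a simplification and is isolated in one place
  (`.pgls_core`) should scaling ever be added.
* **Missing species are dropped gene-wise** (the tree is pruned per gene),
  never imputed. Genes left with one phenotype class are skipped and
  reported with `NA` statistics; a constant response yields a degenerate
  fit with `p = 1` rather than an error.
* **BH over the post-filter universe.** `filter_genes()` first removes
  genes missing in more than half of either phenotype group and genes with
  identical non-missing values (they cannot associate); Benjamini-Hochberg
  q-values are computed across exactly the genes that were tested.
* **Candidates** must clear both the FDR cutoff (default 0.05) and the
  convergence filter: losses (%intact < 60) in at least `min_lineages`
  (default 3) independent foreground lineages. Output rows are ranked by
  `(q, p, gene_id)` so ties break reproducibly.

`control_screen()` re-runs the identical machinery with a user-chosen
foreground — typically the high-acuity sister species of the trait-loss
lineages — as a specificity check.

## Loss mapping

`dollo_count()` maps per-species statuses onto the tree under Dollo
parsimony: an intact gene can be lost on any branch but never regained, and
the gene is presumed intact at the root. The minimum event count is the
number of maximal clades whose non-missing leaves are all lost; each event
sits on its clade's stem branch, the deepest placement consistent with the
minimum. Missing leaves are uninformative — assembly gaps neither create
nor destroy events. An entirely lost tree therefore counts one event, on
the root stem. `shared_mutations()` complements this with direct evidence:
a lesion with identical kind and codon position in all non-missing leaves
of a clade is assigned to that clade's stem; same-kind lesions one codon
apart are reported as "possibly shared" (alignment wobble) but never
merged automatically.

## What the synthetic generator emulates — and what it does not

`simulate_screen_data()` produces complete benchmark data sets with known
truth: an ultrametric pure-birth species tree rescaled to unit height
(`ape::rphylo`), a minority of disjoint foreground clades, foreground
acuities sampled on (0, 0.9] against log-uniform background acuities on
[1.1, 60] (so threshold 1 recovers the intended labels exactly), and
per-gene Poisson mutation histories: associated genes accrue lesions at
rate `lambda_fg` per unit branch length on every branch within foreground
lineages (stem included — mutations on internal branches are inherited by
all descendants), all genes accrue background noise at `lambda_bg = 0.02`.
Lesion kinds are drawn as 30% frameshift deletions, 20% frameshift
insertions, 35% premature stops, 10% splice-site lesions, 5% exon
deletions; positions are uniform over codons. `emit_alignments()` renders
any implanted history as a concrete codon alignment that round-trips
through `detect_mutations()`, which is the end-to-end oracle for the
scanner.

Two calibrations define the default study conditions:

* `lambda_fg` is solved (not guessed) so that the *mean* per-foreground-
  species probability of loss (%intact < 60) is 0.8, using the Poisson
  count distribution along each species' stem-to-tip path and the exact
  distribution of the maximum spacing of uniform breakpoints. Path lengths
  differ across lineages, so individual species range around that mean.
* Eligible foreground lineages must span at least 10% of the tree height
  from their stem origin to their tips (`min_stem_frac = 0.1`). Relaxed
  selection needs evolutionary time: a lineage that split from its
  background sister over a near-zero branch yet carries a fully decayed
  gene is biologically impossible, and such sister pairs are exactly the
  configuration that degrades a Brownian-model fit the most (an abrupt
  change over a tiny shared-history difference inflates the residual
  variance estimate genome-wide).

The generator deliberately omits: any substitution process (queries differ
from the reference only by implanted lesions), within-lineage heterogeneity
in when the trait was lost (trait loss sits at each lineage's stem), rate
variation among genes, and alignment error. Passing benchmarks therefore
demonstrates that the statistical machinery recovers planted signal under
its own assumptions — not that the screen is robust to alignment artifacts
or assembly base error, which real applications must address upstream.

## Calibration, tested conditions and known limitations

The test suite runs the screen at the default conditions (49 species, 7
foreground lineages, 2,000 genes, 20 associated, 20 replicate seeds for the
benchmark; 100 seeded fixtures for the scanner round-trip; 200 random trees
of up to 8 leaves against the brute-force Dollo oracle). Under the null
configuration (no associated genes) the fraction of one-sided p-values
below 0.05 is checked against its 3-binomial-SE band. Two caveats are
documented rather than hidden:

* %intact under a pure-loss process is a point mass at 100 with occasional
  clade-correlated drops — far from Gaussian Brownian motion. PGLS p-values
  on such data are only *approximately* calibrated, and the quality depends
  on tree shape: on trees where few genes survive filtering the 5% tail can
  be noticeably inflated. The FDR cutoff plus the convergence filter is
  what controls false candidates in practice (the null screen flags
  essentially nothing).
* Enrichment sidedness: figure-legend practice in this field is a
  one-sided (over-representation) Fisher test, while a widely used web
  service applies a two-sided one. `fisher_enrichment()` defaults to
  one-sided and exposes `sided = "two.sided"`.

Numerical conventions: zero-length branches are replaced by a configurable
epsilon (`1e-8`) with a warning on input; singular covariances degrade to a
degenerate fit (`p = 1`) rather than an exception; writers emit fixed
column orders and 6-significant-digit numbers with no timestamps, so
identical inputs give byte-identical files; all generator randomness flows
from one seed through named substreams, making any single gene reproducible
in isolation.

## A worked miniature

```{r example}
sim <- simulate_screen_data(sim_config(n_species = 20, n_fg_lineages = 3,
                                       n_genes = 80, n_associated = 6,
                                       seed = 7))
scr <- forward_screen(sim$matrix, sim$tree, sim$assignment)
scr
head(ranked_results(scr)[, c("gene_id", "slope", "p_value", "q_value",
                             "n_lost_lineages", "candidate")], 4)
intersect(candidate_genes(scr), sim$associated_genes)
```

Mapping the top candidate's losses:

```{r dollo}
top <- ranked_results(scr)$gene_id[1]
status <- classify_status(sim$matrix[top, ],
                          ifelse(is.na(sim$matrix[top, ]), 0, 1))
names(status) <- colnames(sim$matrix)
status[status == "uncertain"] <- "missing"
dollo_count(sim$tree, status)$count
```
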