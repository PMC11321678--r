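---
title: "Methods: regulatory circuits from single-cell chromatin accessibility"
author: "mbcircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory circuits from single-cell chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `mbcircuits`, the
conventions behind every tunable parameter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the underlying methods leave the design open. It states no measurement that
the test suite and `scripts/acceptance.R` do not themselves compute.

# The data model

A fragments file records deduplicated Tn5 fragments: chrom, start, end
(0-based half-open), cell barcode, duplicate count. Each fragment reports
two transposition events — its `start` and `end − 1` positions — and every
counting operation in the package (tiles, peaks, windows, TSS profiles)
counts those two insertions, weighted by the duplicate count. This makes
the tile-matrix conservation law exact: the matrix total equals twice the
summed fragment counts, which the tests assert with `identical()`.

# Quality control

Per cell we compute the number of unique fragment records and a TSS
enrichment score: the mean per-bp insertion count in TSS ± 50 bp (101 bp),
aggregated over all TSS, divided by the mean per-bp count in the two
distal flanks 1,901–2,000 bp from the TSS (200 bp per TSS) plus a
pseudocount of 0.1. The window geometry and pseudocount are the
conventions of the standard single-cell ATAC toolkits; they are exposed as
arguments. Cells pass at ≥ 1000 unique fragments AND enrichment ≥ 4, then
at most the top 12,000 cells by enrichment are kept (ties broken by
barcode so the result is deterministic). Thresholds are *inclusive*: the
upstream description of these filters is phrased once as cut-offs and once
as parameter settings whose literal reading would exclude everything below
*or equal*; we adopt the minimum-value convention (a cell exactly at 1000
fragments and enrichment 4.0 is kept). Filtering is idempotent and
monotone in both thresholds — both are property-tested.

# Gene activity scores

For gene $g$ and cell $c$,
$$\mathrm{score}(g,c) = m_g \sum_{t\,:\,|\mathrm{centre}(t)-\mathrm{TSS}_g|\le W} e^{-d(t,g)/\lambda}\, x(t,c)$$
with $W$ = 100 kb, $\lambda$ = 5 kb, $x(t,c)$ the tile insertion count,
and $d(t,g)$ the distance from the tile centre to the nearest gene-body
coordinate (zero inside the body, so body tiles carry weight 1). Tiles are
assigned to the gene window by their centre, which avoids double-counting
tiles straddling the window edge. The size factor $m_g$ rescales
$1/\mathrm{length}_g$ linearly onto $[1, 5]$ across all genes (a single
gene gets the midpoint 3): raw $1/\mathrm{length}$ would make score
magnitudes depend on the unit of length, while the bounded rescaling keeps
the correction monotone and scale-free. The gene window is clipped at
chromosome ends only; it is not truncated by neighbouring genes. Scores
are linear in counts and decrease strictly as fixed insertion mass moves
away from the body — both tested.

# Copy-number inference

The genome is tiled into 10-Mb windows advancing by 2 Mb. Window starts
follow the sliding-window convention of the interval toolkits: starts
advance while `start < length − width + step`, so a truncated trailing
window (always wider than `width − step`) appears only when
`length − width` is not a step multiple; truncated windows below half the
nominal width would be dropped (with the default 10 Mb/2 Mb geometry none
can be). Windows are removed when a blacklist covers more than half of
them or when their GC fraction falls in the bottom 5% — the low-GC tail is
where composition bias concentrates false-positive copy-number signal; the
5th-percentile default makes that filter deterministic and is exposed as
`min_gc`.

For cell $c$ and window $w$ the raw signal is
$$\mathrm{raw}(c,w) = \log_2\frac{n(c,w) + 1}{\overline{n}_{B(w)}(c) + 1},$$
where $B(w)$ is the $k$ kept windows (default $k$ = 100) with GC content
nearest to $w$'s — the window itself excluded, ties broken by genomic
order. Excluding the self-window avoids biasing every ratio toward zero;
the pseudocount guards the log at single-cell sparsity. The corrected
value subtracts the per-window mean of the diploid reference cells
(immune cells in tumour data), which cancels residual, GC-independent
coverage structure; reference cells therefore centre at exactly zero per
window, by construction. Calls are gain above the threshold and loss below
its negative (the deletion rule is taken symmetric to the stated
amplification rule), and runs shorter than `min_consecutive = 2` windows
are smoothed to neutral, because on an overlapping 10 Mb/2 Mb grid an
isolated called window is almost always noise; `min_consecutive = 1`
restores the literal rule.

**The call threshold and the single-copy operating point.** The default
threshold of 1 reproduces the candidate-amplification rule (corrected
log2 ratio above 1). For a one-copy gain on a diploid background the
*expected* corrected value is exactly $\log_2(4/2) = 1$ — and in practice
slightly less, because the amplified windows also inflate their own
GC-matched backgrounds (on the synthetic conditions below, by roughly
0.1). A strict `> 1` rule therefore sits *on* the single-copy-gain
expectation and cannot recover ±1-copy events; it is an operating point
for strong amplifications. The package's recovery analyses for
single-copy-scale events use the midpoint threshold 0.5 — halfway between
the neutral expectation (0) and the one-copy expectation (1) — derived
from the generator's rate law, not fitted to data. The default remains 1.

On the compact synthetic genome (3 × 60 Mb, ~74 kept windows) the
GC-matched background uses $k$ = 50 neighbours, since $k$ = 100 requires at
least 101 kept windows; at genome scale the default applies unchanged.

# Motif deviations

With $X$ the cells × peaks count matrix (counts used as-is, not
binarised — binarisation would break the conservation identity), motif
$m$'s expected count in cell $c$ is $f_m T_c$, where $f_m$ is the fraction
of all insertions falling in motif-$m$ peaks and $T_c$ the cell total. The
raw deviation $(obs - f_m T_c)/(f_m T_c)$ sums to zero over cells for
every motif — an exact identity asserted at $10^{-10}$ relative
tolerance. Each deviation is z-scored against 50 background sets; a
background set replaces every motif peak with one drawn from its 50
nearest neighbours (self included) in standardised (GC, log1p mean
accessibility) space, and the background's own $f$ is recomputed per set.
Background sampling is seeded, so deviations are bit-reproducible. Motifs
with zero expected counts are dropped with a warning. On planted-null
motifs (decoy motifs whose sites fall only in background peaks) the
z-scores behave like standard normals — the tests require per-motif |mean|
< 0.2 and sd within [0.7, 1.4] over cells.

# Circuits

*Markers.* Features are tested cluster-vs-rest with a tie- and
continuity-corrected normal-approximation rank-sum test (vectorised; the
exact test the original toolkits use is also Wilcoxon's), log2 fold
changes of means use pseudocount 1, and BH adjustment is applied within
each cluster. Clusters under 3 cells are skipped with a warning.

*Co-accessibility and CCANs.* Cells are aggregated once into pseudo-bulk
groups of ~20 by greedy nearest-neighbour grouping in the LSI embedding
(each cell assigned exactly once; the visiting order is seeded). Aggregate
profiles are depth-normalised and log1p-transformed, and Pearson
correlations are computed for all same-chromosome peak pairs with midpoint
distance ≤ 250 kb; pairs at or above 0.5 become links. Connected
components of the link graph are the CCANs; a gene joins a CCAN through a
peak overlapping its promoter (TSS ± 2 kb), and the component's other
members become the gene's distal candidate elements. The ± 5 kb window is
reserved for the TF-motif promoter rule below, where that span is stated
explicitly; the 2 kb promoter is the usual gene-linking convention. The
aggregate-correlation approach replaces the penalised graphical model some
toolkits use; max distance and correlation cut are configuration, as no
printed values exist for them.

*Positive regulators and the screen.* Correlations between gene scores and
motif z-scores are computed over **cluster means**, not raw cells: the
source phrasing supports both, and the network rules that set the numeric
cut-offs are defined at cluster level. A TF is a positive regulator when
its own-gene/own-motif correlation exceeds 0.5 *strictly* (a pair at
exactly 0.5 fails), its BH-adjusted p is below 0.01, and its motif delta
(max − min cluster-mean z) reaches the 75th percentile of all tested TFs'
deltas — the delta axis is shown without a printed cut-off, so the
customary quantile rule is used and exposed. The exhaustive screen pairs
every gene with every motif (the pair count is exactly
genes × motifs), BH-adjusts globally across all pairs, and keeps pairs
with r > 0.5 and adjusted p < 0.01. Constant profiles yield undefined
correlations and are flagged, never called positive.

*Network.* A directed edge TF → gene requires all three: the TF is
positive; a motif-bearing peak sits within TSS ± 5 kb of the gene or among
the gene's distal candidate elements; and the (gene, motif) pair passes
the screen. Every edge thus carries motif-location and correlation
evidence that can be re-derived from the stored inputs. Tightening any
cut-off can only remove edges.

# Cohort classifier

Expression is restricted to the NTR catalogue (94 genes in the default
design), z-scored per gene (zero-variance genes dropped with a warning),
and clustered by K-means with 50 seeded restarts for each candidate k
in 2–8. The chosen k maximises the mean Euclidean silhouette, ties going
to the smaller k for parsimony; a fixed k can override the choice (k = 1
is rejected — the silhouette is undefined). Markers are nominated per
cluster as the highest-mean significant gene under a classical equal-
variance one-way ANOVA with BH adjustment over genes; clusters need ≥ 3
samples. Prediction for new samples projects them onto the stored per-gene
centre/scale over the shared genes (at least half must be present) and
assigns the nearest centroid in Euclidean distance. Euclidean-on-z is the
distance convention throughout; it is stored with the fitted object so
predictions are reproducible.

# What the synthetic generator emulates — and what it does not

`simulate_fragments()` draws per-cell fragment counts from a negative
binomial (mean `depth_mean`, size 20) and places first insertion sites by
a per-tile rate law:
baseline × exp(gc_bias × (GC − 0.5)) × (copy number / 2) × program
multipliers; the second insertion sits one sampled fragment length
(80–300 bp) downstream. The GC bias form is monotone, invertible and
zero-centred — the real bias's shape is unknown, only that it exists. The
regulatory scenario adds housekeeping structure shared by all groups
(peaks open ×20 over background, promoters a further ×4), which reproduces
the TSS enrichment and fraction-of-insertions-in-peaks properties real QC
relies on.

The default **CNV study conditions** are 3 chromosomes × 60 Mb, 200
diploid reference cells plus 400 tumour cells of one clone carrying a
copy-4 segment (chr2:10–30 Mb) and a copy-1 segment (chr3:20–40 Mb), mean
depth 8,000 fragments/cell, GC bias on. Recovery is scored per cell and
window at the 0.5 operating point: windows fully inside a segment are
positives, windows not touching a segment are negatives, and boundary
windows partially overlapping a segment are excluded — their expected
signal is intermediate by construction, so window resolution assigns them
no truth state.

The default **regulatory conditions** are 3 × 12 Mb, 94 genes, 4 planted
TF programs (each: one TF with a motif, 5 targets of which 2 are NTR
genes, their promoter peaks plus 8 distal peaks), 40 decoy TFs whose
motifs live only in background peaks, ~150 background peaks, and 9 cell
groups: one reference plus two groups per program at graded effect (×3
and ×2). Two groups per program mirror the several-clusters-per-subgroup
structure of real data and give the cluster-level correlations 9 points —
with only 4 clusters a Pearson p-value has 2 degrees of freedom and can
never reach the 0.01 adjusted cut-off, so a 4-cluster design would make
positive-regulator detection impossible regardless of effect size.

The default **cohort conditions** are 763 samples × 94 genes in 4 groups,
marker-block shift 5 over unit Gaussian noise. Groups 3 and 4 carry
smaller private blocks (12 genes) plus a shared block (6 genes), kept
smaller than the private blocks so that the pair is the closest two groups
— forcing k = 3 merges exactly that pair — while all four remain
separable and the silhouette still peaks at k = 4.

Not emulated: sequence content (no FASTA; motif sites are interval
inputs), fragment-length periodicity, doublets, batch effects, sample-level
heterogeneity within a group, and trans-chromosomal regulation. Passing
tests on this generator therefore demonstrate correctness of the
implemented inference under its stated noise model, not performance on
real tissue; in particular the generator's programs are cleanly disjoint,
so recovery rates here are upper bounds.

# Numerical and degenerate-input conventions

* All intervals are 0-based half-open; an insertion at a peak's start is
  inside, at its end is not; abutting intervals do not overlap.
* BH is the multiple-testing adjustment wherever an adjusted p appears.
* Seeds: every stochastic step takes a seed; pipeline stages derive
  sub-seeds from the global seed and the stage name, and restore the RNG
  state afterwards.
* Empty inputs: an empty barcode set gives an empty QC table; an empty
  marker set gives an empty enrichment table; an empty NTR list gives an
  empty circuit; an empty *query* in overlap fractions is an error (the
  fraction is undefined).
* Zero-variance genes/profiles are dropped or flagged, never silently
  scored.
* Ties: GC matching breaks ties by genomic order, QC ranking by barcode,
  signature annotation alphabetically (with a tie flag), silhouette by
  smaller k.

# Problem sizes

The test suite and acceptance script run the CNV conditions at 600 cells ×
360,000 tiles (~4.8 M fragments), the regulatory conditions at 750 cells
(~1.9 M fragments, 276 peaks, 44 motifs), and the cohort at 763 × 94;
together they complete in a few minutes on one core. These sizes were
chosen so each planted structure spans enough windows, peaks and clusters
for its recovery statement to be meaningful while the whole suite stays
interactive.

# Known limitations

* Iterative LSI is replaced by single-pass TF-IDF + SVD + k-means;
  clustering here is plumbing, and no claim about cluster discovery on
  real data is made or tested.
* Co-accessibility significance is a fixed correlation cut-off, not a
  calibrated null; on small pseudo-bulk counts weak links are noisy.
* The headline counts of the motivating study (tens of thousands of cells,
  hundreds of thousands of peaks, 26 named regulators) derive from
  unreleased patient data and are out of reach of a synthetic test bed;
  the package reproduces the *arithmetic* of those summaries and the
  *behaviour* of the methods under planted truth instead.
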