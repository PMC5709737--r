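---
title: "Methods: tile enrichment, methylome segmentation and bivalent CpG island shores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile enrichment, methylome segmentation and bivalent CpG island shores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoremap)
```

# The problem

De novo DNA methyltransferases are not deposited uniformly along the
genome. DNMT3B tracks H3K36me3 through transcribed gene bodies, while the
long DNMT3A isoform, DNMT3A1, accumulates at the *shores* of unmethylated,
Polycomb-marked (H3K27me3 + H3K4me3, "bivalent") CpG island promoters —
the narrow transition zone where the fully methylated genome gives way to
the protected unmethylated island core. 5-hydroxymethylcytosine, the TET
oxidation intermediate of methylation turnover, concentrates at exactly
these borders. `shoremap` implements the complete computational chain
needed to establish such a picture from tiled ChIP-seq counts and
per-CpG bisulfite calls, and ships a seeded synthetic-genome generator
that plants the structure so every stage can be validated against a known
truth.

# Tile enrichment

The genome is partitioned into fixed-width windows (1 kb default);
trailing sub-width fragments are dropped so all statistics see a constant
window size. Tiles overlapping a blacklist by any amount, with
mappability below 0.5, or with at most 50% of their CpGs covered at least
10x in bisulfite data are removed before any statistic is computed.

Per-track enrichment of IP over input is

$$ e = \log_2\frac{n_\mathrm{ip} + c}{n_\mathrm{input} + c}, \qquad c = 8, $$

where both counts are first scaled to the **mean of the two library
sizes**. The mean-library target keeps normalized values on a count-like
scale, so the pseudocount retains its intended magnitude; scaling to
reads-per-million would silently change what "eight pseudocounts" means.
The pseudocount bounds the statistic, shrinks empty tiles to zero, and
makes the enrichment antisymmetric under swapping IP and input. Track
cross-correlations are Pearson correlations of $\log_2(n + c)$ tile
vectors; a constant track has no defined correlation and is reported as
missing rather than zero.

# Bound-region calling

Tiles bound by each DNMT are called against input with an in-package
negative-binomial machinery rather than an external count-model package,
so that every numerical choice is explicit and testable:

* **Size factors** are median-of-ratios: $s_j = \mathrm{median}_i\,
  k_{ij}/g_i$ with $g_i$ the tile's geometric mean, over tiles with no
  zero count (total-count fallback otherwise). A unit test cross-checks
  the implementation against an independent reference implementation.
* **Dispersion** is estimated blind (across all libraries). The sample
  variance of $n$ normalized counts is $\mathrm{Var}\cdot
  \chi^2_{n-1}/(n-1)$, so per-tile moment estimates are divided by the
  median of that scaled chi-square and summarized per mean-expression bin
  by the **median**, giving a mean–dispersion trend that is approximately
  unbiased under the null yet robust to the minority of truly bound
  tiles, whose cross-group variance is inflated by the group difference.
  With fewer than eight libraries the trend value is used outright;
  otherwise per-tile estimates are shrunk halfway (in log space) toward
  it. Degenerate tiles (variance below the mean) are floored at $10^{-8}$.
* **Test**: two-sided Wald on the log fold change with delta-method
  standard error under $\mathrm{Var}(K) = \mu + \alpha\mu^2$, groups
  pooled by size-factored means. Windows with zero counts in every
  library are excluded up front. Adjustment is Benjamini–Hochberg, and a
  tile is called bound at fold change $> 1$ and adjusted $p < 0.002$.
* **Exclusive sets**: the called sets of DNMT3A1, DNMT3A2 and DNMT3B are
  intersected into the full Venn partition; tiles called for exactly one
  track form that track's exclusive set.

At extreme tiles the Wald tail is lighter than an exact conditional
(binomial) two-sample tail — the calls agree, the p-values can differ by
several orders of magnitude. This is a property of all Wald-type count
tests and is documented in the test suite rather than hidden.

Calibration on a fold-1 simulation (10,000 tiles, dispersion 0.05) gives
a p-value distribution with fraction$(p<0.05)\approx 0.05$ and no calls
at the bound-region thresholds.

# Methylome segmentation

Per-CpG bisulfite calls are retained when coverage is strictly greater
than 10 (WGBS) or 20 (RRBS) and the CpG overlaps no SNP. Region
methylation is the **unweighted mean of per-CpG fractions** times 100
(matching per-CpG percent displays; a pooled-count alternative would
weight high-coverage CpGs more), and densities are CpGs per 100 bp.

Segmentation is a deterministic run-rule system: fractions are smoothed
with a centered 3-CpG running mean (truncated at chromosome ends); CpGs
are linked into blocks wherever the inter-CpG gap is at most 5 kb; within
a block, maximal runs of at least 4 consecutive CpGs with smoothed
fraction at most 0.5 are hypomethylated segments — UMR with at least 30
CpGs, LMR otherwise — and the complementary runs are FMRs. Segment bounds
snap to outermost member CpGs (0-based half-open). The published
segmentations this mirrors were produced by an HMM-based caller on real
methylomes; the run-rule system was chosen because it is exactly
reproducible and admits a brute-force oracle, against which the
implementation is verified on 1,000 random CpG vectors. The UMR/LMR CpG
split at 30 follows the established convention for separating CpG-rich
promoter regions from CpG-poor distal elements.

For profile anchors, UMRs/LMRs within 6 kb of another UMR/LMR are dropped
(both members), as are FMRs of 12 kb or less; surviving FMRs are ranked
by methyl-CpG density (CpGs with fraction $\ge 0.5$ per 100 bp) and split
into three equal bins, lower bins taking the remainder, ties resolved by
genomic order. **UMR borders** are the end of the nearest preceding FMR
and the start of the nearest following FMR of each promoter-overlapping
UMR, with 5′/3′ labels following the linked gene's strand.

# CpG islands, bivalency and shores

Islands are distance clusters: consecutive CpGs closer than the
chromosome-wide median inter-CpG gap merge, and clusters with at least 10
CpGs spanning at least 200 bp are kept. The length/count filters replace
the statistical significance step of sequence-based island callers — the
200-bp filter is applied downstream in the workflow this reproduces, and
a deterministic rule is preferable for a testable pipeline. Islands must
overlap a promoter (TSS ± 1 kb; the source annotation does not state
widths) by at least 1 bp; multi-promoter overlaps resolve to the largest
overlap, ties to the leftmost TSS.

Promoter islands with mean methylation below 20% are *unmethylated*;
among them, an island is *bivalent* when both mean H3K4me3 and mean
H3K27me3 log2 enrichment over its tiles reach $e_{\min} = 1.0$ (2-fold; the
exact published binning thresholds are not available, so the cutoff is a
configurable default). Shores are the fixed 2-kb intervals immediately
flanking the island, clipped at chromosome bounds and labeled 5′/3′ by
gene strand.

# Profiles, clustering, dynamics

Profile matrices are anchors × bins of library-normalized read counts
(reads per bin per $10^7$ library reads; the normalization constant is a
convention — the figures this follows say "library-normalized" without
stating one). Minus-strand anchor rows are reversed so column 1 is always
5′. Anchors whose window leaves the chromosome become missing rows,
excluded from column means. Gene-body profiles rescale each body to a
fixed number of bins and express values as densities per flank-bin width,
so a spatially constant track is flat across flanks and body; overlapping
genes are dropped.

UMR clustering is k-means (k = 5) on $\log_2(x + 8)$ profile rows with
k-means++ seeding, ten restarts keeping the lowest inertia, and a
recorded seed. Condition dynamics are pseudocount-regularized log2 ratios
on a common tile frame, summarized as medians of 500 consecutive windows
ranked by methylation gain; a trailing block of at least 250 windows is
kept, a smaller one merges into its predecessor (an unstated convention;
keeping a tiny trailing block would add one high-variance point).
Promoter-class enrichment of an externally supplied up-regulated gene
list uses upper-tail hypergeometric probabilities, verified against exact
combinatorial enumeration for all universes up to 60 genes.

# The synthetic genome

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

* **Geometry**: 2 chromosomes × 5 Mb, 1-kb tiles; 40 genes of 10 kb
  placed uniformly at random on the tile grid with margins that keep
  planted islands more than two shore widths apart and planted UMRs clear
  of the 6-kb profile filter; 20 promoter CpG islands (2 kb, centered on
  the TSS of their gene), half bivalent; 10 distal LMR regions of 1.2 kb.
  Transcribed genes (half of the island-free genes) model active loci;
  island genes are kept untranscribed, as bivalent promoters are silent.
* **CpG landscape**: geometric inter-CpG gaps, mean 100 bp in the
  background and 12 bp inside islands (realistic density contrast for
  the per-100-bp statistics); per-CpG true methylation 3% in island
  cores, 85% in shores and background, 25% in LMRs.
* **Counts**: per-tile negative binomial with mean 30 reads per 1-kb tile
  and dispersion 0.05 (desk-scale stand-ins for unpublished library
  depths, exposed in the config), fold 8 planted per track: DNMT3A1 at
  bivalent shores, DNMT3B and H3K36me3 in transcribed bodies, H3K4me3 at
  island cores, H3K27me3 over bivalent islands and shores, 5-hmC on the
  border tile flanking each bivalent island edge, DNMT3A2 and input flat.
  DNMT3A1 is simulated as **two IP replicates**, mirroring the two
  independent clones profiled for that isoform — a power analysis shows a
  single 30x library at fold 8 sits near the edge of reliable recovery at
  adjusted $p < 0.002$, whereas the replicated design detects planted
  shores comfortably.
* **Bisulfite**: per CpG, Poisson(30) coverage and binomial methylated
  counts at the true fraction.
* **Determinism**: one global seed fans out into named substreams
  (placement, each track and replicate, bisulfite), so adding a track
  never perturbs existing ones and identical configurations produce
  byte-identical fixtures.
* **Archetype mode** (`umr_archetypes = TRUE`) assigns each bivalent
  island one of five strand-relative DNMT3A1 binding archetypes (5′
  shore, 3′ shore, both shores, center, none) for clustering studies.

What the generator does **not** emulate: sequence composition (no
FASTA), bisulfite conversion error, strand-resolved CpGs, fragment-length
effects, copy-number structure, and spatially correlated noise. Passing
recovery tests therefore demonstrate the correctness and calibration of
the statistical machinery under its stated model, not performance on the
idiosyncrasies of real libraries.

# Worked example

```{r example, eval = FALSE}
library(shoremap)
res <- run_pipeline(synth_config(seed = 1), pipeline_config(),
                    outdir = "shoremap_out")
table(res$segments$class)
res$islands[, c("gene", "meth_pct", "chromatin_class")]
lengths(res$calls$exclusive)
```

The run writes the fixture, enrichment bedGraphs, the track correlation
matrix, exclusive-region BEDs with the Venn partition, segment/border
BEDs, classified island and shore annotations, the 5-hmC border profile
and UMR cluster labels under `outdir`, with a record-count log line per
stage.

# Numerical choices and limitations

* All coordinates are 0-based half-open; interval overlap uses
  established range machinery behind a single conversion helper.
* Reads are assigned to tiles by their 5′ start, without fragment
  extension (the counting layer is abstracted so an extension option
  can be added); a start on a tile boundary belongs to the right tile.
* Blacklist removal is any-overlap (conservative, standard practice).
* `FC > 1` is interpreted on the natural scale.
* Fold changes at zero-input tiles are infinite by construction; the
  Wald variance floors group means at 0.5 to stay defined.
* Region methylation of a region without retained CpGs is missing, never
  zero.
* The pipeline's default problem size (10,000 tiles, ~120,000 CpGs) runs
  end-to-end in seconds; it was chosen as the smallest genome in which
  every planted feature class appears in sufficient numbers for stable
  recovery statistics.
* Reproducing published region counts from the original sequencing runs
  is out of scope: those depend on the deposited raw data and the exact
  versions of the external tools used there. The pipeline reports its
  own counts on its own inputs.
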