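---
title: "Methods: multifactorial single-cell chromatin profile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifactorial single-cell chromatin profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`scmultimark` analyzes multi-target single-cell chromatin profiling data:
experiments in which each antibody carries its own adapter barcode, so every
deduplicated tagmentation event (fragment) is attributable both to a cell
barcode and to the chromatin target (e.g. H3K27me3, H3K4me2, H3K36me3) that
produced it. The input is one Cell Ranger-style fragment BED per target
(`chrom, start, end, barcode, dup_count`; 0-based half-open coordinates).
The package covers fragment QC, barnyard collision rates, LSI-style cell
typing, a per-cell Poisson gene-enrichment test, cross-mark co-occurrence
statistics, and trajectory/group comparisons, plus a synthetic-data
generator with planted ground truth that makes the whole pipeline testable
without sequencing data.

# Fragment model and QC

Uniqueness is defined on `(chrom, start, end, cell, target)`. The target
label is part of the key deliberately: the same coordinates observed by two
different assays in one cell are two distinct biological events, not
duplicates of each other. `deduplicate()` conserves duplicate mass (the
collapsed record's `dup_count` is the sum of its inputs) and is idempotent.

Cells are retained when every required target yields at least
`min_unique = 100` unique fragments (inclusive). Single-cell chromatin data
are sparse and heavy-tailed in per-cell depth; 100 unique fragments per
target is the conventional floor below which per-cell statistics (median
fragment length, target proportions, enrichment tests) become unstable.
The cutoff can be relaxed per target via `relax=` — low-yield elongation
marks often need a lower floor to keep enough cells for trajectory work —
and QC pass rate is monotone non-increasing in the cutoff.

# Barnyard collision rates

For human/mouse mixing experiments, species is read from the reference-name
prefix (`hg19_*` / `mm10_*`) or an explicit map. Reads are pooled across
targets per cell, and a barcode is called a cross-species collision when
strictly less than 90% of its unique reads come from one species. The strict
inequality matters only at the exact boundary but is fixed for determinism.
Collisions under-count same-species doublets by construction; the rate is a
QC diagnostic, not a doublet-removal tool. The displayed percentage is
rounded half-up to one decimal; the raw rate is retained in machine output.

# Cell typing (LSI)

The embedding pipeline follows the standard sparse-chromatin recipe:

1. **Binning**: unique fragments are counted into non-overlapping 50-kb
   windows (final partial window included); a fragment joining two windows
   counts in both (overlap is any shared bp).
2. **Feature selection**: the top 40% of windows by aggregate count are
   kept (`floor(0.4 n)`), ties at the cutoff broken by genomic coordinate
   so runs are reproducible.
3. **TF-IDF + log**: `value = ln(1 + 1e4 · TF · IDF)` with
   `TF_ij = c_ij / colsum_j` and `IDF_i = N / n_i`. This is the common LSI
   form; the scale constant and the variant are parameters, not dogma. TF
   normalization makes the transform invariant to per-cell depth scaling.
   All-zero windows are dropped before IDF; a cell with no counts in the
   selected windows is an error rather than a silent NaN.
4. **SVD**: dimensions whose singular values exceed 0.2% of the sum of all
   singular values are retained; per-cell coordinates are the right
   singular vectors scaled by their singular values. The first dimension is
   *not* dropped (in these data it is not a pure depth axis once TF
   normalization has been applied); if fewer than two dimensions pass, the
   top two are kept with a warning.
5. **Clustering and evaluation**: k-means (10 restarts, fixed seed) runs on
   the retained SVD coordinates — the metric space — not on the 2-D UMAP
   projection, which exists for visualization only. Agreement with known
   labels is scored by normalized mutual information with natural logs,
   normalized by the arithmetic mean of the two entropies by default
   (`max`/`min`/`sqrt` variants are available; the choice only matters for
   unbalanced partitions).

**Integration.** Published weighted-nearest-neighbor integration is out of
scope; `integrate_targets()` provides the simplest defensible substitute:
each target's retained coordinates are centered, scaled to unit total
variance, weighted, and concatenated. On well-separated synthetic types
this retains at least 90% of the best single-target NMI; it will not
reproduce WNN's adaptive per-cell weighting on subtle real data.

# The per-cell Poisson gene-enrichment test

For a cell *i*, a gene, and a target, let *r* be the observed unique
fragments overlapping the gene window, *L_i* the cell's median fragment
length, *f_i* its fragment count (per target by default — each target is a
separate assay sharing the cell; pooled mode is an option), *L_gene* the
window length and *L_genome* the reference length. The test works on the
coverage (depth-per-bp) scale:

- observed: `x = r · L_i / L_gene`
- expected: `mu_i = L_i · f_i / L_genome`
- `p = P(Poisson(mu_i) >= x)`

Both sides are mean per-bp coverage depths, which is the only scaling under
which they share units; under the null, `E[x] ≈ mu_i`, so the statistic is
self-calibrated. Gene windows run from 1 kb upstream of the farthest-distal
TSS to the TES, strand-aware and clipped at zero.

Since Poisson support is integer and `x` is not, the upper tail is
evaluated at `ceiling(x)` by default; a continuous alternative (regularized
upper incomplete gamma at `x`, identical at integer `x`) is provided. The
ceiling rule is conservative and has a resolution consequence worth
knowing: `x` moves in steps of `L_i / L_gene`, so a gene only becomes
distinguishable from background once it accumulates on the order of
`L_gene / L_i` fragments, i.e. roughly 1× base-pair coverage. Enrichment
calls are therefore about *coverage*, not raw counts; short test intervals
or strong multipliers resolve first. `r = 0` gives `p = 1` exactly, and
tails are computed in log space so genuinely tiny p-values do not collapse
to zero.

**Multiple testing.** BH step-up at `q < 0.01` over the family of all
observed (cell, gene, target) combinations in the run. Combinations with
`r = 0` are not part of the family: their p-values are exactly 1, they can
never be called, and including them would only inflate the family size.

**Normalized counts.** For heat maps, bivalency scores and group
comparisons, per-cell counts are scaled to 10^4 total per cell and target —
the usual counts-per-10k convention, chosen because absolute per-cell
depths vary over an order of magnitude.

# Co-occurrence statistics

- **Target proportions**: per-cell share of unique reads per target (sums
  to 1); measurable directly because fragments carry target barcodes.
- **Bivalency score**: per cell, the sum of normalized counts over genes in
  which the repressive mark *and* at least one active mark are both called
  enriched in that same cell; counts from the repressive and each enriched
  active target contribute. Zero when no gene qualifies.
- **Cramér's V**: per cell and target pair, genes are cross-tabulated by
  their two enrichment flags into a 2×2 table; `V = sqrt(chi² / n)` with
  the chi-square computed without continuity correction (determinism on
  sparse cells outweighs small-sample smoothing here). Any zero marginal
  makes the table degenerate: `V = 0` with an explicit flag rather than
  NaN. The gene universe defaults to all genes observed in the run, so `n`
  is comparable across cells; a cell needs data for at least two genes.

# Group and trajectory comparisons

The low/high split on a target's per-cell read share is a median split with
cells exactly at the cutoff sent low (deterministic; quantile and fixed
thresholds available). Differential enrichment per gene is
`LFC = log2((mean_low + 1) / (mean_high + 1))` on normalized counts (the
pseudocount of 1 on the counts-per-10k scale damps ratios driven by
near-zero means) with a two-sided Welch t-test, uncorrected — these
per-gene comparisons are descriptive, and the enrichment calls upstream
already carry the FDR control. Zero-variance-in-both-groups cases are
flagged degenerate (`p = 1` when means agree, `p = 0` otherwise).

Trajectory quality uses two metrics: the fraction of cells assigned to the
wrong lineage (per correct lineage and pooled), and the inversion
frequency — over all cell pairs on a trajectory with distinct known
timepoints, the fraction whose pseudotime ordering contradicts their age
ordering, with pseudotime ties counting one half. This is a Kendall-style
discordance fraction: the minimal formalization of "timepoints out of
order", zero iff pseudotime is weakly monotone in age, and invariant under
monotone transformations of pseudotime. Pseudotime inference itself is
consumed as input, never computed here.

# The synthetic generator

`simulate_experiment()` emulates the statistical structure the pipeline
consumes: per-cell log-normal depth factors (default `sigma = 0.5`,
matching the order-of-magnitude spread of real per-cell unique-read
counts), uniform background fragments at `background_rate` per bp per cell
and target, optional per-target efficiency scalings, and planted genes
whose intervals accumulate fragments at `multiplier ×` background in the
configured cell types. Fragment midpoints (not starts) are placed by the
model, giving symmetric overlap behavior; lengths are normal with mean
200 bp, truncated to [30, 1000] bp. `simulate_species_mix()` builds
barnyard mixtures: doublets split reads `Binomial(n, 0.5)` between species;
singlets carry a 0.001 per-read cross-species contamination, so their
majority fraction stays above 99% with overwhelming probability while
avoiding implausibly pure profiles. Everything is deterministic under the
configured seed.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: fragment-length dependence on chromatin
state, non-uniform background (mappability, blacklist regions, copy
number), antibody cross-reactivity or adapter crossover between targets,
barcode errors, and same-species doublets.

## Study conditions used by the tests and the acceptance script

Problem sizes are chosen so each property is measured in the regime it is
claimed for while the full run stays desk-scale:

- *Enrichment recovery*: 40 test genes of 500 bp on a 1-Mb genome,
  50 cells, ~2,000 fragments per cell (`mu_i ≈ 0.4`), 10 genes planted at
  20× — comfortably past the coverage-resolution threshold above, giving
  recall ≥ 90% at `q < 0.01`; with multiplier 1 everywhere the flagged
  fraction stays ≤ 1%.
- *Cell typing*: two types × 200 cells, ~500 fragments per cell on a 10-Mb
  genome (200 windows), 30 planted 10-kb genes per type; disjoint gene
  sets give NMI ≈ 1, identical sets give NMI ≈ 0.
- *Barnyard*: 2,000 barcodes at 10% doublets and 1,000 reads, recovered
  within three binomial standard errors.
- *Trajectories*: four timepoints × 50 cells; inversion frequency is zero
  at zero noise and increases monotonically with noise.

# Known limitations

- The enrichment test conditions on the cell's own `f_i` and `L_i`;
  extremely shallow cells (near the QC floor) have low power, which is why
  QC precedes testing.
- The ceiling rule makes single-fragment overlaps in short-`mu` cells
  indistinguishable (all have `ceiling(x) = 1`); the continuous tail
  option softens but does not remove this.
- `k`-means with `k = 2` presumes two dominant populations, as in
  two-cell-type mixing designs; for richer structure, cluster the retained
  coordinates with any method and pass the labels to `nmi()`.
- UMAP coordinates are run-to-run deterministic only under a fixed seed and
  single-threaded optimization, which is what `embed_2d()` uses.
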