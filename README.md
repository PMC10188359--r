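# scmultimark

Analysis of **multi-target single-cell chromatin profiling** data —
experiments (antibody-barcoded CUT&Tag-style assays) in which each
deduplicated fragment carries both a cell barcode and the label of the
chromatin target that produced it, so several histone marks are measured
in the *same* single cells. The package is for computational biologists
who have per-target fragment BED files (Cell Ranger convention) and want
QC, cell typing, and cross-mark co-occurrence statistics with a fully
synthetic, ground-truthed test bed.

## What it computes

- **io/QC**: fragment import and validation, deduplication on
  `(chrom, start, end, cell, target)`, the ≥100-unique-fragments-per-target
  cell filter (per-target relaxation supported), strand-aware gene test
  windows (TSS − 1 kb … TES), FRiP and per-peak on-target purity.
- **Barnyard QC**: per-cell species fractions and cross-species collision
  rate — a barcode is a collision when < 90% of its reads come from one
  species.
- **Cell typing (LSI)**: 50-kb binning → top-40% windows → TF-IDF
  (`ln(1 + 10^4·TF·IDF)`) → SVD keeping dimensions with
  `d_j > 0.002 · Σd` → UMAP (visualization) and k-means on the retained
  coordinates → normalized mutual information against known labels;
  simple concatenation-based multi-target integration.
- **Per-cell Poisson enrichment** (the core statistic): for cell *i*, gene
  and target, with observed overlap count *r*, median fragment length
  *L_i*, per-cell fragment count *f_i*,

      x = r·L_i / L_gene,   μ_i = L_i·f_i / L_genome,
      p = P( Poisson(μ_i) ≥ x )

  evaluated at `ceiling(x)` (continuous-tail option available), BH-corrected
  at q < 0.01 over all observed (cell, gene, target) combinations.
- **Co-occurrence**: per-cell target read proportions, per-cell bivalency
  scores (repressive + active mark enriched in the same gene of the same
  cell), and per-cell Cramér's V (`V = sqrt(χ²/n)`, 2×2, no continuity
  correction) between target pairs.
- **Comparisons**: median low/high split on a target's read share with
  per-gene `LFC = log2((mean_low+1)/(mean_high+1))` and two-sided Welch
  t-tests; trajectory misassignment frequency and Kendall-style pseudotime
  inversion frequency.
- **Synthetic data**: `simulate_experiment()` / `simulate_species_mix()`
  generate multi-type, multi-target fragment datasets with planted
  enrichment (including bivalent genes), log-normal depth variation and
  cross-species doublets, plus truth tables; everything downstream is
  testable against planted ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → QC → typing → co-occurrence → comparisons), writing tables
under `results/`. Running

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_qc_species_mixing.R
Rscript analysis/03_cell_typing.R
Rscript analysis/04_cooccurrence.R
Rscript analysis/05_trajectory_groups.R
```

prints, among other things:

```
collision rate: 9.9% (197/2000) at the <90% rule
H3K27me3  retained 40 dims, k-means(2) NMI = 1.0000
integrated (3 targets)        NMI = 1.0000
enrichment scan: 20251 observed combinations, 5055 significant (q < 0.01)
  planted recall 95.4% (5300 combos), null flag rate 0.00%
mean bivalency score: differentiated 0.0, stemlike 6890.5
Cramer's V H3K27me3-H3K4me2   differentiated 0.218, stemlike 0.345
pseudotime inversion frequency per trajectory: ... ectoderm 0.045 ...
```

Reading: the simulated 10% barnyard doublet rate is recovered as 9.9%
under the <90% rule; both planted cell types are perfectly separated by
LSI + k-means (NMI 1.0); 95% of planted (cell, gene, target) enrichments
are recalled at q < 0.01 with essentially no null calls; only the
"stemlike" type — the one with planted repressive+active co-marked genes —
gets nonzero bivalency scores and the higher H3K27me3–H3K4me2 Cramér's V;
and pseudotime inversion frequencies sit at a few percent for the noise
level simulated, reaching 0 when the noise is removed.

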