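library(data.table)

# n short test genes, evenly spaced on one chromosome
make_genes <- function(n = 40L, len = 500L, spacing = 25000L,
                       offset = 5000L, chrom = "chr1", strand = "+") {
  data.table(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             strand = strand,
             start = as.integer((seq_len(n) - 1L) * spacing + offset),
             end = as.integer((seq_len(n) - 1L) * spacing + offset + len))
}

# study conditions for planted-enrichment recovery: 500-bp genes on a 1-Mb
# genome, ~2,000 fragments per cell, multiplier 20 on 10 of 40 genes
planted_sim <- function(seed, multiplier = 20, n_cells = 50L,
                        n_planted = 10L) {
  genes <- make_genes()
  emap <- if (n_planted > 0L) {
    data.table(cell_type = "A", target = "H3K27me3",
               gene_id = genes$gene_id[seq_len(n_planted)],
               multiplier = multiplier)
  } else {
    NULL
  }
  cfg <- sim_config(n_cells, "A", "H3K27me3", genes, 1e6, emap,
                    background_rate = 2e-3, seed = seed)
  list(cfg = cfg, genes = genes,
       windows = gene_windows(genes, upstream = 100L))
}

# two cell types with disjoint (or shared) planted windows on a 10-Mb genome
two_type_sim <- function(seed, informative = TRUE, n_per_type = 200L,
                         target = "mark1") {
  genes <- data.table(
    gene_id = sprintf("g%03d", 1:60), chrom = "chr1", strand = "+",
    start = as.integer(c((0:29) * 1e5 + 2e4, 5e6 + (0:29) * 1e5 + 2e4)),
    end = as.integer(c((0:29) * 1e5 + 3e4, 5e6 + (0:29) * 1e5 + 3e4)))
  gene_b <- if (informative) genes$gene_id[31:60] else genes$gene_id[1:30]
  emap <- rbind(
    data.table(cell_type = "A", target = target,
               gene_id = genes$gene_id[1:30], multiplier = 20),
    data.table(cell_type = "B", target = target,
               gene_id = gene_b, multiplier = 20))
  cfg <- sim_config(n_per_type, c("A", "B"), target, genes, 1e7, emap,
                    background_rate = 5e-5, seed = seed)
  sim <- simulate_experiment(cfg)
  list(sim = sim, genes = genes,
       genome_sizes = data.frame(chrom = "chr1", length = 1e7))
}

type_labels <- function(sim, cells) {
  sim$truth$cells$cell_type[match(cells, sim$truth$cells$cell)]
}

# independent upper Poisson tail: direct pmf summation in log space
pois_tail_oracle <- function(k, mu) {
  if (k <= 0) return(1)
  j <- seq.int(k, k + 400L)
  sum(exp(-mu + j * log(mu) - lgamma(j + 1)))
}

# tiny hand-buildable fragment table
frag_row <- function(chrom, start, end, cell, target, dup = 1L) {
  fragments(chrom, start, end, cell, target, dup)
}
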