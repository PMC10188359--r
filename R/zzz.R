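# silence R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "chrom", "start", "end", "cell", "target", "dup_count", "n_unique",
  "median_len", "pass", "gene_id", "L_gene", "window_start", "window_end",
  "strand", "in_peak", "species", "n", "n_total", "top_species",
  "max_fraction", "f_total", "norm_count", "enriched", "rep_on", "act_on",
  "score", "fraction", "correct", "trajectory", "n_incorrect", "frequency",
  "mis", "timepoint", "pseudotime", "cell_type", "idx", "depth_factor",
  "n_fragments", "multiplier", "ng", "x", "mu", "p", "q"
))
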