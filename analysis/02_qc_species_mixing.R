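#!/usr/bin/env Rscript
# Fragment import, deduplication, per-cell QC at the 100-unique-fragment
# cutoff, and barnyard collision rates at the <90% single-species rule.
# Reads results/data/, writes results/qc/.

suppressMessages({
  library(scmultimark)
  library(data.table)
})

out_dir <- "results/qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
targets <- c("H3K27me3", "H3K4me2", "H3K36me3")

frags <- rbindlist(lapply(targets, function(t)
  read_fragments(file.path("results/data/main",
                           paste0("fragments_", t, ".bed")), t)))
frags <- deduplicate(frags)
cat(sprintf("read %d unique fragments across %d targets\n",
            nrow(frags), length(targets)))

## QC: all three targets required at >= 100 unique fragments, with the
## low-yield H3K36me3 cutoff relaxed to 30 to keep cells for typing.
qc <- cell_qc(frags, targets, min_unique = 100L, relax = c(H3K36me3 = 30))
fwrite(qc, file.path(out_dir, "cell_qc.tsv"), sep = "\t")
cat(sprintf("QC: %d of %d cells pass (H3K36me3 relaxed to 30)\n",
            sum(qc$pass), nrow(qc)))
strict <- cell_qc(frags, targets, min_unique = 100L)
cat(sprintf("    (%d would pass at a strict 100 for all targets)\n",
            sum(strict$pass)))

## Barnyard collision rate.
mixf <- read_fragments("results/data/barnyard/fragments_H3K27me3.bed",
                       "H3K27me3")
prof <- species_fractions(deduplicate(mixf))
cr <- collision_rate(prof, threshold = 0.90)
fwrite(prof, file.path(out_dir, "species_profiles.tsv"), sep = "\t")
jsonlite::write_json(
  list(n_collisions = cr$n_collisions, n_cells = cr$n_cells,
       rate = cr$rate, rate_pct = cr$rate_pct),
  file.path(out_dir, "collision_rate.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("collision rate: %.1f%% (%d/%d) at the <90%% rule\n",
            cr$rate_pct, cr$n_collisions, cr$n_cells))
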