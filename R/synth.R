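#' Simulation configuration for multi-target fragment data
#'
#' Describes a synthetic multi-cell-type, multi-target single-cell
#' tagmentation experiment on a single simulated chromosome: background
#' fragments fall uniformly over the genome at `background_rate` fragments
#' per bp per cell (in expectation), per-cell depth varies by a log-normal
#' factor, and genes listed in `enrichment_map` accumulate fragments at
#' `multiplier` times the background rate in the cells of the given type.
#'
#' @param n_cells_per_type Cells to simulate per cell type (>= 0).
#' @param cell_types Character vector of cell-type labels (non-empty).
#' @param targets Character vector of chromatin-target labels (non-empty).
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end`; intervals must lie within `[0, genome_length)`.
#' @param genome_length Simulated chromosome length in bp.
#' @param enrichment_map data.frame with `cell_type`, `target`, `gene_id`,
#'   `multiplier` (>= 1); which genes are planted enriched, where.
#' @param background_rate Expected background fragments per bp per cell
#'   per target (before depth scaling).
#' @param fragment_length_mean,fragment_length_sd Fragment length model in
#'   bp (normal, truncated to \[30, 1000\]).
#' @param depth_lognormal_mu,depth_lognormal_sigma Per-cell depth factor is
#'   `exp(N(mu, sigma))`; defaults give median factor 1 with realistic
#'   heavy-tailed spread.
#' @param target_scale Optional named per-target depth multipliers
#'   (default 1 for every target), modelling unequal assay efficiencies.
#' @param chrom Chromosome name (default `"chr1"`).
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells_per_type, cell_types, targets, genes,
                       genome_length, enrichment_map = NULL,
                       background_rate = 5e-5,
                       fragment_length_mean = 200,
                       fragment_length_sd = 75,
                       depth_lognormal_mu = 0,
                       depth_lognormal_sigma = 0.5,
                       target_scale = NULL,
                       chrom = "chr1",
                       seed = 1L) {
  if (length(cell_types) == 0L) stop("at least one cell type is required")
  if (length(targets) == 0L) stop("at least one target is required")
  if (n_cells_per_type < 0L) stop("n_cells_per_type must be >= 0")
  stopifnot(genome_length > 0, background_rate > 0)
  genes <- as.data.table(genes)
  if (nrow(genes) > 0L) {
    stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                    names(genes)))
    if (any(genes$start < 0L) || any(genes$end > genome_length)) {
      stop("gene intervals must lie within [0, genome_length)")
    }
    if (any(genes$end <= genes$start)) stop("gene end must be > start")
  }
  if (is.null(enrichment_map)) {
    enrichment_map <- data.table(cell_type = character(),
                                 target = character(),
                                 gene_id = character(),
                                 multiplier = numeric())
  }
  emap <- as.data.table(enrichment_map)
  if (nrow(emap) > 0L) {
    stopifnot(all(c("cell_type", "target", "gene_id", "multiplier") %in%
                    names(emap)))
    if (any(emap$multiplier < 1)) stop("multipliers must be >= 1")
    if (any(!emap$cell_type %in% cell_types)) {
      stop("enrichment_map references unknown cell type")
    }
    if (any(!emap$target %in% targets)) {
      stop("enrichment_map references unknown target")
    }
    if (nrow(genes) == 0L || any(!emap$gene_id %in% genes$gene_id)) {
      stop("enrichment_map references unknown gene")
    }
  }
  if (is.null(target_scale)) {
    target_scale <- stats::setNames(rep(1, length(targets)), targets)
  }
  stopifnot(all(targets %in% names(target_scale)), all(target_scale > 0))
  structure(list(n_cells_per_type = as.integer(n_cells_per_type),
                 cell_types = cell_types, targets = targets,
                 genes = genes, genome_length = as.numeric(genome_length),
                 enrichment_map = emap,
                 background_rate = background_rate,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 depth_lognormal_mu = depth_lognormal_mu,
                 depth_lognormal_sigma = depth_lognormal_sigma,
                 target_scale = target_scale,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-normal fragment lengths in [30, 1000] bp
sim_lengths <- function(n, mean, sd) {
  len <- round(stats::rnorm(n, mean, sd))
  as.integer(pmin(pmax(len, 30), 1000))
}

# build fragments from midpoints: start = mid - len %/% 2, clipped to genome
frags_from_midpoints <- function(mid, len, genome_length, chrom, cell,
                                 target) {
  start <- as.integer(pmax(floor(mid) - len %/% 2L, 0L))
  end <- start + len
  shift <- pmax(end - as.integer(genome_length), 0L)
  start <- start - shift
  end <- end - shift
  start <- pmax(start, 0L)
  data.table(chrom = chrom, start = start, end = end, cell = cell,
             target = target, dup_count = 1L)
}

#' Simulate a multi-target single-cell fragment experiment
#'
#' For each cell: a log-normal depth factor scales all its fragment rates;
#' per target, background fragment midpoints are drawn uniformly over the
#' genome at the configured rate (Poisson counts), and each planted gene
#' receives additional fragments so its interval accumulates signal at
#' `multiplier` times background. Fragment starts derive from midpoints
#' (symmetric overlap behavior). Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `fragments` (deduplicated fragment table) and `truth`
#'   (list: `cells` with `cell`, `cell_type`, `species`, `is_doublet`,
#'   `depth_factor`, `n_fragments`; `planted` with one row per planted
#'   (cell, gene, target) and its multiplier).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per <- config$n_cells_per_type
  if (n_per == 0L) {
    truth_cells <- data.table(cell = character(), cell_type = character(),
                              species = character(), is_doublet = logical(),
                              depth_factor = numeric(),
                              n_fragments = integer())
    planted <- data.table(cell = character(), gene_id = character(),
                          target = character(), multiplier = numeric())
    return(list(fragments = empty_fragments(),
                truth = list(cells = truth_cells, planted = planted)))
  }
  cells <- data.table(
    cell_type = rep(config$cell_types, each = n_per),
    idx = rep(seq_len(n_per), times = length(config$cell_types)))
  cells[, cell := sprintf("%s_c%04d", cell_type, idx)]
  cells[, depth_factor := stats::rlnorm(.N, config$depth_lognormal_mu,
                                        config$depth_lognormal_sigma)]
  genes <- config$genes
  emap <- config$enrichment_map
  frag_list <- list()
  planted_list <- list()
  for (ci in seq_len(nrow(cells))) {
    cc <- cells$cell[ci]
    ct <- cells$cell_type[ci]
    s <- cells$depth_factor[ci]
    for (tgt in config$targets) {
      rate <- config$background_rate * s * config$target_scale[[tgt]]
      n_bg <- stats::rpois(1L, rate * config$genome_length)
      mids <- stats::runif(n_bg, 0, config$genome_length)
      lens <- sim_lengths(n_bg, config$fragment_length_mean,
                          config$fragment_length_sd)
      frag_list[[length(frag_list) + 1L]] <-
        frags_from_midpoints(mids, lens, config$genome_length,
                             config$chrom, cc, tgt)
      planted_here <- emap[emap$cell_type == ct & emap$target == tgt, ]
      if (nrow(planted_here) > 0L) {
        gsub <- merge(planted_here, genes[, .(gene_id, start, end)],
                      by = "gene_id")
        for (gi in seq_len(nrow(gsub))) {
          glen <- gsub$end[gi] - gsub$start[gi]
          n_extra <- stats::rpois(1L, rate * glen *
                                    (gsub$multiplier[gi] - 1))
          if (n_extra > 0L) {
            gmids <- stats::runif(n_extra, gsub$start[gi], gsub$end[gi])
            glens <- sim_lengths(n_extra, config$fragment_length_mean,
                                 config$fragment_length_sd)
            frag_list[[length(frag_list) + 1L]] <-
              frags_from_midpoints(gmids, glens, config$genome_length,
                                   config$chrom, cc, tgt)
          }
        }
        planted_list[[length(planted_list) + 1L]] <-
          data.table(cell = cc, gene_id = gsub$gene_id, target = tgt,
                     multiplier = gsub$multiplier)
      }
    }
  }
  frags <- deduplicate(rbindlist(frag_list))
  planted <- if (length(planted_list) > 0L) {
    rbindlist(planted_list)
  } else {
    data.table(cell = character(), gene_id = character(),
               target = character(), multiplier = numeric())
  }
  depth <- frags[, .(n_fragments = .N), by = cell]
  truth_cells <- merge(cells[, .(cell, cell_type, depth_factor)], depth,
                       by = "cell", all.x = TRUE)
  truth_cells[is.na(n_fragments), n_fragments := 0L]
  truth_cells[, `:=`(species = "synthetic", is_doublet = FALSE)]
  data.table::setcolorder(truth_cells,
                          c("cell", "cell_type", "species", "is_doublet",
                            "depth_factor", "n_fragments"))
  setorder(truth_cells, cell)
  list(fragments = frags,
       truth = list(cells = truth_cells[], planted = planted))
}

#' Simulate a cross-species (barnyard) mixing experiment
#'
#' Each barcode is, with probability `doublet_rate`, a cross-species
#' doublet whose reads split near 50:50 between species
#' (`Binomial(reads, 0.5)`); otherwise it is a single-species cell whose
#' reads come from its own species apart from a small (0.1 percent
#' per-read) cross-contamination. Species is encoded in the chromosome
#' name prefix (`hg19_chr1` / `mm10_chr1`).
#'
#' @param n_cells Number of barcodes.
#' @param doublet_rate Probability a barcode is a cross-species doublet,
#'   in \[0, 1\].
#' @param reads_per_cell Unique fragments per barcode (> 0).
#' @param seed Integer seed.
#' @param target Target label carried by the fragments.
#' @param chrom_length Length of each species' simulated chromosome.
#' @return List with `fragments` and `truth` (`data.table`: `cell`,
#'   `species` (`"human"`, `"mouse"` or `"mixed"`), `is_doublet`).
#' @export
simulate_species_mix <- function(n_cells, doublet_rate, reads_per_cell,
                                 seed = 1L, target = "H3K27me3",
                                 chrom_length = 1e7) {
  if (doublet_rate < 0 || doublet_rate > 1) {
    stop("doublet_rate must be in [0, 1]")
  }
  if (reads_per_cell <= 0L) stop("reads_per_cell must be positive")
  stopifnot(n_cells >= 0L)
  set.seed(seed)
  contamination <- 0.001
  chroms <- c(human = "hg19_chr1", mouse = "mm10_chr1")
  if (n_cells == 0L) {
    return(list(fragments = empty_fragments(),
                truth = data.table(cell = character(), species = character(),
                                   is_doublet = logical())))
  }
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  is_doublet <- stats::runif(n_cells) < doublet_rate
  own <- sample(c("human", "mouse"), n_cells, replace = TRUE)
  n_human <- integer(n_cells)
  n_human[is_doublet] <- stats::rbinom(sum(is_doublet), reads_per_cell, 0.5)
  singlet <- !is_doublet
  n_cross <- stats::rbinom(sum(singlet), reads_per_cell, contamination)
  n_human[singlet] <- ifelse(own[singlet] == "human",
                             reads_per_cell - n_cross, n_cross)
  frag_list <- lapply(seq_len(n_cells), function(i) {
    nh <- n_human[i]
    nm <- reads_per_cell - nh
    sp <- c(rep("human", nh), rep("mouse", nm))
    mids <- stats::runif(reads_per_cell, 0, chrom_length)
    lens <- sim_lengths(reads_per_cell, 200, 75)
    frags_from_midpoints(mids, lens, chrom_length, chroms[sp],
                         cell_ids[i], target)
  })
  frags <- deduplicate(rbindlist(frag_list))
  truth <- data.table(cell = cell_ids,
                      species = ifelse(is_doublet, "mixed", own),
                      is_doublet = is_doublet)
  setorder(truth, cell)
  list(fragments = frags, truth = truth[])
}

#' Write a simulated dataset to disk
#'
#' Writes one coordinate-sorted, headerless 5-column fragment BED per
#' target (`fragments_<target>.bed`) plus tab-separated truth tables with
#' headers. Round-trips losslessly through [read_fragments()].
#'
#' @param fragments Fragment table.
#' @param truth Truth object from [simulate_experiment()] (list with
#'   `cells`/`planted`) or [simulate_species_mix()] (a single table).
#' @param directory Output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_dataset <- function(fragments, truth, directory) {
  fragments <- validate_fragments(fragments)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- character(0)
  for (tgt in sort(unique(fragments$target))) {
    sub <- fragments[fragments$target == tgt,
                     c("chrom", "start", "end", "cell", "dup_count")]
    setorder(sub, chrom, start, end, cell)
    p <- file.path(directory, paste0("fragments_", tgt, ".bed"))
    fwrite(sub, p, sep = "\t", col.names = FALSE)
    paths[paste0("fragments_", tgt)] <- p
  }
  if (is.data.frame(truth)) truth <- list(cells = truth)
  for (nm in names(truth)) {
    p <- file.path(directory, paste0("truth_", nm, ".tsv"))
    fwrite(as.data.table(truth[[nm]]), p, sep = "\t", col.names = TRUE)
    paths[paste0("truth_", nm)] <- p
  }
  paths
}
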