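#' Per-cell species composition for barnyard experiments
#'
#' In a barnyard (cross-species mixing) experiment, each chromosome name
#' encodes its species (e.g. `hg19_chr1` vs `mm10_chr1`). Unique fragment
#' counts are pooled across targets per cell, and the fraction of reads from
#' the majority species is computed; barcodes capturing two cells show a
#' mixed profile.
#'
#' @param frags Deduplicated fragment table.
#' @param species_of Either `NULL` (species inferred as the reference-name
#'   prefix before the first underscore, e.g. `"hg19"`) or a named character
#'   vector mapping chromosome name to species label; an unmapped chromosome
#'   is an error.
#' @return `data.table` with one row per cell: `cell`, `n_total`,
#'   `top_species`, `max_fraction`.
#' @export
species_fractions <- function(frags, species_of = NULL) {
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0L) {
    return(data.table(cell = character(), n_total = integer(),
                      top_species = character(), max_fraction = numeric()))
  }
  chroms <- unique(frags$chrom)
  if (is.null(species_of)) {
    species_map <- sub("_.*$", "", chroms)
    names(species_map) <- chroms
  } else {
    unmapped <- setdiff(chroms, names(species_of))
    if (length(unmapped) > 0L) {
      stop("chromosome(s) not mapped to a species: ",
           paste(unmapped, collapse = ", "))
    }
    species_map <- species_of
  }
  dt <- copy_dt(frags)[, species := species_map[chrom]]
  counts <- dt[, .(n = .N), by = .(cell, species)]
  prof <- counts[, {
    tot <- sum(n)
    i <- which.max(n)
    .(n_total = tot, top_species = species[i],
      max_fraction = n[i] / tot)
  }, by = cell]
  setorder(prof, cell)
  prof[]
}

#' Cross-species collision rate
#'
#' A barcode is called a collision (two cells of different species captured
#' together) when strictly less than `threshold` of its reads come from a
#' single species. The rate is the fraction of profiled barcodes called
#' collisions; note this undercounts same-species doublets, which a
#' barnyard design cannot see.
#'
#' @param profiles Output of [species_fractions()].
#' @param threshold Majority-species fraction below which a cell is a
#'   collision (default 0.90; strict `<`).
#' @return List with `n_collisions`, `n_cells`, `rate` (raw fraction),
#'   `rate_pct` (percentage rounded half-up to one decimal for display),
#'   and `collision` (logical per input row).
#' @export
collision_rate <- function(profiles, threshold = 0.90) {
  profiles <- as.data.table(profiles)
  if (nrow(profiles) == 0L) stop("no species profiles supplied")
  if (!"max_fraction" %in% names(profiles)) {
    stop("profiles must carry a max_fraction column")
  }
  collision <- profiles$max_fraction < threshold
  n_coll <- sum(collision)
  n_cells <- nrow(profiles)
  rate <- n_coll / n_cells
  list(n_collisions = n_coll, n_cells = n_cells, rate = rate,
       rate_pct = round_half_up(100 * rate, 1L), collision = collision)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
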