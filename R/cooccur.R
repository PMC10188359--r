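#' Count fragment-gene window overlaps
#'
#' For every (cell, gene, target) combination with at least one overlap,
#' counts the unique fragments of that cell and target overlapping the gene
#' window by >= 1 bp. A fragment overlapping two gene windows counts for
#' both.
#'
#' @param frags Deduplicated, QC-passed fragment table.
#' @param windows Gene windows from [gene_windows()].
#' @return `data.table` with columns `cell`, `gene_id`, `target`, `r`
#'   (observed overlap count). Combinations with zero overlaps are omitted.
#' @export
count_gene_overlaps <- function(frags, windows) {
  frags <- validate_fragments(frags)
  windows <- as.data.table(windows)
  if (nrow(windows) == 0L) stop("empty gene window list")
  if (nrow(frags) == 0L) {
    return(data.table(cell = character(), gene_id = character(),
                      target = character(), r = integer()))
  }
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(windows$window_start + 1L, windows$window_end))
  hits <- GenomicRanges::findOverlaps(win_gr, frag_granges(frags))
  if (length(hits) == 0L) {
    return(data.table(cell = character(), gene_id = character(),
                      target = character(), r = integer()))
  }
  dt <- data.table(gene_id = windows$gene_id[S4Vectors_from(hits)],
                   cell = frags$cell[S4Vectors_to(hits)],
                   target = frags$target[S4Vectors_to(hits)])
  out <- dt[, .(r = .N), by = .(cell, gene_id, target)]
  setorder(out, cell, gene_id, target)
  out[]
}

#' Per-cell Poisson fragment-enrichment test
#'
#' Tests whether a cell's observed fragment accumulation over a gene window
#' exceeds its genome-wide expectation. With `r` observed overlapping
#' fragments, per-cell median fragment length `L_i`, per-cell fragment count
#' `f_i`, gene window length `L_gene` and reference length `L_genome`, the
#' depth-scaled observation is `x = r * L_i / L_gene` and the expected
#' per-bp coverage is `mu_i = L_i * f_i / L_genome`; the p-value is the
#' upper Poisson tail `P(X >= x | mu_i)`. Since Poisson support is integer,
#' the default evaluates the tail at `ceiling(x)`; `tail = "continuous"`
#' instead uses the regularized upper incomplete gamma function at `x`.
#' `r = 0` gives `p = 1`. Tails are computed in log space internally, so
#' very small p-values do not underflow to 0 until below double range.
#'
#' @param r Observed overlap counts (vectorized).
#' @param median_len Median fragment length `L_i` in bp (> 0).
#' @param n_frags Fragments mapped in the cell, `f_i` (> 0).
#' @param gene_len Gene window length `L_gene` in bp (> 0).
#' @param genome_len Reference genome length `L_genome` in bp (> 0).
#' @param tail `"ceiling"` (default) or `"continuous"`.
#' @return `data.table` with columns `r`, `x`, `mu`, `p`.
#' @export
poisson_test <- function(r, median_len, n_frags, gene_len, genome_len,
                         tail = c("ceiling", "continuous")) {
  tail <- match.arg(tail)
  n <- length(r)
  median_len <- rep_len(median_len, n)
  n_frags <- rep_len(n_frags, n)
  gene_len <- rep_len(gene_len, n)
  genome_len <- rep_len(genome_len, n)
  if (any(r < 0)) stop("r must be >= 0")
  if (any(median_len <= 0) || any(gene_len <= 0) || any(genome_len <= 0)) {
    stop("lengths must be positive")
  }
  if (any(n_frags <= 0)) stop("n_frags must be positive")
  x <- r * median_len / gene_len
  mu <- median_len * n_frags / genome_len
  p <- if (tail == "ceiling") {
    k <- ceiling(x)
    ifelse(k <= 0, 1, stats::ppois(k - 1, mu, lower.tail = FALSE))
  } else {
    # P(Poisson(mu) >= k) == pgamma(mu, k); extends to non-integer x
    ifelse(x <= 0, 1, stats::pgamma(mu, x, lower.tail = TRUE))
  }
  data.table(r = r, x = x, mu = mu, p = p)
}

#' Benjamini-Hochberg adjustment with a significance call
#'
#' Standard BH step-up (monotone) q-values over one test family, with
#' significance declared at `q < alpha` (strict).
#'
#' @param pvals Numeric p-values in (0, 1\].
#' @param alpha FDR level (default 0.01).
#' @return List with `q` (adjusted p-values) and `significant` (logical).
#' @export
bh_adjust <- function(pvals, alpha = 0.01) {
  if (length(pvals) == 0L) return(list(q = numeric(0), significant = logical(0)))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Full per-cell, per-gene, per-target enrichment scan
#'
#' Runs the Poisson enrichment test over every observed (cell, gene, target)
#' overlap in one pass: per-cell, per-target fragment statistics (`L_i`,
#' `f_i`) are computed from the fragment table, overlaps counted, p-values
#' derived and BH-corrected over the whole family of observed combinations,
#' and per-cell normalized counts (scaled to `norm_scale` total per cell and
#' target) attached for downstream heat maps and scores.
#'
#' @param frags Deduplicated, QC-passed fragment table.
#' @param windows Gene windows from [gene_windows()].
#' @param genome_length Reference genome length in bp (sum of the
#'   genome-sizes table).
#' @param alpha FDR level for the enrichment call (default 0.01).
#' @param tail Tail evaluation rule, see [poisson_test()].
#' @param pool_targets If `TRUE`, `L_i` and `f_i` pool fragments across
#'   targets within the cell; default `FALSE` (per-target statistics, since
#'   each target is a separate assay sharing the cell).
#' @param norm_scale Per-cell, per-target total for normalized counts
#'   (default 1e4).
#' @return A `cooccurrence` `data.table`: `cell`, `gene_id`, `target`, `r`,
#'   `x`, `mu`, `p`, `q`, `enriched`, `norm_count`; attribute `alpha`.
#' @export
test_enrichment <- function(frags, windows, genome_length, alpha = 0.01,
                            tail = c("ceiling", "continuous"),
                            pool_targets = FALSE, norm_scale = 1e4) {
  tail <- match.arg(tail)
  stopifnot(genome_length > 0)
  frags <- validate_fragments(frags)
  counts <- count_gene_overlaps(frags, windows)
  stats_ct <- cell_stats(frags)
  if (pool_targets) {
    pooled <- frags[, .(n_unique = .N,
                        median_len = as.numeric(median(end - start))),
                    by = cell]
    stats_use <- merge(counts[, .(cell, gene_id, target, r)],
                       pooled, by = "cell")
  } else {
    stats_use <- merge(counts, stats_ct, by = c("cell", "target"))
  }
  windows <- as.data.table(windows)
  stats_use <- merge(stats_use, windows[, .(gene_id, L_gene)], by = "gene_id")
  if (nrow(stats_use) == 0L) {
    out <- data.table(cell = character(), gene_id = character(),
                      target = character(), r = integer(), x = numeric(),
                      mu = numeric(), p = numeric(), q = numeric(),
                      enriched = logical(), norm_count = numeric())
    data.table::setattr(out, "alpha", alpha)
    data.table::setattr(out, "class", c("cooccurrence", class(out)))
    return(out)
  }
  pt <- poisson_test(stats_use$r, stats_use$median_len, stats_use$n_unique,
                     stats_use$L_gene, genome_length, tail = tail)
  stats_use[, `:=`(x = pt$x, mu = pt$mu, p = pt$p)]
  adj <- bh_adjust(stats_use$p, alpha = alpha)
  stats_use[, `:=`(q = adj$q, enriched = adj$significant)]
  # normalized count: fragments per norm_scale total in that cell and target
  per_ct <- stats_ct[, .(cell, target, f_total = n_unique)]
  stats_use <- merge(stats_use, per_ct, by = c("cell", "target"))
  stats_use[, norm_count := r / f_total * norm_scale]
  out <- stats_use[, .(cell, gene_id, target, r, x, mu, p, q, enriched,
                       norm_count)]
  setorder(out, cell, gene_id, target)
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "class", c("cooccurrence", class(out)))
  out
}

#' Per-cell target read proportions
#'
#' The share of each cell's unique reads contributed by each profiled
#' target; relative target abundances are directly measurable because each
#' fragment carries its target barcode.
#'
#' @param frags Deduplicated, QC-passed fragment table.
#' @return `data.table` with `cell`, `target`, `n_unique`, `fraction`;
#'   fractions sum to 1 within each cell.
#' @export
target_proportions <- function(frags) {
  st <- cell_stats(frags)
  if (nrow(st) == 0L) {
    return(data.table(cell = character(), target = character(),
                      n_unique = integer(), fraction = numeric()))
  }
  st[, fraction := n_unique / sum(n_unique), by = cell]
  setorder(st, cell, target)
  st[]
}

#' Per-cell bivalency score
#'
#' For each cell, sums the normalized counts over genes in a "bivalent"
#' context: genes where the repressive mark and at least one active mark are
#' both flagged enriched in that same cell. Counts from the repressive
#' target and from each enriched active target in qualifying genes
#' contribute to the sum. High scores mark cells carrying poised
#' (repressive + active) chromatin at the same genes.
#'
#' @param cooc A `cooccurrence` table from [test_enrichment()].
#' @param repressive Repressive target label (e.g. `"H3K27me3"`).
#' @param active Character vector of active target labels
#'   (e.g. `c("H3K4me2", "H3K36me3")`).
#' @return `data.table` with `cell`, `score` (0 for cells with no bivalent
#'   gene), covering every cell in `cooc`.
#' @export
bivalency_score <- function(cooc, repressive, active) {
  cooc <- as.data.table(cooc)
  known <- unique(cooc$target)
  unknown <- setdiff(c(repressive, active), known)
  if (length(unknown) > 0L && nrow(cooc) > 0L) {
    stop("unknown target label(s): ", paste(unknown, collapse = ", "))
  }
  cells <- unique(cooc$cell)
  if (length(cells) == 0L) {
    return(data.table(cell = character(), score = numeric()))
  }
  enr <- cooc[cooc$enriched == TRUE, ]
  score <- data.table(cell = cells, score = 0)
  if (nrow(enr) > 0L) {
    flags <- enr[, .(rep_on = any(target == repressive),
                     act_on = any(target %in% active)),
                 by = .(cell, gene_id)]
    biv <- flags[rep_on & act_on, .(cell, gene_id)]
    if (nrow(biv) > 0L) {
      contrib <- merge(enr[target %in% c(repressive, active)], biv,
                       by = c("cell", "gene_id"))
      ssum <- contrib[, .(score = sum(norm_count)), by = cell]
      score <- merge(data.table(cell = cells), ssum, by = "cell",
                     all.x = TRUE)
      score[is.na(score), score := 0]
    }
  }
  setorder(score, cell)
  score[]
}

# closed-form 2x2 chi-square without continuity correction
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(NA_real_)
  n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
}

#' Cramer's V of co-enrichment between two targets in one cell
#'
#' Over a gene universe, cross-tabulates per-gene enrichment flags for two
#' targets in one cell into a 2x2 table and reports
#' `V = sqrt(chi^2 / n)` (the 2x2 special case of Cramer's V), with the
#' chi-square computed without continuity correction. A table with any zero
#' marginal is degenerate: `V = 0` with `degenerate = TRUE`.
#'
#' @param cooc A `cooccurrence` table from [test_enrichment()].
#' @param cell Cell barcode.
#' @param target_a,target_b The two target labels.
#' @param genes Gene universe (default: all genes in `cooc`). Genes without
#'   data in the cell count as not-enriched for both targets.
#' @return List of class `association_result`: `cell`, `target_a`,
#'   `target_b`, `table` (2x2), `n`, `chisq`, `v`, `degenerate`.
#' @export
cramers_v <- function(cooc, cell, target_a, target_b, genes = NULL) {
  cooc <- as.data.table(cooc)
  if (is.null(genes)) genes <- unique(cooc$gene_id)
  genes <- unique(as.character(genes))
  sel_cell <- cell
  sub <- cooc[cooc$cell == sel_cell & cooc$gene_id %in% genes, ]
  if (length(unique(sub$gene_id)) < 2L) {
    stop("cell ", cell, " has data for fewer than 2 genes")
  }
  ea <- unique(sub$gene_id[sub$target == target_a & sub$enriched])
  eb <- unique(sub$gene_id[sub$target == target_b & sub$enriched])
  fa <- genes %in% ea
  fb <- genes %in% eb
  a <- sum(fa & fb); b <- sum(fa & !fb); c <- sum(!fa & fb)
  d <- sum(!fa & !fb)
  n <- length(genes)
  chi2 <- chisq_2x2(a, b, c, d)
  degenerate <- is.na(chi2)
  v <- if (degenerate) 0 else sqrt(chi2 / n)
  structure(list(cell = cell, target_a = target_a, target_b = target_b,
                 table = matrix(c(a, c, b, d), 2L, 2L,
                                dimnames = list(paste0(target_a, c("+", "-")),
                                                paste0(target_b, c("+", "-")))),
                 n = n, chisq = if (degenerate) 0 else chi2, v = v,
                 degenerate = degenerate),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Cramer's V (%s vs %s, cell %s): V = %.4f over %d genes%s\n",
              x$target_a, x$target_b, x$cell, x$v, x$n,
              if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}

#' Cramer's V for every cell
#'
#' Vectorized convenience wrapper around [cramers_v()]; cells with fewer
#' than 2 genes with data are skipped.
#'
#' @inheritParams cramers_v
#' @return `data.table` with `cell`, `n`, `chisq`, `v`, `degenerate`.
#' @export
cramers_v_cells <- function(cooc, target_a, target_b, genes = NULL) {
  cooc <- as.data.table(cooc)
  cells <- unique(cooc$cell)
  n_genes_cell <- cooc[, .(ng = length(unique(gene_id))), by = cell]
  eligible <- n_genes_cell$cell[n_genes_cell$ng >= 2L]
  res <- lapply(eligible, function(cc)
    cramers_v(cooc, cc, target_a, target_b, genes = genes))
  data.table(cell = eligible,
             n = vapply(res, `[[`, numeric(1L), "n"),
             chisq = vapply(res, `[[`, numeric(1L), "chisq"),
             v = vapply(res, `[[`, numeric(1L), "v"),
             degenerate = vapply(res, `[[`, logical(1L), "degenerate"))
}
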