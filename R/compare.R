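#' Split cells into low/high groups by a target's read share
#'
#' Partitions cells on their per-cell fraction of reads from one target.
#' The default is a median split; cells exactly at the cutoff go to the low
#' group (deterministic tie rule). `method = "quantile"` splits at an
#' arbitrary quantile, `method = "threshold"` at a fixed fraction.
#'
#' @param props Per-cell proportions from [target_proportions()], or any
#'   data.frame with columns `cell`, `target`, `fraction`.
#' @param target Target label to split on.
#' @param method `"median"`, `"quantile"` or `"threshold"`.
#' @param q Quantile for `method = "quantile"` (default 0.5).
#' @param threshold Fixed cutoff for `method = "threshold"`.
#' @return List with `low`, `high` (cell barcode vectors) and `cutoff`.
#' @export
partition_by_fraction <- function(props, target,
                                  method = c("median", "quantile",
                                             "threshold"),
                                  q = 0.5, threshold = NULL) {
  method <- match.arg(method)
  props <- as.data.table(props)
  sel_target <- target
  sub <- props[props$target == sel_target, ]
  if (nrow(sub) < 2L) stop("need at least 2 cells with data for ", target)
  fr <- sub$fraction
  if (length(unique(fr)) == 1L) {
    stop("all fractions identical (", fr[1L], "): no partition possible")
  }
  cutoff <- switch(method,
                   median = stats::median(fr),
                   quantile = stats::quantile(fr, q, names = FALSE),
                   threshold = {
                     if (is.null(threshold)) stop("threshold not supplied")
                     threshold
                   })
  low <- sub$cell[fr <= cutoff]
  high <- sub$cell[fr > cutoff]
  if (length(high) == 0L) stop("no cells above cutoff ", cutoff)
  list(low = low, high = high, cutoff = cutoff)
}

# Welch two-sample two-sided t-test on summary-free vectors
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # zero variance in both groups
    if (m1 == m2) return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = Inf * sign(m1 - m2), df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Differential gene enrichment between two cell groups
#'
#' Per gene, compares per-cell normalized counts of one target between a
#' low and a high group: log fold change
#' `LFC = log2((mean_low + eps) / (mean_high + eps))` and a two-sided
#' (Welch) t-test without multiple-testing correction. Cells without an
#' observed overlap for a gene contribute a zero count.
#'
#' @param cooc A `cooccurrence` table from [test_enrichment()].
#' @param low,high Cell barcode vectors (each >= 2 cells).
#' @param target Target label whose counts are compared.
#' @param eps Pseudocount added to both group means (default 1, on the
#'   normalized-count scale).
#' @param genes Optional gene universe; genes absent from `cooc` are
#'   skipped with a warning.
#' @return `data.table` with `gene_id`, `mean_low`, `mean_high`, `lfc`,
#'   `t_stat`, `p`, `neg_log10_p`, `degenerate`.
#' @export
differential_enrichment <- function(cooc, low, high, target, eps = 1,
                                    genes = NULL) {
  cooc <- as.data.table(cooc)
  if (length(low) < 2L || length(high) < 2L) {
    stop("both groups need at least 2 cells")
  }
  if (length(intersect(low, high)) > 0L) stop("groups overlap")
  sel_target <- target
  sub <- cooc[cooc$target == sel_target, ]
  present <- unique(sub$gene_id)
  if (is.null(genes)) {
    genes <- present
  } else {
    absent <- setdiff(genes, present)
    if (length(absent) > 0L) {
      warning("gene(s) absent from counts, skipped: ",
              paste(utils::head(absent, 5L), collapse = ", "))
      genes <- intersect(genes, present)
    }
  }
  res <- lapply(genes, function(g) {
    gsub <- sub[sub$gene_id == g, ]
    vals <- stats::setNames(gsub$norm_count, gsub$cell)
    xv <- ifelse(low %in% names(vals), vals[low], 0)
    yv <- ifelse(high %in% names(vals), vals[high], 0)
    wt <- welch_t(xv, yv)
    ml <- mean(xv); mh <- mean(yv)
    data.table(gene_id = g, mean_low = ml, mean_high = mh,
               lfc = log2((ml + eps) / (mh + eps)),
               t_stat = wt$t, p = wt$p,
               neg_log10_p = -log10(wt$p),
               degenerate = wt$degenerate)
  })
  rbindlist(res)
}

#' Trajectory misassignment frequency
#'
#' Given inferred trajectory assignments and the correct trajectory for
#' each cell type, the frequency of cells assigned to the wrong trajectory,
#' per correct trajectory and pooled.
#'
#' @param assignments data.frame with columns `cell`, `cell_type`,
#'   `trajectory` (inferred).
#' @param truth_map Named character vector: cell type -> correct trajectory.
#' @return List with `per_trajectory` (`data.table`: `trajectory`, `n`,
#'   `n_incorrect`, `frequency`) and `overall` (pooled frequency).
#' @export
trajectory_assignment_error <- function(assignments, truth_map) {
  dt <- data.table::copy(as.data.table(assignments))
  missing_types <- setdiff(unique(dt$cell_type), names(truth_map))
  if (length(missing_types) > 0L) {
    stop("cell type(s) absent from truth_map: ",
         paste(missing_types, collapse = ", "))
  }
  dt[, correct := truth_map[cell_type]]
  empty <- setdiff(unique(truth_map), dt$correct)
  if (length(empty) > 0L) {
    warning("trajectory with no cells excluded: ",
            paste(empty, collapse = ", "))
  }
  dt[, mis := trajectory != correct]
  per <- dt[, .(n = .N, n_incorrect = sum(mis)),
            by = .(trajectory = correct)]
  per[, frequency := n_incorrect / n]
  setorder(per, trajectory)
  list(per_trajectory = per[],
       overall = sum(per$n_incorrect) / sum(per$n))
}

# pairwise discordance between known timepoints and pseudotime
pairwise_inversion <- function(timepoint, pseudotime) {
  dt_t <- outer(timepoint, timepoint, `-`)
  dt_p <- outer(pseudotime, pseudotime, `-`)
  comparable <- upper.tri(dt_t) & dt_t != 0
  if (!any(comparable)) return(NA_real_)
  s_t <- sign(dt_t[comparable])
  s_p <- sign(dt_p[comparable])
  disc <- ifelse(s_p == 0, 0.5, as.numeric(s_p != s_t))
  sum(disc) / length(disc)
}

#' Pseudotime inversion frequency
#'
#' Over all pairs of cells on the same trajectory with distinct known
#' timepoints, the fraction of pairs whose inferred pseudotime ordering
#' contradicts the known timepoint ordering (a Kendall-style discordance
#' fraction; pseudotime ties count 0.5). Zero means pseudotime is weakly
#' monotone in developmental age; invariant under strictly monotone
#' transformations of pseudotime.
#'
#' @param cells data.frame with columns `pseudotime`, `timepoint`, and
#'   optionally `trajectory` (one group if absent).
#' @return `data.table` with `trajectory`, `n`, `frequency`.
#' @export
inversion_frequency <- function(cells) {
  dt <- data.table::copy(as.data.table(cells))
  if (!all(c("pseudotime", "timepoint") %in% names(dt))) {
    stop("cells needs pseudotime and timepoint columns")
  }
  if (!"trajectory" %in% names(dt)) dt[, trajectory := "all"]
  bad <- dt[, .(ok = length(unique(timepoint)) >= 2L), by = trajectory]
  if (any(!bad$ok)) {
    stop("trajectory with fewer than 2 distinct timepoints: ",
         paste(bad$trajectory[!bad$ok], collapse = ", "))
  }
  out <- dt[, .(n = .N,
                frequency = pairwise_inversion(timepoint, pseudotime)),
            by = trajectory]
  setorder(out, trajectory)
  out[]
}
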