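#' Bin fragments into fixed-width genomic windows
#'
#' Tiles each chromosome with non-overlapping `bin`-bp windows (the final
#' partial window included) and counts, per cell, the unique fragments
#' overlapping each window by at least 1 bp. A fragment spanning a window
#' boundary is counted in every window it touches.
#'
#' @param frags Deduplicated fragment table (QC-passing cells only, by
#'   convention).
#' @param genome_sizes data.frame with columns `chrom`, `length` (bp).
#' @param bin Window size in bp (default 50000, the standard coarse bin for
#'   sparse single-cell chromatin data).
#' @param target Optional single target label to subset to.
#' @return A `count_matrix` object (windows x cells sparse counts) if one
#'   target is present after subsetting, else a named list of them.
#' @export
bin_counts <- function(frags, genome_sizes, bin = 50000L, target = NULL) {
  frags <- validate_fragments(frags)
  gs <- as.data.table(genome_sizes)
  if (!all(c("chrom", "length") %in% names(gs))) {
    stop("genome_sizes needs columns chrom, length")
  }
  if (!is.null(target)) {
    keep_targets <- target
    frags <- frags[frags$target %in% keep_targets, ]
  }
  bad_chrom <- setdiff(unique(frags$chrom), gs$chrom)
  if (length(bad_chrom) > 0L) {
    stop("chromosome(s) absent from genome_sizes: ",
         paste(bad_chrom, collapse = ", "))
  }
  windows <- gs[, {
    ws <- seq.int(0L, max(length - 1L, 0L), by = bin)
    .(start = as.integer(ws), end = as.integer(pmin(ws + bin, length)))
  }, by = chrom]
  setorder(windows, chrom, start)
  targets <- sort(unique(frags$target))
  cells <- sort(unique(frags$cell))
  one_target <- function(tgt) {
    sub <- frags[frags$target == tgt, ]
    tcells <- sort(unique(sub$cell))
    m <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nrow(windows), length(tcells)),
      dimnames = list(paste0(windows$chrom, ":", windows$start, "-",
                             windows$end), tcells))
    if (nrow(sub) > 0L) {
      hits <- GenomicRanges::findOverlaps(bed_granges(windows),
                                          frag_granges(sub))
      if (length(hits) > 0L) {
        wi <- S4Vectors_from(hits)
        ci <- match(sub$cell[S4Vectors_to(hits)], tcells)
        m <- Matrix::sparseMatrix(
          i = wi, j = ci, x = 1,
          dims = c(nrow(windows), length(tcells)),
          dimnames = dimnames(m))
      }
    }
    structure(list(counts = m, windows = copy_dt(windows), bin = bin,
                   target = tgt),
              class = "count_matrix")
  }
  if (length(targets) == 0L) {
    return(one_target(if (is.null(target)) "none" else target[1L]))
  }
  if (length(targets) == 1L) return(one_target(targets))
  stats::setNames(lapply(targets, one_target), targets)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d windows x %d cells (%d-bp bins, target %s)\n",
              nrow(x$counts), ncol(x$counts), x$bin, x$target))
  invisible(x)
}

#' Keep the most-covered windows
#'
#' Retains the `floor(keep_frac * n_windows)` windows with the largest
#' aggregate (row-sum) counts; ties at the cutoff rank are broken by genomic
#' coordinate order so the selection is deterministic. Output windows stay
#' in genomic order.
#'
#' @param m A `count_matrix`.
#' @param keep_frac Fraction of windows to keep, in (0, 1\] (default 0.40).
#' @return A `count_matrix` restricted to the selected windows.
#' @export
select_top_windows <- function(m, keep_frac = 0.40) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.numeric(keep_frac) || length(keep_frac) != 1L ||
      keep_frac <= 0 || keep_frac > 1) {
    stop("keep_frac must be in (0, 1]")
  }
  n <- nrow(m$counts)
  if (n == 0L) stop("count matrix has no windows")
  n_keep <- max(1L, floor(keep_frac * n))
  rs <- Matrix::rowSums(m$counts)
  ord <- order(-rs, m$windows$chrom, m$windows$start)
  keep <- sort(ord[seq_len(n_keep)])
  structure(list(counts = m$counts[keep, , drop = FALSE],
                 windows = m$windows[keep],
                 bin = m$bin, target = m$target),
            class = "count_matrix")
}

#' TF-IDF scaling with log transform
#'
#' The standard LSI transform for sparse chromatin count matrices:
#' `TF_ij = c_ij / colsum_j` (per-cell depth normalization),
#' `IDF_i = N_cells / n_cells_with_window_i`, and the reported value is
#' `ln(1 + scale * TF_ij * IDF_i)`. All-zero windows are dropped before the
#' IDF is computed; a cell with zero counts in the selected windows is an
#' error (it cannot be normalized).
#'
#' @param m A `count_matrix` (typically after [select_top_windows()]).
#' @param scale Scale constant inside the log (default 1e4).
#' @return A `tfidf_matrix` object: `x` (transformed sparse matrix),
#'   `idf`, `scale`, `windows`, `target`.
#' @export
tfidf_log <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  nonzero <- Matrix::rowSums(counts) > 0
  counts <- counts[nonzero, , drop = FALSE]
  windows <- m$windows[which(nonzero)]
  if (nrow(counts) == 0L) stop("no non-zero windows")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    stop("cell(s) with zero counts in selected windows: ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  }
  n_cells <- ncol(counts)
  idf <- n_cells / Matrix::rowSums(counts > 0)
  tf <- counts %*% Matrix::Diagonal(x = 1 / cs)
  x <- Matrix::Diagonal(x = idf) %*% tf
  x <- methods::as(x, "CsparseMatrix")
  x@x <- log1p(scale * x@x)
  dimnames(x) <- dimnames(counts)
  structure(list(x = x, idf = idf, scale = scale, windows = windows,
                 target = m$target),
            class = "tfidf_matrix")
}

#' SVD with diagonal-sum dimension retention
#'
#' Decomposes the transformed windows x cells matrix and keeps the SVD
#' dimensions whose singular values exceed `retain_frac` of the sum of all
#' singular values (default 0.2 percent). Per-cell coordinates are the
#' retained right-singular vectors scaled by their singular values. If
#' fewer than two dimensions pass the rule, the top two are kept with a
#' warning. The first dimension is not dropped.
#'
#' @param x A `tfidf_matrix`, or a plain numeric matrix (features x cells)
#'   with cell column names.
#' @param retain_frac Retention threshold as a fraction of the singular
#'   value sum (default 0.002). `0` retains all dimensions.
#' @return An `embedding_model`: `d` (all singular values, non-increasing),
#'   `retained` (indices), `coords` (cells x retained dims), `u`, `v`,
#'   `cells`, `target`.
#' @export
svd_select <- function(x, retain_frac = 0.002) {
  target <- NA_character_
  if (inherits(x, "tfidf_matrix")) {
    target <- x$target
    x <- x$x
  }
  xm <- as.matrix(x)
  if (!all(is.finite(xm))) stop("matrix contains non-finite values")
  cells <- colnames(xm)
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(xm)))
  s <- svd(xm)
  keep <- which(s$d > retain_frac * sum(s$d))
  if (length(keep) < 2L) {
    warning("fewer than 2 dimensions pass the retention rule; keeping top 2")
    keep <- seq_len(min(2L, length(s$d)))
  }
  coords <- sweep(s$v[, keep, drop = FALSE], 2L, s$d[keep], `*`)
  rownames(coords) <- cells
  colnames(coords) <- paste0("dim", keep)
  structure(list(d = s$d, retained = keep, coords = coords,
                 u = s$u, v = s$v, cells = cells, target = target),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("embedding_model: %d cells, %d retained dimension(s)\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' 2-D UMAP projection of the retained dimensions
#'
#' Nonlinear 2-D embedding of the retained SVD coordinates for
#' visualization; clustering should run on the retained coordinates
#' themselves, not on this projection. Deterministic under a fixed seed
#' (single-threaded optimization).
#'
#' @param model An `embedding_model`.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (capped at n_cells - 1).
#' @param min_dist UMAP minimum embedding distance.
#' @return Numeric matrix (cells x 2) with cell row names.
#' @export
embed_2d <- function(model, seed = 42L, n_neighbors = 15L, min_dist = 0.1) {
  stopifnot(inherits(model, "embedding_model"))
  n <- nrow(model$coords)
  if (n < 3L) stop("need at least 3 cells to embed")
  set.seed(seed)
  out <- uwot::umap(model$coords,
                    n_neighbors = min(n_neighbors, n - 1L),
                    min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 0)
  rownames(out) <- rownames(model$coords)
  colnames(out) <- c("umap1", "umap2")
  out
}

#' k-means clustering of the retained dimensions
#'
#' Clusters cells in the retained SVD coordinate space (not the 2-D
#' projection) with multiple random restarts. Labels are renumbered
#' canonically by order of first appearance so the output is invariant to
#' the arbitrary cluster numbering.
#'
#' @param model An `embedding_model`.
#' @param k Number of clusters (2 <= k <= n_cells).
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @return Named integer vector of cluster labels (1..k), one per cell.
#' @export
cluster_kmeans <- function(model, k, seed = 42L, nstart = 10L) {
  stopifnot(inherits(model, "embedding_model"))
  n <- nrow(model$coords)
  if (k > n) stop("k (", k, ") exceeds number of cells (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  if (k == n) {
    # degenerate: every cell its own cluster
    labels <- seq_len(n)
    names(labels) <- rownames(model$coords)
    return(labels)
  }
  set.seed(seed)
  km <- stats::kmeans(model$coords, centers = k, nstart = nstart,
                      iter.max = 100L)
  labels <- canonical_labels(km$cluster)
  names(labels) <- rownames(model$coords)
  labels
}

# renumber labels 1..k in order of first appearance
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Normalized mutual information between two labelings
#'
#' `NMI = I(A;B) / normalizer`, computed with natural logarithms from the
#' label contingency table. The default normalizer is the arithmetic mean of
#' the two entropies; `max`, `min` and `sqrt` variants are available. On a
#' scale of 0 (independent partitions) to 1 (identical partitions).
#'
#' @param true_labels,cluster_labels Equal-length label vectors.
#' @param variant Normalizer: one of `"mean"`, `"max"`, `"min"`, `"sqrt"`.
#' @return NMI as a numeric scalar with the contingency table attached as
#'   attribute `"contingency"`.
#' @export
nmi <- function(true_labels, cluster_labels,
                variant = c("mean", "max", "min", "sqrt")) {
  variant <- match.arg(variant)
  if (length(true_labels) != length(cluster_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(cluster_labels), ")")
  }
  if (length(true_labels) == 0L) stop("empty labelings")
  tab <- table(true_labels, cluster_labels)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  outer_p <- outer(pa, pb)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  denom <- switch(variant,
                  mean = (ha + hb) / 2,
                  max = max(ha, hb),
                  min = min(ha, hb),
                  sqrt = sqrt(ha * hb))
  val <- if (mi <= 0 || denom <= 0) 0 else mi / denom
  structure(val, contingency = tab)
}

#' Concatenation-based multi-target integration
#'
#' A deliberately simple substitute for weighted-nearest-neighbor
#' integration: each target's retained coordinates are centered, scaled to
#' unit total variance, multiplied by its weight, and concatenated into one
#' coordinate space that downstream embedding/clustering consumes as usual.
#'
#' @param models List of `embedding_model` objects over the same cells.
#' @param weights Numeric weights, one per model (default equal).
#' @return An `embedding_model` whose `coords` are the concatenated scaled
#'   coordinates (singular values are not carried over).
#' @export
integrate_targets <- function(models, weights = NULL) {
  stopifnot(length(models) >= 1L)
  for (m in models) stopifnot(inherits(m, "embedding_model"))
  if (is.null(weights)) weights <- rep(1, length(models))
  stopifnot(length(weights) == length(models), all(weights > 0))
  cell_sets <- lapply(models, function(m) sort(rownames(m$coords)))
  ref <- cell_sets[[1L]]
  for (i in seq_along(cell_sets)[-1L]) {
    if (!identical(cell_sets[[i]], ref)) {
      d1 <- setdiff(ref, cell_sets[[i]])
      d2 <- setdiff(cell_sets[[i]], ref)
      stop("cell sets differ between models: missing from model ", i, ": ",
           paste(utils::head(d1, 5L), collapse = ", "),
           "; extra in model ", i, ": ",
           paste(utils::head(d2, 5L), collapse = ", "))
    }
  }
  blocks <- mapply(function(m, w) {
    co <- m$coords[ref, , drop = FALSE]
    co <- scale(co, center = TRUE, scale = FALSE)
    tv <- sum(co^2) / max(nrow(co) - 1L, 1L)
    if (tv > 0) co <- co / sqrt(tv)
    co * w
  }, models, weights, SIMPLIFY = FALSE)
  coords <- do.call(cbind, blocks)
  colnames(coords) <- paste0("idim", seq_len(ncol(coords)))
  structure(list(d = NULL, retained = seq_len(ncol(coords)), coords = coords,
                 u = NULL, v = NULL, cells = ref,
                 target = paste(vapply(models, function(m)
                   as.character(m$target), character(1L)), collapse = "+")),
            class = "embedding_model")
}
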