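#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv := .N .SD rbindlist fwrite dcast
#' @importFrom stats median
NULL

FRAG_COLS <- c("chrom", "start", "end", "cell", "target", "dup_count")

#' Build a fragment table
#'
#' Fragments are deduplicated tagmentation events in Cell Ranger-style BED
#' convention: 0-based half-open coordinates, a cell barcode, and (here) a
#' chromatin-target label identifying which antibody-barcoded assay produced
#' the fragment.
#'
#' @param chrom Character vector of reference names.
#' @param start,end Integer fragment coordinates, 0-based half-open
#'   (`end > start >= 0`).
#' @param cell Cell barcode strings (non-empty).
#' @param target Chromatin-target labels (non-empty), e.g. `"H3K27me3"`.
#' @param dup_count Number of duplicate read pairs collapsed into each
#'   fragment (>= 1).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `cell`,
#'   `target`, `dup_count`, validated and coordinate-sorted.
#' @export
fragments <- function(chrom = character(), start = integer(), end = integer(),
                      cell = character(), target = character(),
                      dup_count = rep(1L, length(chrom))) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   cell = as.character(cell),
                   target = as.character(target),
                   dup_count = as.integer(dup_count))
  validate_fragments(dt)
}

#' Validate a fragment table
#'
#' @param frags A data.frame-like object with the six fragment columns.
#' @return The validated table as a coordinate-sorted `data.table`.
#' @export
validate_fragments <- function(frags) {
  dt <- as.data.table(frags)
  missing_cols <- setdiff(FRAG_COLS, names(dt))
  if (length(missing_cols) > 0L) {
    stop("fragment table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, FRAG_COLS, with = FALSE]
  if (nrow(dt) > 0L) {
    if (anyNA(dt)) stop("fragment table contains missing values")
    if (any(dt$start < 0L)) stop("fragment start must be >= 0")
    if (any(dt$end <= dt$start)) stop("fragment end must be > start")
    if (any(!nzchar(dt$cell))) stop("empty cell barcode")
    if (any(!nzchar(dt$target))) stop("empty target label")
    if (any(dt$dup_count < 1L)) stop("dup_count must be >= 1")
  }
  setorder(dt, chrom, start, end, cell, target)
  dt[]
}

empty_fragments <- function() {
  fragments()
}

#' Read a Cell Ranger-style fragment BED file
#'
#' Expects tab-separated lines `chrom  start  end  barcode  [dup_count]`
#' with 0-based half-open coordinates; a missing fifth column is taken as
#' `dup_count = 1`. Lines that do not parse raise an error naming the
#' offending line number.
#'
#' @param path Path to the fragment file (plain text).
#' @param target Chromatin-target label to attach to every fragment.
#' @return A fragment `data.table` (see [fragments()]).
#' @export
read_fragments <- function(path, target) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_fragments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L | nf > 5L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected 4 or 5 tab-separated columns, found %d",
                 bad[1L], nf[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  s_chr <- vapply(fields, `[[`, character(1L), 2L)
  e_chr <- vapply(fields, `[[`, character(1L), 3L)
  cell <- vapply(fields, `[[`, character(1L), 4L)
  dup_chr <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "1",
                    character(1L))
  bad_int <- which(!grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr) |
                     !grepl("^[0-9]+$", dup_chr))
  if (length(bad_int) > 0L) {
    stop(sprintf("line %d: non-integer coordinate or duplicate count",
                 bad_int[1L]))
  }
  start <- as.integer(s_chr)
  end <- as.integer(e_chr)
  bad_coord <- which(end <= start)
  if (length(bad_coord) > 0L) {
    stop(sprintf("line %d: end (%d) must be greater than start (%d)",
                 bad_coord[1L], end[bad_coord[1L]], start[bad_coord[1L]]))
  }
  fragments(chrom = chrom, start = start, end = end, cell = cell,
            target = target, dup_count = as.integer(dup_chr))
}

#' Collapse duplicate fragments
#'
#' Two records are duplicates when they share `(chrom, start, end, cell,
#' target)`; the target label is part of the key because identical
#' coordinates observed by two different assays in the same cell are distinct
#' tagmentation events. `dup_count` mass is conserved: the collapsed record
#' carries the sum of the input counts. Idempotent.
#'
#' @param frags Fragment table.
#' @return Deduplicated fragment table.
#' @export
deduplicate <- function(frags) {
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0L) return(frags)
  out <- frags[, .(dup_count = sum(dup_count)),
               by = .(chrom, start, end, cell, target)]
  validate_fragments(out)
}

#' Per-cell, per-target fragment statistics
#'
#' Computes, for each (cell, target) pair present, the number of unique
#' fragments `f_i` and the median fragment length `L_i` in bp. Input should
#' be deduplicated.
#'
#' @param frags Deduplicated fragment table.
#' @return `data.table` with columns `cell`, `target`, `n_unique`,
#'   `median_len`.
#' @export
cell_stats <- function(frags) {
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0L) {
    return(data.table(cell = character(), target = character(),
                      n_unique = integer(), median_len = numeric()))
  }
  frags[, .(n_unique = .N, median_len = as.numeric(median(end - start))),
        by = .(cell, target)]
}

#' Per-cell QC on unique fragment counts
#'
#' A cell passes QC when it has at least `min_unique` unique fragments for
#' every required target. The threshold can be relaxed for individual
#' targets (e.g. a lower cutoff for a low-yield mark) via `relax`.
#'
#' @param frags Deduplicated fragment table.
#' @param required_targets Character vector of targets every passing cell
#'   must satisfy.
#' @param min_unique Minimum unique fragments per required target
#'   (inclusive; default 100).
#' @param relax Optional named numeric vector of per-target thresholds
#'   overriding `min_unique`, e.g. `c(H3K36me3 = 50)`.
#' @return `data.table` with one row per cell: `cell`, per-target unique
#'   counts (`n_<target>`), per-target median fragment lengths
#'   (`len_<target>`), and logical `pass`.
#' @export
cell_qc <- function(frags, required_targets, min_unique = 100L, relax = NULL) {
  stats_long <- cell_stats(frags)
  available <- unique(stats_long$target)
  missing_t <- setdiff(required_targets, available)
  if (length(missing_t) > 0L) {
    stop("required target(s) absent from data: ",
         paste(missing_t, collapse = ", "),
         "; available: ", paste(sort(available), collapse = ", "))
  }
  thresholds <- rep(as.numeric(min_unique), length(required_targets))
  names(thresholds) <- required_targets
  if (!is.null(relax)) {
    unknown <- setdiff(names(relax), required_targets)
    if (length(unknown) > 0L) {
      stop("relax names not in required_targets: ",
           paste(unknown, collapse = ", "))
    }
    thresholds[names(relax)] <- as.numeric(relax)
  }
  wide_n <- dcast(stats_long, cell ~ target, value.var = "n_unique",
                  fill = 0L)
  wide_l <- dcast(stats_long, cell ~ target, value.var = "median_len",
                  fill = NA_real_)
  tgts <- setdiff(names(wide_n), "cell")
  data.table::setnames(wide_n, tgts, paste0("n_", tgts))
  data.table::setnames(wide_l, tgts, paste0("len_", tgts))
  out <- merge(wide_n, wide_l, by = "cell")
  pass <- rep(TRUE, nrow(out))
  for (t in required_targets) {
    pass <- pass & out[[paste0("n_", t)]] >= thresholds[[t]]
  }
  out[, pass := pass]
  setorder(out, cell)
  out[]
}

#' Cells passing QC
#'
#' @inheritParams cell_qc
#' @return Character vector of passing cell barcodes.
#' @export
qc_pass_cells <- function(frags, required_targets, min_unique = 100L,
                          relax = NULL) {
  qc <- cell_qc(frags, required_targets, min_unique, relax)
  qc$cell[qc$pass]
}

#' Strand-aware gene test windows
#'
#' Builds, for each gene, the interval used for fragment-gene overlap
#' testing: from `upstream` bp upstream of the farthest-distal annotated TSS
#' to the annotated TES. On the + strand the window is
#' `[start - upstream, end)`; on the - strand `[start, end + upstream)`;
#' clipped at 0.
#'
#' @param annotation data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open gene body,
#'   TSS-to-TES in genomic orientation).
#' @param upstream Upstream extension in bp (default 1000).
#' @return `data.table` with `gene_id`, `chrom`, `strand`, `window_start`,
#'   `window_end`, `L_gene`.
#' @export
gene_windows <- function(annotation, upstream = 1000L) {
  ann <- as.data.table(annotation)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    stop("unknown strand value(s): ",
         paste(unique(setdiff(ann$strand, c("+", "-"))), collapse = ", "))
  }
  if (any(ann$end <= ann$start)) stop("gene end must be > start")
  out <- ann[, .(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    window_start = as.integer(ifelse(strand == "+",
                                     pmax(start - upstream, 0L), start)),
    window_end = as.integer(ifelse(strand == "+", end, end + upstream))
  )]
  out[, L_gene := window_end - window_start]
  setorder(out, chrom, window_start)
  out[]
}

# GRanges view of a fragment table (1-based closed, per IRanges convention)
frag_granges <- function(frags) {
  GenomicRanges::GRanges(frags$chrom,
                         IRanges::IRanges(frags$start + 1L, frags$end))
}

bed_granges <- function(bed) {
  GenomicRanges::GRanges(as.character(bed$chrom),
                         IRanges::IRanges(bed$start + 1L, bed$end))
}

#' Fraction of reads in peaks (FRiP)
#'
#' Per target, the fraction of unique fragments overlapping at least 1 bp of
#' any peak. A signal-to-noise metric: high values mean reads concentrate in
#' called enrichment domains.
#'
#' @param frags Deduplicated fragment table.
#' @param peaks data.frame with BED-style `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Named numeric vector, one fraction in \[0,1\] per target present;
#'   `NA` (with a warning) for a target with no fragments cannot occur, but
#'   an entirely empty fragment set returns an empty vector with a warning.
#' @export
frip <- function(frags, peaks) {
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0L) {
    warning("empty fragment set: FRiP undefined")
    return(stats::setNames(numeric(0), character(0)))
  }
  peaks <- as.data.table(peaks)
  hit <- if (nrow(peaks) == 0L) {
    rep(FALSE, nrow(frags))
  } else {
    IRanges::overlapsAny(frag_granges(frags), bed_granges(peaks))
  }
  frags2 <- copy_dt(frags)[, in_peak := hit]
  res <- frags2[, .(frip = mean(in_peak)), by = target]
  stats::setNames(res$frip, res$target)
}

copy_dt <- function(x) data.table::copy(x)

#' Per-peak on-target purity
#'
#' For each peak, the fraction of overlapping unique fragments that carry
#' the expected target label. Peaks with no overlapping fragments are
#' excluded from the summary fraction (purity undefined).
#'
#' @param frags Deduplicated multi-target fragment table.
#' @param peaks BED-style data.frame (`chrom`, `start`, `end`).
#' @param expected_target Target label the peaks were called for.
#' @param purity_threshold Purity above which a peak counts as on-target
#'   (default 0.8, i.e. >80 percent of fragments from the expected assay).
#' @return List with `purity` (numeric per peak, `NA` where no fragments
#'   overlap), `n_assessable`, and `fraction_pure` (share of assessable
#'   peaks with purity >= threshold).
#' @export
peak_target_purity <- function(frags, peaks, expected_target,
                               purity_threshold = 0.8) {
  frags <- validate_fragments(frags)
  peaks <- as.data.table(peaks)
  if (nrow(peaks) == 0L) {
    return(list(purity = numeric(0), n_assessable = 0L,
                fraction_pure = NA_real_))
  }
  purity <- rep(NA_real_, nrow(peaks))
  if (nrow(frags) > 0L) {
    hits <- GenomicRanges::findOverlaps(bed_granges(peaks),
                                        frag_granges(frags))
    if (length(hits) > 0L) {
      dt <- data.table(peak = S4Vectors_from(hits),
                       expected = frags$target[S4Vectors_to(hits)] ==
                         expected_target)
      agg <- dt[, .(purity = mean(expected)), by = peak]
      purity[agg$peak] <- agg$purity
    }
  }
  assessable <- !is.na(purity)
  frac <- if (any(assessable)) {
    mean(purity[assessable] >= purity_threshold)
  } else {
    NA_real_
  }
  list(purity = purity, n_assessable = sum(assessable), fraction_pure = frac)
}

S4Vectors_from <- function(h) as.integer(S4Vectors::queryHits(h))
S4Vectors_to <- function(h) as.integer(S4Vectors::subjectHits(h))
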