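gs1 <- data.frame(chrom = "chr1", length = 130000L)

test_that("window binning counts a fragment in every 50-kb window it touches", {
  fr <- fragments(chrom = "chr1", start = c(100L, 49990L),
                  end = c(200L, 50010L), cell = c("c1", "c1"),
                  target = "A")
  m <- bin_counts(fr, gs1, bin = 50000L)
  expect_s3_class(m, "count_matrix")
  expect_equal(nrow(m$counts), 3L)  # final partial window included
  expect_equal(m$windows$end, c(50000L, 100000L, 130000L))
  expect_equal(as.numeric(m$counts[, "c1"]), c(2, 1, 0))  # boundary spanner in both

  m0 <- bin_counts(fr[0], gs1, bin = 50000L)
  expect_equal(sum(m0$counts), 0)

  fr_bad <- fragments(chrom = "chrX", start = 1L, end = 100L,
                      cell = "c", target = "A")
  expect_error(bin_counts(fr_bad, gs1), "chrX")

  # multi-target input splits per target; target= subsets to one matrix
  fr2 <- fragments(chrom = "chr1", start = c(100L, 200L, 300L),
                   end = c(150L, 250L, 350L), cell = "c1",
                   target = c("A", "A", "B"))
  ml <- bin_counts(fr2, gs1)
  expect_named(ml, c("A", "B"))
  expect_equal(sum(ml$A$counts), 2)
  mb <- bin_counts(fr2, gs1, target = "B")
  expect_s3_class(mb, "count_matrix")
  expect_equal(sum(mb$counts), 1)
})

test_that("top-window selection keeps floor(frac*n) windows by aggregate count, deterministically", {
  # 10 windows with row sums 1..10
  gs <- data.frame(chrom = "chr1", length = 10L * 50000L)
  fr <- do.call(rbind, lapply(1:10, function(w) {
    n <- w
    fragments(chrom = "chr1", start = (w - 1L) * 50000L + seq_len(n) * 10L,
              end = (w - 1L) * 50000L + seq_len(n) * 10L + 5L,
              cell = "c1", target = "A")
  }))
  m <- bin_counts(fr, gs, bin = 50000L)
  expect_equal(unname(Matrix::rowSums(m$counts)), as.numeric(1:10))
  sel <- select_top_windows(m, keep_frac = 0.40)
  expect_equal(unname(Matrix::rowSums(sel$counts)), as.numeric(7:10))

  ident <- select_top_windows(m, keep_frac = 1)
  expect_equal(as.matrix(ident$counts), as.matrix(m$counts))

  expect_error(select_top_windows(m, keep_frac = 0), "keep_frac")
  expect_error(select_top_windows(m, keep_frac = 1.5), "keep_frac")

  # ties at the cutoff rank resolve by genomic order: identical across runs
  fr_tie <- fragments(chrom = "chr1", start = c(10L, 50010L, 100010L),
                      end = c(20L, 50020L, 100020L),
                      cell = "c1", target = "A")
  m_tie <- bin_counts(fr_tie, gs, bin = 50000L)
  s1 <- select_top_windows(m_tie, 0.2)
  s2 <- select_top_windows(m_tie, 0.2)
  expect_equal(s1$windows, s2$windows)
  # earliest coordinates win the three-way tie for 2 slots
  expect_equal(s1$windows$start, c(0L, 50000L))
})

test_that("TF-IDF log transform matches the stated formula and drops empty windows", {
  counts <- Matrix::Matrix(matrix(c(2, 8), nrow = 2,
                                  dimnames = list(c("w1", "w2"), "c1")),
                           sparse = TRUE)
  m <- structure(list(counts = counts,
                      windows = data.table(chrom = "chr1",
                                           start = c(0L, 50000L),
                                           end = c(50000L, 100000L)),
                      bin = 50000L, target = "A"),
                 class = "count_matrix")
  tx <- tfidf_log(m, scale = 1e4)
  expect_equal(as.numeric(tx$x[, 1]), c(log(1 + 2000), log(1 + 8000)),
               tolerance = 1e-12)
  expect_equal(as.numeric(tx$x[, 1]), c(7.6014, 8.9873), tolerance = 1e-4)

  # per-cell depth scale invariance: doubling a cell's counts changes nothing
  counts2 <- cbind(counts * 2, counts)
  colnames(counts2) <- c("c1", "c2")
  m2 <- m; m2$counts <- counts2
  tx2 <- tfidf_log(m2)
  expect_equal(as.numeric(tx2$x[, "c1"]), as.numeric(tx2$x[, "c2"]))

  # all-zero window dropped, not NaN
  counts3 <- rbind(counts, Matrix::Matrix(0, 1, 1, sparse = TRUE))
  rownames(counts3) <- c("w1", "w2", "w3")
  m3 <- m
  m3$counts <- counts3
  m3$windows <- data.table(chrom = "chr1", start = c(0L, 50000L, 100000L),
                           end = c(50000L, 100000L, 150000L))
  tx3 <- tfidf_log(m3)
  expect_equal(nrow(tx3$x), 2L)
  expect_false(any(is.na(tx3$x@x)))

  # a cell with zero counts cannot be normalized
  counts4 <- cbind(counts, Matrix::Matrix(0, 2, 1, sparse = TRUE))
  colnames(counts4) <- c("c1", "empty_cell")
  m4 <- m; m4$counts <- counts4
  expect_error(tfidf_log(m4), "empty_cell")
})

test_that("SVD retention keeps dimensions above 0.2% of the singular-value sum", {
  # matrix engineered to have singular values (10, 5, 1, 0.02)
  set.seed(3)
  d_target <- c(10, 5, 1, 0.02)
  q1 <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:4]
  q2 <- qr.Q(qr(matrix(rnorm(16), 4)))
  x <- q1 %*% diag(d_target) %*% t(q2)
  colnames(x) <- paste0("c", 1:4)
  em <- svd_select(x, retain_frac = 0.002)
  expect_equal(em$d, d_target, tolerance = 1e-8)
  # cutoff 0.002 * 16.02 = 0.03204 -> 3 dimensions retained
  expect_equal(length(em$retained), 3L)
  expect_true(all(diff(em$d) <= 1e-8))

  em_all <- svd_select(x, retain_frac = 0)
  expect_equal(length(em_all$retained), 4L)
  # full reconstruction reproduces the input
  rec <- em_all$u %*% diag(em_all$d) %*% t(em_all$v)
  expect_equal(unname(rec), unname(x), tolerance = 1e-8)

  # coordinates are singular-value-scaled right singular vectors
  expect_equal(unname(em_all$coords),
               unname(sweep(em_all$v, 2, em_all$d, `*`)), tolerance = 1e-10)

  # retained count monotone non-increasing in retain_frac
  ks <- vapply(c(0, 0.002, 0.05, 0.4),
               function(rf) length(suppressWarnings(
                 svd_select(x, rf))$retained), integer(1L))
  expect_true(all(diff(ks) <= 0))
  expect_warning(svd_select(x, retain_frac = 0.9), "top 2")
})

test_that("k-means on retained coordinates recovers separable clouds and ignores input order", {
  set.seed(8)
  coords <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
                  matrix(rnorm(60, 10, 0.1), ncol = 2))
  rownames(coords) <- sprintf("c%02d", 1:60)
  em <- structure(list(coords = coords), class = "embedding_model")
  cl <- cluster_kmeans(em, 2, seed = 1)
  expect_equal(unname(cl), rep(1:2, each = 30))

  # permuting cell order yields the same partition after renumbering
  perm <- sample(60)
  em_p <- structure(list(coords = coords[perm, ]), class = "embedding_model")
  cl_p <- cluster_kmeans(em_p, 2, seed = 1)
  expect_equal(as.numeric(nmi(cl[rownames(coords)[perm]], cl_p)), 1)

  # degenerate k = n: every cell its own cluster
  em5 <- structure(list(coords = coords[1:5, ]), class = "embedding_model")
  cl_n <- cluster_kmeans(em5, 5, seed = 1)
  expect_equal(sort(unique(cl_n)), 1:5)

  expect_error(cluster_kmeans(em, 61, seed = 1), "exceeds")
})

test_that("NMI matches identity, independence, and hand-computed contingency cases", {
  expect_equal(as.numeric(nmi(c(1, 1, 2, 2), c(2, 2, 7, 7))), 1)
  expect_equal(as.numeric(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))), 0)
  # hand-computed: MI = 0.21576 nats, H(A) = ln 2, H(B) = 0.56233
  val <- as.numeric(nmi(c(1, 1, 2, 2), c(1, 1, 1, 2)))
  expect_equal(val, 0.21576 / mean(c(0.69315, 0.56233)), tolerance = 1e-4)
  expect_equal(val, 0.3437, tolerance = 1e-4)
  # normalizer variants
  expect_equal(as.numeric(nmi(c(1, 1, 2, 2), c(1, 1, 1, 2), "max")),
               0.21576 / 0.69315, tolerance = 1e-4)
  expect_error(nmi(1:3, 1:4), "length")
  expect_true(as.numeric(nmi(c(1, 2, 1, 2), c(1, 1, 2, 2))) >= 0)
})

test_that("2-D embedding is deterministic under a seed and separates planted cell types", {
  tt <- two_type_sim(seed = 31, informative = TRUE, n_per_type = 60L)
  em <- svd_select(tfidf_log(select_top_windows(
    bin_counts(tt$sim$fragments, tt$genome_sizes))))
  xy1 <- embed_2d(em, seed = 7)
  xy2 <- embed_2d(em, seed = 7)
  expect_equal(xy1, xy2)
  labels <- type_labels(tt$sim, rownames(xy1))
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(xy1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_2d(structure(list(coords = xy1[1:2, ]),
                                  class = "embedding_model")), "3 cells")
})

test_that("multi-target integration preserves the separation carried by an informative target", {
  tt_a <- two_type_sim(seed = 41, informative = TRUE, n_per_type = 80L,
                       target = "mark1")
  # same cells, uninformative second target
  tt_b <- two_type_sim(seed = 41, informative = FALSE, n_per_type = 80L,
                       target = "mark1")
  pipeline <- function(sim, gsz) {
    svd_select(tfidf_log(select_top_windows(bin_counts(sim$fragments, gsz))))
  }
  em_a <- pipeline(tt_a$sim, tt_a$genome_sizes)
  em_b <- pipeline(tt_b$sim, tt_b$genome_sizes)

  # single model: integration is the identity up to global scale
  em_single <- integrate_targets(list(em_a))
  cl_a <- cluster_kmeans(em_a, 2, seed = 1)
  cl_single <- cluster_kmeans(em_single, 2, seed = 1)
  expect_equal(as.numeric(nmi(cl_a[names(cl_single)], cl_single)), 1)

  # two identical models cluster like one
  em_dup <- integrate_targets(list(em_a, em_a))
  cl_dup <- cluster_kmeans(em_dup, 2, seed = 1)
  expect_equal(as.numeric(nmi(cl_a[names(cl_dup)], cl_dup)), 1)

  # informative + uninformative keeps >= 90% of the informative NMI
  truth_a <- type_labels(tt_a$sim, names(cl_a))
  nmi_a <- as.numeric(nmi(truth_a, cl_a))
  em_int <- integrate_targets(list(em_a, em_b))
  cl_int <- cluster_kmeans(em_int, 2, seed = 1)
  truth_int <- type_labels(tt_a$sim, names(cl_int))
  expect_gte(as.numeric(nmi(truth_int, cl_int)), 0.9 * nmi_a)

  # mismatched cell sets are rejected with the difference named
  em_sub <- em_a
  em_sub$coords <- em_sub$coords[-1, , drop = FALSE]
  expect_error(integrate_targets(list(em_a, em_sub)), "differ")
})
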