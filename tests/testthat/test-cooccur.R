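test_that("fragment-gene overlap counting respects half-open boundaries", {
  win <- data.table(gene_id = "g1", chrom = "chr1", strand = "+",
                    window_start = 4000L, window_end = 8000L,
                    L_gene = 4000L)
  fr <- fragments(chrom = "chr1",
                  start = c(4500L, 3900L, 3000L),
                  end = c(4700L, 4001L, 4000L),
                  cell = "c1", target = "A")
  counts <- count_gene_overlaps(fr, win)
  # [4500,4700) inside; [3900,4001) overlaps 1 bp; [3000,4000) does not (half-open)
  expect_equal(counts$r, 2L)

  # a fragment overlapping two gene windows counts for both
  win2 <- rbind(win, data.table(gene_id = "g2", chrom = "chr1",
                                strand = "+", window_start = 4600L,
                                window_end = 9000L, L_gene = 4400L))
  counts2 <- count_gene_overlaps(fr, win2)
  expect_equal(counts2[gene_id == "g2"]$r, 1L)
  expect_error(count_gene_overlaps(fr, win[0]), "empty")
})

test_that("the Poisson tail follows the coverage-scaled statistic in closed form", {
  # r = 0 has an empty upper tail
  expect_equal(poisson_test(0, 200, 1000, 1e4, 1e8)$p, 1)

  # mu = 0.02, x = 0.06 -> ceil 1 -> p = 1 - exp(-0.02)
  pt <- poisson_test(3, 200, 1e4, 1e4, 1e8)
  expect_equal(pt$mu, 0.02)
  expect_equal(pt$x, 0.06)
  expect_equal(pt$p, 1 - exp(-0.02), tolerance = 1e-12)
  expect_equal(pt$p, 0.019801, tolerance = 1e-4)

  # x = 6 at small mu: tiny tail computed without underflow to zero
  pt2 <- poisson_test(300, 200, 1e4, 1e4, 1e8)
  expect_equal(pt2$x, 6)
  expect_equal(pt2$p, pois_tail_oracle(6, 0.02), tolerance = 1e-10)
  expect_equal(pt2$p, 8.8e-14, tolerance = 0.02)
  expect_gt(pt2$p, 0)

  expect_error(poisson_test(1, 0, 10, 1e4, 1e8), "positive")
  expect_error(poisson_test(1, 200, 0, 1e4, 1e8), "positive")
  expect_error(poisson_test(-1, 200, 10, 1e4, 1e8), ">= 0")

  # p non-increasing in r, all else fixed
  ps <- poisson_test(0:50, 200, 1000, 2000, 1e6)$p
  expect_true(all(diff(ps) <= 1e-15))
  expect_true(all(ps > 0 & ps <= 1))

  # continuous-tail variant agrees with the ceiling rule at integer x
  pc <- poisson_test(10, 100, 1000, 1000, 1e6, tail = "continuous")
  pk <- poisson_test(10, 100, 1000, 1000, 1e6, tail = "ceiling")
  expect_equal(pc$p, pk$p, tolerance = 1e-12)
})

test_that("Poisson tail equals the pmf-summation oracle over a mu-by-k grid", {
  for (mu in c(0.001, 0.02, 1, 10)) {
    for (k in 0:20) {
      # choose r and lengths so that ceiling(x) = k
      p <- poisson_test(r = k, median_len = 1000, n_frags = mu * 1e6 / 1000,
                        gene_len = 1000, genome_len = 1e6)$p
      expect_equal(p, pois_tail_oracle(k, mu), tolerance = 1e-9,
                   label = sprintf("mu=%g k=%d", mu, k))
    }
  }
})

test_that("BH adjustment reproduces the hand-applied step-up and its boundary cases", {
  adj <- bh_adjust(c(0.001, 0.02, 0.03, 0.5), alpha = 0.01)
  expect_equal(adj$q, c(0.004, 0.04, 0.04, 0.5))
  expect_equal(adj$significant, c(TRUE, FALSE, FALSE, FALSE))

  all1 <- bh_adjust(rep(1, 5))
  expect_equal(all1$q, rep(1, 5))
  expect_false(any(all1$significant))

  single <- bh_adjust(0.004)
  expect_equal(single$q, 0.004)

  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("per-cell target proportions normalize to one", {
  fr <- rbind(
    fragments(chrom = "chr1", start = seq_len(894L) * 100L,
              end = seq_len(894L) * 100L + 50L, cell = "c1", target = "H3K27me3"),
    fragments(chrom = "chr1", start = seq_len(60L) * 100L + 10L,
              end = seq_len(60L) * 100L + 60L, cell = "c1", target = "H3K4me2"),
    fragments(chrom = "chr1", start = seq_len(46L) * 100L + 20L,
              end = seq_len(46L) * 100L + 70L, cell = "c1", target = "H3K36me3"),
    fragments(chrom = "chr1", start = 5L, end = 55L, cell = "c2",
              target = "H3K27me3"))
  pr <- target_proportions(fr)
  c1 <- pr[cell == "c1"]
  expect_equal(c1[target == "H3K27me3"]$fraction, 0.894)
  expect_equal(c1[target == "H3K4me2"]$fraction, 0.060)
  expect_equal(c1[target == "H3K36me3"]$fraction, 0.046)
  expect_equal(pr[cell == "c2"]$fraction, 1)
  sums <- pr[, .(s = sum(fraction)), by = cell]$s
  expect_true(all(abs(sums - 1) < 1e-12))
})

# a cooccurrence-shaped table built by hand for score/association tests
mk_cooc <- function(df) {
  dt <- as.data.table(df)
  data.table::setattr(dt, "class", c("cooccurrence", class(dt)))
  dt
}

test_that("bivalency score sums normalized counts over jointly enriched genes", {
  cooc <- mk_cooc(data.table(
    cell = c("c1", "c1", "c1", "c2", "c2"),
    gene_id = c("g1", "g1", "g2", "g1", "g2"),
    target = c("K27", "K4", "K36", "K27", "K4"),
    norm_count = c(5, 3, 7, 4, 6),
    enriched = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  sc <- bivalency_score(cooc, repressive = "K27", active = c("K4", "K36"))
  # c1: g1 bivalent (K27+K4): 5 + 3; g2 lacks K27 -> excluded
  expect_equal(sc[sc$cell == "c1", ]$score, 8)
  # c2: no gene with both marks enriched
  expect_equal(sc[sc$cell == "c2", ]$score, 0)
  expect_error(bivalency_score(cooc, "K27", "nope"), "unknown target")
})

test_that("bivalency scores separate cells with planted bivalent genes", {
  genes <- make_genes(n = 30L)
  biv_genes <- genes$gene_id[1:8]
  emap <- rbind(
    data.table(cell_type = "biv", target = "K27", gene_id = biv_genes,
               multiplier = 20),
    data.table(cell_type = "biv", target = "K4", gene_id = biv_genes,
               multiplier = 20),
    # non-bivalent type: the same genes active-only
    data.table(cell_type = "mono", target = "K4", gene_id = biv_genes,
               multiplier = 20))
  cfg <- sim_config(40, c("biv", "mono"), c("K27", "K4"), genes, 1e6, emap,
                    background_rate = 1e-3, seed = 17)
  sim <- simulate_experiment(cfg)
  cooc <- test_enrichment(sim$fragments, gene_windows(genes, 100L), 1e6)
  sc <- bivalency_score(cooc, "K27", "K4")
  sc$type <- type_labels(sim, sc$cell)
  tt <- t.test(score ~ type, data = sc, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("Cramer's V matches the closed-form 2x2 chi-square", {
  flags_to_cooc <- function(fa, fb, genes) {
    mk_cooc(data.table(
      cell = "c1",
      gene_id = rep(genes, 2L),
      target = rep(c("a", "b"), each = length(genes)),
      norm_count = 1,
      enriched = c(fa, fb)))
  }
  # table (a=30, b=10, c=10, d=30): chi2 = 20, V = 0.5
  genes <- sprintf("g%02d", 1:80)
  fa <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  fb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  res <- cramers_v(flags_to_cooc(fa, fb, genes), "c1", "a", "b")
  expect_equal(res$chisq, 20)
  expect_equal(res$v, 0.5)

  # perfect association
  fa2 <- rep(c(TRUE, FALSE), c(20, 20))
  res2 <- cramers_v(flags_to_cooc(fa2, fa2, sprintf("h%02d", 1:40)),
                    "c1", "a", "b")
  expect_equal(res2$v, 1)

  # proportional rows: exact independence
  fa3 <- rep(c(TRUE, FALSE), c(20, 5))
  fb3 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(16, 4, 4, 1))
  res3 <- cramers_v(flags_to_cooc(fa3, fb3, sprintf("i%02d", 1:25)),
                    "c1", "a", "b")
  expect_equal(res3$chisq, 0)
  expect_equal(res3$v, 0)

  # degenerate marginal flagged, V reported as 0
  res4 <- cramers_v(flags_to_cooc(rep(FALSE, 10), rep(c(TRUE, FALSE), 5),
                                  sprintf("j%02d", 1:10)), "c1", "a", "b")
  expect_true(res4$degenerate)
  expect_equal(res4$v, 0)

  expect_error(cramers_v(flags_to_cooc(TRUE, TRUE, "g1"), "c1", "a", "b"),
               "fewer than 2")
})

test_that("Cramer's V uses only the requested cell's flags in a multi-cell table", {
  cooc <- mk_cooc(data.table(
    cell = rep(c("c1", "c2"), each = 8L),
    gene_id = rep(sprintf("g%d", 1:4), 4L),
    target = rep(rep(c("a", "b"), each = 4L), 2L),
    norm_count = 1,
    # c1: perfect association; c2: no enrichment at all
    enriched = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                 rep(FALSE, 8L))))
  expect_equal(cramers_v(cooc, "c1", "a", "b")$v, 1)
  res2 <- cramers_v(cooc, "c2", "a", "b")
  expect_true(res2$degenerate)
  expect_equal(res2$v, 0)
  both <- cramers_v_cells(cooc, "a", "b")
  expect_equal(both$v, c(1, 0))
})

test_that("Cramer's V agrees with an independent chi-square implementation on random tables", {
  set.seed(99)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 8) + 1L, 2L)  # +1 avoids zero marginals
    genes <- sprintf("g%03d", seq_len(sum(tab)))
    fa <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tab[1, 1], tab[1, 2],
                                             tab[2, 1], tab[2, 2]))
    fb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tab[1, 1], tab[1, 2],
                                             tab[2, 1], tab[2, 2]))
    cooc <- mk_cooc(data.table(cell = "c1", gene_id = rep(genes, 2L),
                               target = rep(c("a", "b"),
                                            each = length(genes)),
                               norm_count = 1, enriched = c(fa, fb)))
    res <- cramers_v(cooc, "c1", "a", "b")
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$v, sqrt(unname(ref$statistic) / sum(tab)),
                 tolerance = 1e-10)
    expect_true(res$v >= 0 && res$v <= 1)
  }
})

test_that("the full enrichment scan controls false positives and recovers planted genes", {
  ps <- planted_sim(seed = 7)
  sim <- simulate_experiment(ps$cfg)
  cooc <- test_enrichment(sim$fragments, ps$windows, 1e6)
  merged <- merge(cooc, sim$truth$planted,
                  by = c("cell", "gene_id", "target"), all.y = TRUE)
  expect_gte(mean(merged$enriched %in% TRUE), 0.9)

  ps0 <- planted_sim(seed = 107, n_planted = 0L)
  sim0 <- simulate_experiment(ps0$cfg)
  cooc0 <- test_enrichment(sim0$fragments, ps0$windows, 1e6)
  expect_lte(mean(cooc0$enriched), 0.01)
})
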