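test_that("welch_t and welch_p match the reference implementation", {
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6)), -3.6742, tolerance = 1e-3)
  expect_equal(welch_p(c(1, 2, 3), c(4, 5, 6)), 0.0214, tolerance = 0.01)
  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(sample(2:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -2, 2))
    ref <- t.test(a, b)
    expect_equal(welch_t(a, b), unname(ref$statistic), tolerance = 1e-6)
    expect_equal(welch_p(a, b), ref$p.value, tolerance = 1e-6)
  }
  a <- c(1.3, 2.1, 0.4)
  expect_equal(welch_t(a, a), 0)
  expect_equal(welch_p(a, a), 1)
  expect_equal(welch_t(2 * a, 2 * c(4, 5, 6)), welch_t(a, c(4, 5, 6)))
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("degenerate zero-variance groups give capped statistics", {
  expect_equal(welch_t(c(2, 2), c(2, 2, 2)), 0)
  expect_equal(welch_t(c(3, 3), c(2, 2)), 1e3)
  expect_equal(welch_t(c(1, 1), c(2, 2)), -1e3)
  expect_gt(welch_p(c(3, 3), c(2, 2)), 0)
  expect_equal(welch_p(c(2, 2), c(2, 2)), 1)
})

test_that("score pairs aggregate components by max and min, unclamped", {
  h <- rbind(c(1, 1, 1, 5, 5, 5),   # t strongly negative
             c(5, 5, 5, 1, 1, 1),   # t strongly positive
             c(3, 3, 3, 3, 3, 3))   # flat
  h <- h + matrix(seq(0.01, 0.18, by = 0.01), 3, 6)
  f <- structure(list(H = h, W = matrix(1, 2, 3)), class = "odegr_nmf")
  groups <- rep(c("A", "B"), each = 3)
  p <- component_score_pair(f, groups)
  ts <- apply(h, 1, function(v) welch_t(v[1:3], v[4:6]))
  expect_equal(p$t_pos, max(ts))
  expect_equal(p$t_neg, min(ts))
  # K = 1: both members equal the single component's t
  f1 <- structure(list(H = h[1, , drop = FALSE]), class = "odegr_nmf")
  p1 <- component_score_pair(f1, groups)
  expect_equal(p1$t_pos, p1$t_neg)
  # all-positive components keep their sign (no clamping in the pair)
  h_up <- rbind(c(5, 5.1, 5, 1, 1.1, 1), c(4, 4.2, 4.1, 3.2, 3.4, 3.3))
  f2 <- structure(list(H = h_up), class = "odegr_nmf")
  p2 <- component_score_pair(f2, groups)
  expect_gt(p2$t_neg, 0)
  expect_error(component_score_pair(f, groups[1:4]), "length")
})

test_that("multi-rank pair reduces to the single-rank pair and recovers a
           planted profile", {
  g <- rank1_gene()
  single <- nmf_score_pair(g$x, g$labels, ranks = 2, seed = 1)
  f <- nmf_factorize(t(log10(g$x$values + 1)), K = 2, seed = 1)
  direct <- component_score_pair(f, g$groups)
  expect_equal(single$t_pos, direct$t_pos)
  expect_equal(single$t_neg, direct$t_neg)

  # the gene is one structure whose amplitude differs between groups; in
  # the factorized (log) space the true per-cell profile is
  # log10(amp + 1), so the recovered component's t should approximate
  # the Welch t of that profile
  lamp <- log10(g$amp + 1)
  t_true <- welch_t(lamp[g$groups == "A"], lamp[g$groups == "B"])
  extreme <- if (abs(single$t_neg) > single$t_pos) single$t_neg else
    single$t_pos
  expect_lt(abs(extreme - t_true) / abs(t_true), 0.2)

  # infeasible ranks are skipped with a warning; all infeasible errors
  expect_warning(p <- nmf_score_pair(g$x, g$labels, ranks = c(2, 1e4),
                                     seed = 1), "infeasible")
  expect_equal(p$t_pos, single$t_pos)
  expect_error(suppressWarnings(
    nmf_score_pair(g$x, g$labels, ranks = 1e4)), "feasible")
})

test_that("mean-coverage t equals Welch t on per-cell means and ignores
           bin order", {
  vals <- 10^(matrix(c(1, 2, 3, 4, 5, 6), 6, 5)) - 1  # row means 1..6
  cells <- sprintf("c%d", 1:6)
  x <- binned_region_matrix(gene_region("g", "c", 0, 500), vals, cells)
  labels <- group_labels(cells, rep(c("A", "B"), each = 3))
  expect_equal(mean_coverage_t(x, labels), -3.6742, tolerance = 1e-3)
  xp <- binned_region_matrix(x$gene, vals[, c(3, 1, 5, 2, 4)], cells)
  expect_equal(mean_coverage_t(xp, labels), mean_coverage_t(x, labels))
})

test_that("TPM pair takes transcript-wise extremes and is idempotent
           under duplication", {
  cells <- sprintf("c%d", 1:8)
  labels <- group_labels(cells, rep(c("A", "B"), each = 4))
  up <- c(3, 3.1, 3.2, 3.05, 1, 1.1, 0.9, 1.05)
  dn <- rev(up)
  m <- rbind(t1 = up, t2 = dn)
  colnames(m) <- cells
  p <- tpm_score_pair(m, labels)
  expect_gt(p$t_pos, 0); expect_lt(p$t_neg, 0)
  expect_equal(p$t_pos, -p$t_neg, tolerance = 1e-10)  # mirrored rows
  p_dup <- tpm_score_pair(m[c(1, 2, 1), ], labels)
  expect_equal(p_dup$t_pos, p$t_pos)
  expect_equal(p_dup$t_neg, p$t_neg)
  p1 <- tpm_score_pair(m[1, , drop = FALSE], labels)
  expect_equal(p1$t_pos, p1$t_neg)
  expect_error(tpm_score_pair(m[0, ], labels), "transcript")
})

test_that("delta score measures one-sided excess with zero clamping", {
  expect_equal(delta_score(score_pair(10, -2), score_pair(1, -2)), 9)
  expect_equal(delta_score(score_pair(0, -12), score_pair(0, -3)), 9)
  x <- score_pair(4.2, -1.7)
  expect_equal(delta_score(x, x), 0)
  # reference dominating on both sides can never give a positive delta
  expect_lte(delta_score(score_pair(2, -1), score_pair(5, -4)), 0)
  # a one-sided reference (t, t) only competes on its own side
  expect_equal(delta_score(score_pair(1, 0), score_pair(12, 12)), 0)
})

test_that("label swap negates t and mirrors every score pair", {
  g <- rank1_gene()
  swapped <- group_labels(names(g$labels),
                          ifelse(unclass(g$labels) == "A", "B", "A"))
  expect_equal(mean_coverage_t(g$x, swapped), -mean_coverage_t(g$x, g$labels))
  p <- nmf_score_pair(g$x, g$labels, ranks = c(2, 3), seed = 2)
  q <- nmf_score_pair(g$x, swapped, ranks = c(2, 3), seed = 2)
  expect_equal(q$t_pos, -p$t_neg, tolerance = 1e-10)
  expect_equal(q$t_neg, -p$t_pos, tolerance = 1e-10)
})

test_that("per-gene record takes the minimum delta over seeds and is
           reproducible", {
  co <- tiny_cohort()
  x <- co$matrices[[1]]
  rows <- gene_tpm_rows(co$tpm, x$gene$gene_id)
  r1 <- score_gene(x, rows, co$labels, ranks = c(2, 4), seeds = c(1, 2, 3))
  r2 <- score_gene(x, rows, co$labels, ranks = c(2, 4), seeds = c(1, 2, 3))
  expect_identical(r1, r2)
  per_seed <- vapply(c(1, 2, 3), function(s) {
    p <- nmf_score_pair(x, co$labels, ranks = c(2, 4), seed = s)
    delta_score(p, r1$tpm_pair)
  }, numeric(1))
  expect_equal(r1$delta_nmf_tpm, min(per_seed))
  expect_true(all(r1$delta_nmf_tpm <= per_seed + 1e-12))
})

test_that("ranking and Z-scores follow descending delta with sample sd", {
  df <- data.frame(gene_id = sprintf("g%d", 1:5),
                   delta_nmf_tpm = c(0, 10, 0, 0, 0))
  out <- rank_and_zscore(df)
  expect_equal(out$gene_id[1], "g2")
  expect_equal(out$rank, 1:5)
  # direct evaluation: mean 2, sample sd sqrt(20); (10 - 2)/4.4721
  expect_equal(out$zscore[1], 1.7889, tolerance = 1e-3)
  expect_equal(out$zscore, (out$delta_nmf_tpm - 2) / sqrt(20),
               tolerance = 1e-6)
  # degenerate all-equal deltas: all zero Z-scores, ranks still complete
  flat <- rank_and_zscore(data.frame(gene_id = c("b", "a"),
                                     delta_nmf_tpm = c(1, 1)))
  expect_equal(flat$zscore, c(0, 0))
  expect_equal(flat$gene_id, c("a", "b"))  # ties broken lexicographically
  expect_error(rank_and_zscore(df[1, ]), "at least 2")
})
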