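test_that("top-DE selection orders genes by whole-gene significance", {
  co <- tiny_cohort()
  top <- select_top_de_genes(co$matrices, co$labels, n = 4)
  expect_equal(nrow(top), 4L)
  expect_true(!is.unsorted(top$p))
  # the truly DE genes should dominate the head of the ranking
  de <- co$meta$gene_id[co$meta$is_de]
  expect_true(all(top$gene_id %in% de))
  all_g <- select_top_de_genes(co$matrices, co$labels,
                               n = length(co$matrices))
  expect_setequal(all_g$gene_id, names(co$matrices))
  expect_identical(top, select_top_de_genes(co$matrices, co$labels, n = 4))
  expect_error(select_top_de_genes(co$matrices, co$labels, n = 99),
               "only")
})

test_that("window-average reshape follows the floor-index formula", {
  X <- matrix(c(0, 2, 4, 6), 1, 4)
  expect_equal(reshape_to_length(X, 2), matrix(c(1, 4), 1, 2))
  expect_equal(reshape_to_length(matrix(5, 3, 7), 3), matrix(5, 3, 3))
  set.seed(13)
  for (i in 1:10) {
    L <- sample(5:60, 1)
    Lp <- sample(seq_len(L - 1), 1)
    X <- matrix(runif(4 * L), 4, L)
    out <- reshape_to_length(X, Lp)
    expect_equal(dim(out), c(4L, Lp))
    expect_true(all(is.finite(out)))
    expect_equal(out, reshape_brute(X, Lp))
  }
  expect_error(reshape_to_length(X, ncol(X)), "must be <")
})

test_that("reshape commutes with group averaging", {
  set.seed(21)
  X <- matrix(runif(10 * 24), 10, 24)
  grp <- rep(c(TRUE, FALSE), each = 5)
  direct <- colMeans(reshape_to_length(X, 7)[grp, ]) -
    colMeans(reshape_to_length(X, 7)[!grp, ])
  averaged <- reshape_to_length(rbind(colMeans(X[grp, ])), 7) -
    reshape_to_length(rbind(colMeans(X[!grp, ])), 7)
  expect_equal(direct, drop(averaged))
})

test_that("positive controls reject same-trend hosts and append the
           donor exactly", {
  co <- tiny_cohort()
  stats <- select_top_de_genes(co$matrices, co$labels,
                               n = length(co$matrices))
  donor_row <- stats[1, ]
  donor <- reshape_to_length(co$matrices[[donor_row$gene_id]]$values, 10)
  # force every host but one to share the donor's trend strongly
  pool <- stats
  pool$p <- 1e-30
  pool$direction <- donor_row$direction
  ok_id <- pool$gene_id[5]
  pool$direction[5] <- -donor_row$direction
  set.seed(9)
  for (i in 1:5) {
    pc <- make_positive_control(donor, donor_row$direction, pool,
                                co$matrices, id = "p")
    expect_equal(attr(pc, "insert")$host, ok_id)
  }
  host <- co$matrices[[ok_id]]
  expect_equal(ncol(pc$values), ncol(host$values) + 10L)
  expect_equal(unname(pc$values[, ncol(host$values) + 1:10]),
               unname(donor))
  expect_equal(unname(pc$values[, seq_len(ncol(host$values))]),
               unname(host$values))
  # opposite direction at high significance is admissible by definition;
  # same direction everywhere leaves no host
  pool$direction[5] <- donor_row$direction
  expect_error(make_positive_control(donor, donor_row$direction, pool,
                                     co$matrices), "no admissible host")
  # configurable insert position keeps the donor block intact
  set.seed(9)
  mid <- make_positive_control(donor, donor_row$direction,
                               stats, co$matrices, insert_after = 3)
  expect_equal(unname(mid$values[, 4:13]),
               unname(donor[mid$cell_ids, ]))
})

test_that("benchmark generation is seeded and sized as requested", {
  co <- tiny_cohort()
  b1 <- generate_benchmark(co$matrices, co$labels, L_prime = 10,
                           n_positives = 6, n_top = 4, seed = 3)
  expect_length(b1$positives, 6L)
  expect_equal(nrow(b1$pos_meta), 6L)
  expect_true(all(b1$pos_meta$L_prime == 10))
  expect_true(all(vapply(b1$positives, function(p)
    attr(p, "insert")$L_prime, numeric(1)) == 10))
  expect_length(b1$negatives, length(co$matrices))
  b2 <- generate_benchmark(co$matrices, co$labels, L_prime = 10,
                           n_positives = 6, n_top = 4, seed = 3)
  expect_equal(lapply(b1$positives, `[[`, "values"),
               lapply(b2$positives, `[[`, "values"))
  b3 <- generate_benchmark(co$matrices, co$labels, L_prime = 10,
                           n_positives = 6, n_top = 4, seed = 4)
  expect_false(identical(b1$pos_meta$donor, b3$pos_meta$donor))
})

test_that("synthetic cohorts have the declared shape and DE bookkeeping", {
  co <- synth_cohort(12, 5, 7, 30, de_fraction = 0.5, seed = 2)
  expect_length(co$matrices, 12L)
  expect_true(all(vapply(co$matrices, function(x)
    identical(dim(x$values), c(12L, 30L)), logical(1))))
  expect_equal(sum(co$meta$is_de), 6L)
  expect_equal(sum(unclass(co$labels) == "A"), 5L)
  co0 <- synth_cohort(10, 5, 5, 20, de_fraction = 0, seed = 2)
  expect_false(any(co0$meta$is_de))
  # reproducibility
  co2 <- synth_cohort(12, 5, 7, 30, de_fraction = 0.5, seed = 2)
  expect_equal(co$matrices[[3]]$values, co2$matrices[[3]]$values)
  # matched TPM table covers every gene
  expect_setequal(unique(co$tpm$tx2gene$gene_id), names(co$matrices))
})

test_that("null cohorts give calibrated whole-gene type-I error", {
  co <- synth_cohort(500, 20, 20, 30, de_fraction = 0, seed = 77,
                     n_structures = 2)
  stats <- select_top_de_genes(co$matrices, co$labels, n = 500)
  frac <- mean(stats$p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("label shuffles preserve sizes and respond to seeds", {
  co <- tiny_cohort()
  s1 <- shuffle_labels(co$labels, seed = 1)
  expect_setequal(names(s1), names(co$labels))
  expect_equal(sum(unclass(s1) == "A"), sum(unclass(co$labels) == "A"))
  expect_identical(unclass(shuffle_labels(co$labels, seed = 1)),
                   unclass(s1))
  expect_false(identical(unclass(shuffle_labels(co$labels, seed = 2)),
                         unclass(s1)))
})
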