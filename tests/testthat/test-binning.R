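test_that("bin_region sums per-base coverage with a partial final bin", {
  cov <- read_coverage(write_bedgraph("chr1", 0, 200, 2))
  r200 <- gene_region("g", "chr1", 0, 200, bin_size = 100)
  expect_equal(bin_region(cov, r200), c(200, 200))

  cov1 <- read_coverage(write_bedgraph("chr1", 0, 250, 1))
  r250 <- gene_region("g", "chr1", 0, 250, bin_size = 100)
  expect_equal(r250$n_bins, 3L)
  expect_equal(bin_region(cov1, r250), c(100, 100, 50))

  # zero coverage everywhere (track on another interval)
  cov0 <- read_coverage(write_bedgraph("chr1", 5000, 5100, 7))
  expect_equal(bin_region(cov0, r250), c(0, 0, 0))

  expect_error(bin_region(cov, gene_region("g", "chrZ", 0, 200)), "chrZ")
})

test_that("binning conserves total coverage and nests across bin sizes", {
  set.seed(7)
  # piecewise-constant track over 600 bp
  starts <- seq(0, 580, by = 20)
  vals <- rpois(length(starts), 5)
  cov <- read_coverage(write_bedgraph("chr1", starts, starts + 20, vals))
  region <- gene_region("g", "chr1", 0, 600, bin_size = 50)
  b50 <- bin_region(cov, region)
  expect_equal(sum(b50), sum(vals * 20))
  # summing adjacent fine bins equals coarse binning when lengths divide
  b100 <- bin_region(cov, region, bin_size = 100)
  expect_equal(b100, b50[c(TRUE, FALSE)] + b50[c(FALSE, TRUE)])
})

test_that("bin mask drops gene-overlap and low-mappability bins", {
  target <- gene_region("g1", "chr1", 0, 400, bin_size = 100)
  other <- gene_region("g2", "chr1", 150, 230, bin_size = 100)
  regions <- list(target, other)
  # bins 2 and 3 (1-based) intersect g2
  expect_equal(build_bin_mask(target, regions), c(TRUE, FALSE, FALSE, TRUE))

  # mappability: bin minimum 0.4 -> dropped, 0.6 -> kept; 0.5 is "or less"
  mapp <- read_coverage(write_bedgraph(
    "chr1", c(0, 100, 200, 300), c(100, 200, 300, 400),
    c(1.0, 0.4, 0.6, 0.5)))
  expect_equal(build_bin_mask(target, list(target), mapp),
               c(TRUE, FALSE, TRUE, FALSE))

  # isolated gene, full mappability: everything kept
  full <- read_coverage(write_bedgraph("chr1", 0, 400, 1))
  expect_true(all(build_bin_mask(target, list(target), full)))

  # bases missing from the mappability track count as 0 -> dropped
  partial <- read_coverage(write_bedgraph("chr1", 0, 250, 1))
  expect_equal(build_bin_mask(target, list(target), partial),
               c(TRUE, TRUE, FALSE, FALSE))

  # masking criteria commute (order independence)
  both <- build_bin_mask(target, regions, mapp)
  expect_equal(both,
               build_bin_mask(target, regions) &
                 build_bin_mask(target, list(target), mapp))
})

test_that("finalize_gene_matrix enforces the strict minimum-bin filter", {
  region <- gene_region("g", "chr1", 0, 150 * 100, bin_size = 100)
  raw <- binned_region_matrix(region, matrix(9, 4, 150),
                              sprintf("c%d", 1:4))
  mask99 <- rep(c(TRUE, FALSE), c(99, 51))
  expect_null(finalize_gene_matrix(raw, mask99, min_bins = 100))
  mask100 <- rep(c(TRUE, FALSE), c(100, 50))
  kept <- finalize_gene_matrix(raw, mask100, min_bins = 100)
  expect_equal(ncol(kept$values), 100L)
  expect_true(kept$transformed)
  expect_equal(unname(kept$values[1, 1]), 1)  # log10(9 + 1)
  expect_error(finalize_gene_matrix(kept, rep(TRUE, 100)), "transform")
  expect_error(finalize_gene_matrix(raw, rep(TRUE, 10)), "mask length")
})

test_that("GTF genes are read with 0-based half-open coordinates", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start1 = c(101, 501), end1 = c(350, 900),
                      strand = c("+", "-"),
                      gene_type = c("protein_coding", "lincRNA"))
  tx <- data.frame(transcript_id = c("tA1", "tA2", "tB1"),
                   gene_id = c("gA", "gA", "gB"))
  ann <- read_gtf_genes(write_gtf(genes, tx), bin_size = 100)
  expect_named(ann$regions, c("gA", "gB"))
  expect_equal(ann$regions$gA$start, 100L)
  expect_equal(ann$regions$gA$end, 350L)
  expect_equal(ann$regions$gA$n_bins, 3L)
  expect_equal(unname(ann$gene_type["gB"]), "lincRNA")
  expect_setequal(ann$tx2gene$transcript_id, c("tA1", "tA2", "tB1"))
})
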