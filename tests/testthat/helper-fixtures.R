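# Shared fixtures and independent oracles. Everything is generated in
# code; file-based fixtures are written to tempdir() at test time.

# bedGraph writer: intervals are 0-based half-open, as in the format.
write_bedgraph <- function(chrom, start, end, value,
                           path = tempfile(fileext = ".bedGraph")) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, start, end, value), path)
  path
}

# Minimal GENCODE-style GTF with gene and transcript rows.
# genes: data.frame(gene_id, chrom, start1, end1, strand, gene_type)
# tx:    data.frame(transcript_id, gene_id) (spans copied from the gene)
write_gtf <- function(genes, tx = NULL,
                      path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
    genes$chrom, genes$start1, genes$end1, genes$strand, genes$gene_id,
    genes$gene_type)
  if (!is.null(tx)) {
    g <- genes[match(tx$gene_id, genes$gene_id), ]
    lines <- c(lines, sprintf(
      paste0('%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
             'transcript_id "%s"; gene_type "%s";'),
      g$chrom, g$start1, g$end1, g$strand, tx$gene_id, tx$transcript_id,
      g$gene_type))
  }
  writeLines(lines, path)
  path
}

# Brute-force O(n^2) AUROC oracle: pairwise comparison with 0.5 for ties.
auroc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Literal floor-index evaluation of the window-averaging reshape.
reshape_brute <- function(X, Lp) {
  L <- ncol(X)
  out <- matrix(0, nrow(X), Lp)
  for (b in seq_len(Lp)) {
    lo <- floor((b - 1) * (L - 1) / Lp)
    hi <- floor(b * (L - 1) / Lp)
    for (c in seq_len(nrow(X))) out[c, b] <- mean(X[c, (lo:hi) + 1])
  }
  out
}

# Small two-group cohort reused across scoring tests.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_cohort(n_genes = 8, n_cells_A = 12, n_cells_B = 12,
                             n_bins = 40, de_fraction = 0.5, seed = 42)
    cache
  }
})

# A rank-deficient gene whose single profile differs between groups:
# raw counts built from one known block structure times known per-cell
# amplitudes (no noise), for factorization-recovery checks.
rank1_gene <- function(n_a = 15, n_b = 15, n_bins = 60, shift = 6) {
  w <- rep(0, n_bins)
  w[ceiling(n_bins / 4):floor(3 * n_bins / 4)] <- 1
  amp <- c(rnorm(n_a, 20, 2), rnorm(n_b, 20 + shift, 2))
  cells <- sprintf("c%02d", seq_len(n_a + n_b))
  vals <- outer(pmax(amp, 1), w)
  x <- binned_region_matrix(gene_region("r1", "chrT", 0, n_bins * 100),
                            vals, cells)
  labels <- group_labels(cells, rep(c("A", "B"), c(n_a, n_b)))
  list(x = x, labels = labels, amp = amp,
       groups = rep(c("A", "B"), c(n_a, n_b)))
}
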