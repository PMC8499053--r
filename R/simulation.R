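#' Rank genes by whole-gene differential expression significance
#'
#' Per gene, each cell is summarised by its mean `log10(count + 1)` over
#' bins and the two groups compared by Welch's test; the `n` smallest-p
#' genes are returned together with the direction (sign of the t
#' statistic). These serve as donors of genuine DE signal for the
#' positive-control construction.
#'
#' @param matrices named list of `odegr_matrix` (raw or transformed).
#' @param labels an `odegr_labels`.
#' @param n number of top genes to return (default 100).
#' @return data.frame `gene_id`, `p`, `t`, `direction` ordered by
#'   increasing p.
#' @export
select_top_de_genes <- function(matrices, labels, n = 100L) {
  if (n > length(matrices))
    stop(sprintf("requested top %d genes but only %d available",
                 n, length(matrices)))
  stats <- .gene_mean_de(matrices, labels)
  utils::head(stats[order(stats$p, stats$gene_id), ], n)
}

# Whole-gene mean-log-coverage Welch t and p for every gene.
.gene_mean_de <- function(matrices, labels) {
  rows <- lapply(matrices, function(x) {
    x <- .as_log(x)
    groups <- .aligned_groups(labels, x$cell_ids)
    m <- rowMeans(x$values)
    t <- welch_t(m[groups == "A"], m[groups == "B"])
    data.frame(gene_id = x$gene$gene_id, p = welch_p(m[groups == "A"],
                                                     m[groups == "B"]),
               t = t, direction = sign(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compress a cells x L matrix to L' columns by window averaging
#'
#' Column `b` of the output (1-based) is the row-wise mean of input
#' columns with 0-based indices `floor((b - 1) (L - 1) / L')` through
#' `floor(b (L - 1) / L')`, both ends included; adjacent windows overlap
#' by construction. This shrinks a donor gene's coverage pattern to a
#' chosen insert length while preserving its group difference structure.
#'
#' @param X cells x L numeric matrix.
#' @param L_prime target number of columns, `1 <= L_prime < L`.
#' @return cells x `L_prime` matrix.
#' @export
reshape_to_length <- function(X, L_prime) {
  X <- as.matrix(X)
  L <- ncol(X)
  L_prime <- as.integer(L_prime)
  if (L_prime >= L) stop(sprintf("L_prime (%d) must be < L (%d)", L_prime, L))
  if (L_prime < 1L) stop("L_prime must be >= 1")
  out <- vapply(seq_len(L_prime), function(b) {
    lo <- floor((b - 1) * (L - 1) / L_prime) + 1L
    hi <- floor(b * (L - 1) / L_prime) + 1L
    rowMeans(X[, lo:hi, drop = FALSE])
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X))
  rownames(out) <- rownames(X)
  out
}

#' Graft a reshaped donor block onto a host gene
#'
#' Draws host genes uniformly from the pool (consuming the current RNG
#' stream) until one passes the same-trend rejection: a host is redrawn
#' when its own whole-gene test has `-log10(p) > same_trend_threshold`
#' with the SAME direction as the donor, because such a host already
#' carries the donor's trend and the graft would not create a *local* DE
#' pattern. The donor columns are appended after the host columns (the
#' insert position is configurable via `insert_after`).
#'
#' @param donor_reshaped cells x L' matrix of reshaped raw donor counts.
#' @param donor_direction sign (+1/-1) of the donor's whole-gene t.
#' @param host_pool data.frame `gene_id`, `p`, `direction` for every
#'   candidate host (typically the whole-gene DE statistics over all retained genes).
#' @param matrices named list of raw `odegr_matrix` holding the hosts.
#' @param same_trend_threshold `-log10(p)` cutoff (default 10).
#' @param insert_after 0-based column after which the donor block is
#'   inserted; defaults to the host width (append at the end).
#' @param id identifier for the combined gene.
#' @return raw `odegr_matrix` of width `host width + L'`, with attribute
#'   `"insert"` = list(host, donor_cols, L_prime).
#' @export
make_positive_control <- function(donor_reshaped, donor_direction, host_pool,
                                  matrices, same_trend_threshold = 10,
                                  insert_after = NULL, id = "positive") {
  same_trend <- (-log10(host_pool$p) > same_trend_threshold) &
    (host_pool$direction == donor_direction)
  if (all(same_trend))
    stop("no admissible host: every pool gene shares the donor's DE trend")
  repeat {
    i <- sample.int(nrow(host_pool), 1L)
    if (!same_trend[i]) break
  }
  host <- matrices[[host_pool$gene_id[i]]]
  if (isTRUE(host$transformed))
    stop("positive controls are built from raw count matrices")
  if (!identical(rownames(donor_reshaped), host$cell_ids))
    donor_reshaped <- donor_reshaped[host$cell_ids, , drop = FALSE]
  L <- ncol(host$values)
  Lp <- ncol(donor_reshaped)
  at <- if (is.null(insert_after)) L else as.integer(insert_after)
  if (at < 0L || at > L) stop("insert_after must lie in [0, host width]")
  vals <- cbind(host$values[, seq_len(at), drop = FALSE],
                donor_reshaped,
                host$values[, seq_len(L - at) + at, drop = FALSE])
  g <- host$gene
  region <- gene_region(id, g$chrom, g$start,
                        g$start + (L + Lp) * g$bin_size, g$strand, g$bin_size)
  out <- binned_region_matrix(region, vals, host$cell_ids)
  attr(out, "insert") <- list(host = g$gene_id,
                              donor_cols = seq_len(Lp) + at, L_prime = Lp)
  out
}

#' Build a local-DE benchmark from a gene-matrix collection
#'
#' Positives: repeatedly draw a donor (uniform with replacement) from the
#' `n_top` most significant whole-gene DE genes, compress it to `L_prime`
#' bins with [reshape_to_length()], and graft it onto a host that does not
#' share its trend ([make_positive_control()]). Negatives: the unmodified
#' matrices. Everything is reproducible from `seed`.
#'
#' @param matrices named list of raw `odegr_matrix`.
#' @param labels an `odegr_labels`.
#' @param L_prime insert length in bins (the study uses 10, 50, 100).
#' @param n_positives number of grafted positives (default 1000).
#' @param n_top donor pool size (default 100).
#' @param seed integer seed.
#' @param same_trend_threshold passed to [make_positive_control()].
#' @return `odegr_benchmark`: list with `positives` (named list of
#'   matrices), `pos_meta` (data.frame id, host, donor, L_prime),
#'   `negatives`, `labels`, `params`.
#' @export
generate_benchmark <- function(matrices, labels, L_prime,
                               n_positives = 1000L, n_top = 100L,
                               seed = 1L, same_trend_threshold = 10) {
  stats <- .gene_mean_de(matrices, labels)
  top <- utils::head(stats[order(stats$p, stats$gene_id), ], n_top)
  .with_seed(seed, {
    positives <- vector("list", n_positives)
    meta <- vector("list", n_positives)
    for (i in seq_len(n_positives)) {
      j <- sample.int(nrow(top), 1L)
      donor <- matrices[[top$gene_id[j]]]
      if (isTRUE(donor$transformed))
        stop("benchmark construction needs raw count matrices")
      reshaped <- reshape_to_length(donor$values, L_prime)
      id <- sprintf("pos_%04d", i)
      positives[[i]] <- make_positive_control(
        reshaped, top$direction[j], stats, matrices,
        same_trend_threshold = same_trend_threshold, id = id)
      meta[[i]] <- data.frame(id = id, host = attr(positives[[i]],
                                                   "insert")$host,
                              donor = top$gene_id[j], L_prime = L_prime,
                              stringsAsFactors = FALSE)
    }
    names(positives) <- vapply(meta, `[[`, character(1), "id")
    empty_meta <- data.frame(id = character(), host = character(),
                             donor = character(), L_prime = integer(),
                             stringsAsFactors = FALSE)
    structure(list(positives = positives,
                   pos_meta = if (n_positives == 0) empty_meta else
                     do.call(rbind, meta),
                   negatives = matrices, labels = labels,
                   params = list(L_prime = L_prime,
                                 n_positives = n_positives,
                                 n_top = n_top, seed = seed)),
              class = "odegr_benchmark")
  })
}

#' Synthetic two-group cohort of binned coverage matrices
#'
#' Emulates full-length scRNA-seq coverage over gene regions as a
#' non-negative superposition of a few contiguous block-shaped bin-loading
#' profiles ("transcript structures") weighted by per-cell amplitudes.
#' Amplitudes are log10-normal around a base of 10 counts per bin with
#' standard deviation `dispersion`; in DE genes the amplitude is shifted
#' by `effect_log10` between the groups (half up in one group, half down
#' in the other, random sign). With `de_scope = "gene"` (default) the
#' shift applies to every structure — ordinary whole-gene differential
#' expression, the dominant pattern in real cohorts and the donor
#' material for the local-DE benchmark. With `de_scope = "structure"`
#' only one randomly chosen structure shifts, creating genuinely local
#' differential expression. Counts are Poisson draws on the resulting
#' intensity. A matched TPM table reports the per-structure amplitudes as
#' "transcripts"; with probability `hidden_fraction` a DE gene's shifted
#' structure is omitted from the table, producing genes whose
#' differential expression is invisible to annotation-based scoring (the
#' overlooked-DE construction; meaningful with `de_scope = "structure"`).
#'
#' @param n_genes number of genes.
#' @param n_cells_A,n_cells_B cells per group.
#' @param n_bins bins per gene.
#' @param de_fraction fraction of genes with a group shift.
#' @param effect_log10 amplitude shift between groups, log10 units.
#' @param de_scope `"gene"` (shift all structures) or `"structure"`
#'   (shift one).
#' @param n_structures structures per gene (default 3).
#' @param dispersion between-cell log10 amplitude s.d. (default 0.3).
#' @param hidden_fraction fraction of DE genes whose shifted structure is
#'   hidden from the TPM table (default 0).
#' @param seed integer seed.
#' @param bin_size nominal bin width for the synthetic regions.
#' @return list with `matrices` (named list of raw `odegr_matrix`),
#'   `labels`, `tpm` (an `odegr_tpm`), `meta` (data.frame gene_id, is_de,
#'   de_structure, direction, hidden).
#' @export
synth_cohort <- function(n_genes, n_cells_A = 60L, n_cells_B = 60L,
                         n_bins = 300L, de_fraction = 0.3,
                         effect_log10 = 0.5, de_scope = c("gene", "structure"),
                         n_structures = 3L, dispersion = 0.3,
                         hidden_fraction = 0, seed = 1L, bin_size = 100L) {
  de_scope <- match.arg(de_scope)
  if (n_genes < 1 || n_cells_A < 2 || n_cells_B < 2 || n_bins < 2)
    stop("infeasible cohort shape")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  n_cells <- n_cells_A + n_cells_B
  cells <- c(sprintf("A%03d", seq_len(n_cells_A)),
             sprintf("B%03d", seq_len(n_cells_B)))
  groups <- rep(c("A", "B"), c(n_cells_A, n_cells_B))
  labels <- group_labels(cells, groups)
  n_de <- round(de_fraction * n_genes)

  .with_seed(seed, {
    de_genes <- sort(sample.int(n_genes, n_de))
    matrices <- vector("list", n_genes)
    meta <- vector("list", n_genes)
    tpm_rows <- list(); tx_ids <- character(); tx_genes <- character()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%04d", g)
      is_de <- g %in% de_genes
      # contiguous exon-like blocks, 20-60% of the region each
      lens <- pmax(2L, round(runif(n_structures, 0.2, 0.6) * n_bins))
      starts <- vapply(lens, function(l) sample.int(n_bins - l + 1L, 1L),
                       integer(1))
      W <- matrix(0, n_bins, n_structures)
      for (k in seq_len(n_structures)) W[starts[k]:(starts[k] + lens[k] - 1L),
                                         k] <- 1
      mu <- matrix(1, n_cells, n_structures)  # base amplitude 10^1 per bin
      k_de <- NA_integer_; dir <- 0L
      if (is_de) {
        k_shift <- if (de_scope == "structure") {
          k_de <- sample.int(n_structures, 1L)
        } else seq_len(n_structures)
        dir <- sample(c(-1L, 1L), 1L)
        mu[groups == "A", k_shift] <- 1 + dir * effect_log10 / 2
        mu[groups == "B", k_shift] <- 1 - dir * effect_log10 / 2
      }
      amp <- 10^(mu + matrix(rnorm(n_cells * n_structures, 0, dispersion),
                             n_cells, n_structures))
      intensity <- amp %*% t(W)
      counts <- matrix(rpois(length(intensity), intensity),
                       n_cells, n_bins)
      region <- gene_region(gid, "chrS", (g - 1L) * (n_bins + 10L) * bin_size,
                            (g - 1L) * (n_bins + 10L) * bin_size +
                              n_bins * bin_size, "+", bin_size)
      matrices[[g]] <- binned_region_matrix(region, counts, cells)
      hidden <- is_de && de_scope == "structure" && hidden_fraction > 0 &&
        runif(1) < hidden_fraction
      keep_k <- seq_len(n_structures)
      if (hidden) keep_k <- setdiff(keep_k, k_de)
      for (k in keep_k) {
        tx_ids <- c(tx_ids, sprintf("%s.t%d", gid, k))
        tx_genes <- c(tx_genes, gid)
        tpm_rows[[length(tpm_rows) + 1L]] <- amp[, k]
      }
      meta[[g]] <- data.frame(gene_id = gid, is_de = is_de,
                              de_structure = k_de, direction = dir,
                              hidden = hidden, stringsAsFactors = FALSE)
    }
    names(matrices) <- vapply(matrices, function(x) x$gene$gene_id,
                              character(1))
    tpm <- do.call(rbind, tpm_rows)
    dimnames(tpm) <- list(tx_ids, cells)
    list(matrices = matrices, labels = labels,
         tpm = tpm_table(tpm,
                         data.frame(transcript_id = tx_ids, gene_id = tx_genes,
                                    stringsAsFactors = FALSE),
                         setNames(rep("protein_coding", n_genes),
                                  names(matrices))),
         meta = do.call(rbind, meta))
  })
}

#' Permute group assignments, preserving group sizes
#'
#' @param labels an `odegr_labels`.
#' @param seed integer seed.
#' @return an `odegr_labels` with the same cells and group sizes.
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  .with_seed(seed, {
    group_labels(names(labels), sample(unclass(labels)))
  })
}
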