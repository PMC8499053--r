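#' Two-group cell labels
#'
#' @param cell_ids cell identifiers.
#' @param groups group assignment per cell, values `"A"` or `"B"`; each
#'   group needs at least 2 cells (Welch variance needs n >= 2).
#' @return named character vector of class `odegr_labels`.
#' @export
group_labels <- function(cell_ids, groups) {
  groups <- as.character(groups)
  if (length(cell_ids) != length(groups))
    stop("cell_ids and groups must have equal length")
  if (anyDuplicated(cell_ids)) stop("each cell must be labeled exactly once")
  if (!all(groups %in% c("A", "B")))
    stop("groups must be 'A' or 'B'")
  if (sum(groups == "A") < 2 || sum(groups == "B") < 2)
    stop("each group needs at least 2 cells")
  structure(setNames(groups, cell_ids), class = "odegr_labels")
}

# Align labels to a cell ordering; error on mismatch.
.aligned_groups <- function(labels, cell_ids) {
  if (!all(cell_ids %in% names(labels))) {
    missing <- setdiff(cell_ids, names(labels))
    stop(sprintf("cells without group label: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  unclass(labels)[cell_ids]
}

# Capped statistic used when both group variances vanish but means differ;
# the t statistic is formally infinite there.
.T_CAP <- 1e3

#' Welch's t statistic
#'
#' `(mean(a) - mean(b)) / sqrt(var(a)/|a| + var(b)/|b|)` with unbiased
#' sample variances. When both variances are zero the statistic is 0 for
#' equal means and capped at +/-1000 otherwise.
#'
#' @param a,b numeric samples of the two groups, each of length >= 2.
#' @return the t statistic (group A minus group B in the numerator).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) return(if (d == 0) 0 else sign(d) * .T_CAP)
  d / sqrt(se2)
}

#' Two-sided Welch p-value
#'
#' Uses the t distribution with Welch-Satterthwaite degrees of freedom.
#' In the degenerate zero-variance case the p-value is 1 for equal means
#' and the smallest positive double otherwise.
#'
#' @inheritParams welch_t
#' @return two-sided p-value in (0, 1].
#' @export
welch_p <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    return(if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  max(2 * pt(-abs(t), df), .Machine$double.xmin)
}

#' Positive-maximum / negative-minimum score pair
#'
#' @param t_pos,t_neg aggregated maximum and minimum t statistics;
#'   `t_pos >= t_neg`. Neither is clamped at zero: when every component
#'   shifts the same way both members share that sign, which keeps the
#'   label-swap antisymmetry `(p, n) -> (-n, -p)` exact.
#' @return list of class `odegr_pair`.
#' @export
score_pair <- function(t_pos, t_neg) {
  if (t_pos < t_neg) stop("t_pos must be >= t_neg")
  structure(list(t_pos = t_pos, t_neg = t_neg), class = "odegr_pair")
}

#' Score pair over the components of one factorization
#'
#' Computes the Welch t of each factor expression profile (row of `H`)
#' between groups A and B and returns the maximum and minimum over
#' components. Because `H` is non-negative, the sign of each component's t
#' reflects which group expresses that candidate transcript structure more.
#'
#' @param f an `odegr_nmf` factorization.
#' @param groups character vector of `"A"`/`"B"` aligned with the columns
#'   of `f$H` (use [group_labels()] plus the matrix's cell order).
#' @return an `odegr_pair`.
#' @export
component_score_pair <- function(f, groups) {
  if (length(groups) != ncol(f$H))
    stop("group vector length must equal the number of cells in H")
  ia <- groups == "A"; ib <- groups == "B"
  ts <- apply(f$H, 1, function(h) welch_t(h[ia], h[ib]))
  score_pair(max(ts), min(ts))
}

#' Multi-rank NMF score pair for one gene
#'
#' Factorizes the transposed log-count matrix at each rank in `ranks` and
#' aggregates the per-rank component score pairs into the overall pair
#' (max of maxima, min of minima). A single inappropriate rank blurs
#' transcript structures (too small merges them, too large splinters
#' them), so several ranks are tried and the most extreme differential
#' signal on each side is kept.
#'
#' @param x an `odegr_matrix`; transformed with `log10(x + 1)` on entry if
#'   still raw.
#' @param labels an `odegr_labels`.
#' @param ranks integer ranks to factorize at (default `c(2, 5, 10)`).
#'   Ranks exceeding `min(dim)` are skipped with a warning; if none is
#'   feasible an error is raised.
#' @param seed NMF initialization seed.
#' @param detail if `TRUE`, attach the per-rank pairs as attribute
#'   `"by_rank"` (a named list).
#' @return an `odegr_pair`.
#' @export
nmf_score_pair <- function(x, labels, ranks = c(2L, 5L, 10L), seed = 1L,
                           detail = FALSE) {
  x <- .as_log(x)
  groups <- .aligned_groups(labels, x$cell_ids)
  V <- t(x$values)  # bins x cells
  feasible <- ranks[ranks <= min(dim(V))]
  if (length(feasible) < length(ranks)) {
    warning(sprintf("gene %s: skipping infeasible ranks %s (matrix %d x %d)",
                    x$gene$gene_id,
                    paste(setdiff(ranks, feasible), collapse = ","),
                    nrow(V), ncol(V)))
  }
  if (length(feasible) == 0) stop("no feasible factorization rank")
  by_rank <- lapply(feasible, function(K) {
    component_score_pair(nmf_factorize(V, K, seed = seed), groups)
  })
  names(by_rank) <- as.character(feasible)
  out <- score_pair(max(vapply(by_rank, `[[`, numeric(1), "t_pos")),
                    min(vapply(by_rank, `[[`, numeric(1), "t_neg")))
  if (detail) attr(out, "by_rank") <- by_rank
  out
}

#' Welch t of the per-cell mean log coverage
#'
#' The annotation-free baseline: each cell is summarised by the mean of
#' `log10(count + 1)` over kept bins, and the two groups are compared with
#' Welch's t. A gene whose NMF score pair beats this statistic carries
#' differential signal in a sub-region that whole-gene averaging dilutes.
#'
#' @inheritParams nmf_score_pair
#' @return the t statistic.
#' @export
mean_coverage_t <- function(x, labels) {
  x <- .as_log(x)
  groups <- .aligned_groups(labels, x$cell_ids)
  m <- rowMeans(x$values)
  welch_t(m[groups == "A"], m[groups == "B"])
}

#' Score pair over a gene's annotated transcripts
#'
#' @param tpm_rows transcripts x cells matrix of `log10(TPM + 1)` values
#'   for the gene's selected transcripts; at least one row.
#' @param labels an `odegr_labels`; columns of `tpm_rows` must be named by
#'   cell.
#' @return an `odegr_pair` of the max/min per-transcript Welch t.
#' @export
tpm_score_pair <- function(tpm_rows, labels) {
  tpm_rows <- as.matrix(tpm_rows)
  if (nrow(tpm_rows) == 0)
    stop("no annotated transcript passes expression filter")
  groups <- .aligned_groups(labels, colnames(tpm_rows))
  ts <- apply(tpm_rows, 1, function(v) welch_t(v[groups == "A"],
                                               v[groups == "B"]))
  score_pair(max(ts), min(ts))
}

#' Overlooked-differential-expression excess score
#'
#' The larger of the two one-sided excesses of NMF-detected over
#' reference-detected differential expression,
#' `max(max(p_n, 0) - max(p_r, 0), min(n_r, 0) - min(n_n, 0))` for NMF
#' pair `(p_n, n_n)` and reference pair `(p_r, n_r)`. Each side is
#' clamped at zero before differencing: a positive t carries no evidence
#' of group-B-upregulated structure, so on the negative side only
#' statistics below zero count (and symmetrically). Without the clamp, a
#' gene whose differential expression the reference captures perfectly on
#' one side (e.g. a large positive `t_mean`, giving the degenerate
#' reference pair `(t, t)`) would score `t - n_n` on the other side even
#' when neither method sees any down-regulated structure, and
#' whole-gene-DE genes would dominate the ranking. Large positive values
#' flag genes where the factorization sees group differences the
#' reference statistic misses.
#'
#' @param nmf,ref `odegr_pair` objects.
#' @return the delta score (any sign; `delta_score(x, x) == 0`).
#' @export
delta_score <- function(nmf, ref) {
  max(max(nmf$t_pos, 0) - max(ref$t_pos, 0),
      min(ref$t_neg, 0) - min(nmf$t_neg, 0))
}

#' Full score record for one gene
#'
#' Runs the multi-rank NMF scoring once per seed and keeps, for each delta,
#' the minimum over seeds: NMF only finds local optima, so requiring the
#' excess to persist across several initializations screens out
#' factorization flukes. The reported NMF pair is the one from the seed
#' attaining the minimum `delta_nmf_tpm` (or minimum `delta_nmf_mean` when
#' no TPM rows are supplied).
#'
#' @inheritParams nmf_score_pair
#' @param tpm_rows transcripts x cells `log10(TPM + 1)` matrix for the
#'   gene, or `NULL` to skip the annotation-based reference (the TPM pair
#'   and `delta_nmf_tpm` are then `NA`).
#' @param seeds integer vector of NMF seeds (default `c(1, 2, 3)`).
#' @param detail if `TRUE`, attach per-rank `delta_nmf_mean` minima (over
#'   seeds) as field `delta_mean_by_rank`.
#' @return list with `gene_id`, `nmf_pair`, `tpm_pair`, `t_mean`,
#'   `delta_nmf_tpm`, `delta_nmf_mean`, and optionally
#'   `delta_mean_by_rank`.
#' @export
score_gene <- function(x, tpm_rows, labels, ranks = c(2L, 5L, 10L),
                       seeds = c(1L, 2L, 3L), detail = FALSE) {
  x <- .as_log(x)
  t_mean <- mean_coverage_t(x, labels)
  mean_pair <- score_pair(t_mean, t_mean)
  tpm_pair <- if (is.null(tpm_rows)) NULL else tpm_score_pair(tpm_rows, labels)

  per_seed <- lapply(seeds, function(s)
    nmf_score_pair(x, labels, ranks = ranks, seed = s, detail = detail))
  d_mean <- vapply(per_seed, delta_score, numeric(1), ref = mean_pair)
  d_tpm <- if (is.null(tpm_pair)) rep(NA_real_, length(seeds)) else
    vapply(per_seed, delta_score, numeric(1), ref = tpm_pair)

  pick <- if (is.null(tpm_pair)) which.min(d_mean) else which.min(d_tpm)
  rec <- list(gene_id = x$gene$gene_id,
              nmf_pair = per_seed[[pick]],
              tpm_pair = tpm_pair,
              t_mean = t_mean,
              delta_nmf_tpm = if (is.null(tpm_pair)) NA_real_ else min(d_tpm),
              delta_nmf_mean = min(d_mean))
  if (detail) {
    ranks_chr <- names(attr(per_seed[[1]], "by_rank"))
    rec$delta_mean_by_rank <- setNames(vapply(ranks_chr, function(K) {
      min(vapply(per_seed, function(p)
        delta_score(attr(p, "by_rank")[[K]], mean_pair), numeric(1)))
    }, numeric(1)), ranks_chr)
  }
  rec
}

#' Rank genes by a delta score and attach Z-scores
#'
#' Ranks descend by the chosen delta (ties broken by `gene_id`); the
#' Z-score standardises each delta against the mean and sample standard
#' deviation over all scored genes (all-equal deltas give all-zero
#' Z-scores).
#'
#' @param records data.frame with columns `gene_id` and the ranking column.
#' @param by ranking column (default `"delta_nmf_tpm"`).
#' @return the data.frame with `zscore` and `rank` columns, ordered by rank.
#' @export
rank_and_zscore <- function(records, by = "delta_nmf_tpm") {
  if (nrow(records) < 2) stop("need at least 2 gene records to rank")
  d <- records[[by]]
  if (any(is.na(d))) stop(sprintf("missing values in %s", by))
  s <- sd(d)
  records$zscore <- if (s == 0) rep(0, length(d)) else (d - mean(d)) / s
  ord <- order(-d, records$gene_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

# Flatten score_gene() records into the output table.
.records_to_df <- function(recs) {
  na_pair <- list(t_pos = NA_real_, t_neg = NA_real_)
  do.call(rbind, lapply(recs, function(r) {
    tp <- if (is.null(r$tpm_pair)) na_pair else r$tpm_pair
    data.frame(gene_id = r$gene_id,
               T_nmf_pos = r$nmf_pair$t_pos, T_nmf_neg = r$nmf_pair$t_neg,
               T_tpm_pos = tp$t_pos, T_tpm_neg = tp$t_neg,
               T_mean = r$t_mean,
               dT_nmf_tpm = r$delta_nmf_tpm, dT_nmf_mean = r$delta_nmf_mean,
               stringsAsFactors = FALSE)
  }))
}
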