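#' Area under the ROC curve, Mann-Whitney formulation
#'
#' Fraction of (positive, negative) pairs where the positive outscores the
#' negative; ties credit 0.5. Computed from rank sums, which is exactly
#' the pairwise count with average-rank tie handling.
#'
#' @param scores numeric score per item (higher = more positive-like).
#' @param labels logical (or 0/1) per item, `TRUE` = positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return data.frame `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the endpoints, ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last of each tied block
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, cumsum(!l)[keep] / nn),
             tpr = c(0, cumsum(l)[keep] / np))
}

#' Alternative-isoform positive/negative gene labeling from TPM
#'
#' A gene is a positive when the transcript attaining its positive-maximum
#' TPM t statistic and the transcript attaining its negative-minimum one
#' are both significant at `-log10(p) > alpha` on opposite sides (the max
#' t must be positive and the min t negative, so two distinct transcripts
#' shift in opposite directions — an isoform switch). All other genes,
#' including single-transcript genes, are negatives.
#'
#' @param table an `odegr_tpm`.
#' @param labels an `odegr_labels`.
#' @param alpha significance cutoff on `-log10(p)` (the study uses 5, 10,
#'   15).
#' @param threshold transcript expression filter passed to
#'   [select_transcripts()].
#' @return list with character vectors `positive` and `negative`.
#' @export
alt_isoform_labels <- function(table, labels, alpha, threshold = 0.5) {
  selected <- select_transcripts(table, threshold)
  genes <- unique(table$tx2gene$gene_id[table$tx2gene$transcript_id %in%
                                          selected])
  groups <- .aligned_groups(labels, colnames(table$tpm))
  ia <- groups == "A"; ib <- groups == "B"
  is_pos <- vapply(genes, function(g) {
    rows <- gene_tpm_rows(table, g, selected)
    ts <- apply(rows, 1, function(v) welch_t(v[ia], v[ib]))
    ps <- apply(rows, 1, function(v) welch_p(v[ia], v[ib]))
    i_max <- which.max(ts); i_min <- which.min(ts)
    ts[i_max] > 0 && ts[i_min] < 0 &&
      -log10(ps[i_max]) > alpha && -log10(ps[i_min]) > alpha
  }, logical(1))
  list(positive = genes[is_pos], negative = genes[!is_pos])
}

#' Permutation p-value for a gene's overlooked-DE score
#'
#' Recomputes the gene's `dT_nmf_tpm` under `n_perm` size-preserving label
#' shuffles and reports the add-one empirical p,
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)`. The factorization does
#' not depend on the labels, so each rank is factorized once (a single NMF
#' seed) and only the Welch statistics are recomputed per permutation; the
#' observed score uses the identical single-seed scheme so that under the
#' null the observed value is exchangeable with the permuted ones.
#'
#' @inheritParams score_gene
#' @param n_perm number of permutations (>= 1).
#' @param seed seed for the shuffle sequence.
#' @param nmf_seed NMF initialization seed.
#' @return list with `p`, `observed`, `permuted` (numeric of length
#'   `n_perm`).
#' @export
permutation_null <- function(x, tpm_rows, labels, n_perm = 99L, seed = 1L,
                             ranks = c(2L, 5L, 10L), nmf_seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- .as_log(x)
  V <- t(x$values)
  feasible <- ranks[ranks <= min(dim(V))]
  if (length(feasible) == 0) stop("no feasible factorization rank")
  H_rows <- do.call(rbind, lapply(feasible, function(K)
    nmf_factorize(V, K, seed = nmf_seed)$H))
  tpm_rows <- as.matrix(tpm_rows)
  tpm_rows <- tpm_rows[, x$cell_ids, drop = FALSE]

  delta_for <- function(groups) {
    ia <- groups == "A"; ib <- groups == "B"
    t_h <- apply(H_rows, 1, function(h) welch_t(h[ia], h[ib]))
    t_tpm <- apply(tpm_rows, 1, function(v) welch_t(v[ia], v[ib]))
    delta_score(score_pair(max(t_h), min(t_h)),
                score_pair(max(t_tpm), min(t_tpm)))
  }

  groups0 <- .aligned_groups(labels, x$cell_ids)
  observed <- delta_for(groups0)
  permuted <- vapply(seq_len(n_perm), function(i) {
    li <- shuffle_labels(labels, seed = (seed * 1009L + i) %% .Machine$integer.max)
    delta_for(.aligned_groups(li, x$cell_ids))
  }, numeric(1))
  list(p = (1 + sum(permuted >= observed)) / (n_perm + 1),
       observed = observed, permuted = permuted)
}
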