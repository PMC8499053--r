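#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (bins x cells) into `W %*% H` with
#' `W` (bins x K) holding the bin loadings ("metagenes", candidate transcript
#' structures) and `H` (K x cells) the per-cell expression profile of each
#' structure. The squared Frobenius (Euclidean) reconstruction error is
#' minimized locally with Lee-Seung multiplicative updates, which keep both
#' factors non-negative and never increase the objective.
#'
#' Initial entries of `W` and `H` are drawn uniformly from `(0, s]` where `s`
#' is the mean of `V`, from a generator seeded with `seed`, so a fixed
#' `(V, K, seed, max_iter, tol)` gives bit-identical factors on re-run.
#'
#' @param V non-negative numeric matrix (bins x cells) with at least one
#'   positive entry.
#' @param K factorization rank, `1 <= K <= min(dim(V))`.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of update iterations.
#' @param tol relative objective decrease over a 10-iteration window below
#'   which iteration stops.
#' @param eps small constant added to update denominators.
#' @param track_objective record the objective at every iteration (in
#'   `objective_trace`); off by default since the evaluation costs a full
#'   reconstruction per iteration.
#' @return An object of class `odegr_nmf`: list with `W`, `H`, `K`, `seed`,
#'   `objective` (final squared Frobenius error), `objective_trace`
#'   (per-iteration objective starting at the initial factors, `NULL`
#'   unless `track_objective`) and `n_iter`.
#' @examples
#' V <- outer(c(1, 2, 3), c(2, 1, 4))
#' f <- nmf_factorize(V, K = 1, seed = 1)
#' f$objective < 1e-8
#' @export
nmf_factorize <- function(V, K, seed = 1L, max_iter = 500L, tol = 1e-5,
                          eps = 1e-12, track_objective = FALSE) {
  V <- as.matrix(V)
  if (!is.numeric(V)) stop("V must be numeric")
  if (any(!is.finite(V))) stop("V contains non-finite values")
  if (any(V < 0)) stop("V has negative entries; NMF requires non-negative input")
  if (all(V == 0)) stop("degenerate matrix: V is all zero")
  K <- as.integer(K)
  if (K < 1L || K > min(dim(V))) {
    stop(sprintf("rank K = %d must lie in [1, %d]", K, min(dim(V))))
  }
  s <- mean(V)
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  # runif() lives in [0,1); flip to (0,1] so no initial entry is exactly zero
  W0 <- matrix(s * (1 - runif(nrow(V) * K)), nrow(V), K)
  H0 <- matrix(s * (1 - runif(K * ncol(V))), K, ncol(V))
  res <- .nmf_mu_cpp(V, W0, H0, as.integer(max_iter), tol, eps, 10L,
                     isTRUE(track_objective))
  structure(
    list(W = res$W, H = res$H, K = K, seed = as.integer(seed),
         objective = res$objective,
         objective_trace = if (isTRUE(track_objective)) res$objective_trace,
         n_iter = res$n_iter),
    class = "odegr_nmf")
}

#' Squared Frobenius reconstruction error of a factorization
#'
#' @param f an `odegr_nmf` object.
#' @param V the matrix that was factorized.
#' @return `sum((V - W %*% H)^2)`.
#' @export
reconstruction_error <- function(f, V) {
  V <- as.matrix(V)
  if (nrow(f$W) != nrow(V) || ncol(f$H) != ncol(V)) {
    stop(sprintf("shape mismatch: factors reconstruct %d x %d, V is %d x %d",
                 nrow(f$W), ncol(f$H), nrow(V), ncol(V)))
  }
  sum((V - f$W %*% f$H)^2)
}

#' @export
print.odegr_nmf <- function(x, ...) {
  cat(sprintf("NMF factorization: %d bins x %d cells, K = %d, seed = %d\n",
              nrow(x$W), ncol(x$H), x$K, x$seed))
  cat(sprintf("  objective %.6g after %d iterations\n", x$objective, x$n_iter))
  invisible(x)
}

# Run `expr` under a temporary RNG seed without disturbing the caller's
# RNG state (package functions must not clobber user seeds).
.seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_seed <- function(seed, expr) {
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  expr
}
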