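// Lee-Seung multiplicative updates for the Euclidean (squared Frobenius)
// NMF objective ||V - W H||_F^2.  The update rules guarantee a
// non-increasing objective; a small eps in the denominators guards
// against division by zero without breaking non-negativity.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// V: m x n (bins x cells), W0: m x k, H0: k x n.
// Convergence: every `check_every` iterations, stop when the relative
// decrease of the objective over that window falls below `tol`.
// With track = false the objective is evaluated only at the checks
// (and on entry/exit); with track = true it is recorded every
// iteration so callers can verify the monotonicity guarantee.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, const arma::mat& W0,
                      const arma::mat& H0, int max_iter, double tol,
                      double eps, int check_every, bool track) {
    mat W = W0;
    mat H = H0;
    std::vector<double> trace;
    double obj0 = accu(square(V - W * H));
    if (track) trace.push_back(obj0);

    int it = 0;
    double window_ref = obj0;
    double obj = obj0;
    for (it = 1; it <= max_iter; ++it) {
        // H <- H .* (W'V) ./ (W'W H + eps)
        H %= (W.t() * V) / (W.t() * W * H + eps);
        // W <- W .* (V H') ./ (W H H' + eps)
        W %= (V * H.t()) / (W * (H * H.t()) + eps);
        if (track) {
            obj = accu(square(V - W * H));
            trace.push_back(obj);
        }
        if (it % check_every == 0) {
            if (!track) obj = accu(square(V - W * H));
            double denom = std::max(window_ref, 1e-300);
            if ((window_ref - obj) / denom < tol) break;
            window_ref = obj;
        }
    }
    if (it > max_iter) it = max_iter;
    if (!track && it % check_every != 0) obj = accu(square(V - W * H));

    return Rcpp::List::create(
        Rcpp::Named("W") = W,
        Rcpp::Named("H") = H,
        Rcpp::Named("objective") = obj,
        Rcpp::Named("objective_trace") = trace,
        Rcpp::Named("n_iter") = it);
}
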