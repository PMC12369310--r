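// Multiplicative-update NNMF (Lee-Seung, Frobenius objective).
// D (m x n) ~ W (m x k) * H (k x n); all factors non-negative.
// The R wrapper handles initialization, restarts and reporting.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nnmf_mu_cpp(const arma::mat& D, arma::mat W, arma::mat H,
                       int max_iter, double tol) {
  const double eps = 1e-12;
  double sse_prev = accu(square(D - W * H));
  double sse = sse_prev;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H <- H .* (W'D) ./ (W'W H)
    H %= (W.t() * D) / (W.t() * W * H + eps);
    // W <- W .* (D H') ./ (W H H')
    W %= (D * H.t()) / (W * (H * H.t()) + eps);
    sse = accu(square(D - W * H));
    if (sse_prev > 0 && std::abs(sse_prev - sse) / sse_prev < tol) break;
    sse_prev = sse;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("sse") = sse,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
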