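// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Matrix exponential of a dense square matrix (scaling-and-squaring Pade).
// Compartmental rate matrices with equal transit rates are defective, so an
// eigendecomposition is not an option; expmat handles the Jordan structure.
// [[Rcpp::export]]
arma::mat expm_dense(const arma::mat& A) {
  return arma::expmat(A);
}
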