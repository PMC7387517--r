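// Hot loops of the 1D convolution layers: im2col + one GEMM per call.
// Activations are cubes of dim (channels, length, batch); weights are
// (filters) x (channels * kernel) with same (zero) padding and stride 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat im2col1d(const cube& X, const int k) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int pad = (k - 1) / 2;
  mat Xc(C * k, (size_t)L * B, fill::zeros);
  for (int bt = 0; bt < B; ++bt) {
    const mat& Xs = X.slice(bt);
    for (int t = 0; t < L; ++t) {
      double* dst = Xc.colptr((size_t)bt * L + t);
      for (int j = 0; j < k; ++j) {
        const int p = t + j - pad;
        if (p >= 0 && p < L)
          std::memcpy(dst + (size_t)j * C, Xs.colptr(p), C * sizeof(double));
      }
    }
  }
  return Xc;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, const int k) {
  const int L = X.n_cols, B = X.n_slices, F = W.n_rows;
  mat Y = W * im2col1d(X, k);
  Y.each_col() += b;
  cube out(F, L, B);
  std::memcpy(out.memptr(), Y.memptr(), Y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, const int k) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices, F = W.n_rows;
  const int pad = (k - 1) / 2;
  const mat Xc = im2col1d(X, k);
  const mat dYm(const_cast<double*>(dY.memptr()), F, (size_t)L * B, false);
  mat dW = dYm * Xc.t();
  vec db = sum(dYm, 1);
  mat dXc = W.t() * dYm;
  cube dX(C, L, B, fill::zeros);
  for (int bt = 0; bt < B; ++bt) {
    mat& dXs = dX.slice(bt);
    for (int t = 0; t < L; ++t) {
      const double* src = dXc.colptr((size_t)bt * L + t);
      for (int j = 0; j < k; ++j) {
        const int p = t + j - pad;
        if (p >= 0 && p < L) {
          double* dst = dXs.colptr(p);
          const double* s = src + (size_t)j * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
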