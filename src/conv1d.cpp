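// Length-preserving 1D convolution, forward and backward, for the U-Net.
//
// Tensors use the (channels, time, batch) layout of the R side: an
// arma::cube with n_rows = channels, n_cols = time, n_slices = batch.
// Rather than materializing an im2col matrix (whose construction is
// memory-bandwidth bound at these shapes), the convolution accumulates one
// GEMM per kernel tap over submatrix views, handling the "same"-padding
// boundary by clipping the valid column range. Weights W are stored
// (C_out x k*C_in) with column index (j*C_in + c) for tap j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Valid output-column range [t0, t1] for tap j with source offset `off`:
// source column = output column + off must lie in [0, T-1].
static inline bool tap_range(const int off, const int T, int& t0, int& t1) {
  t0 = std::max(0, -off);
  t1 = std::min(T - 1, T - 1 - off);
  return t0 <= t1;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, const int k, const int d) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int padl = ((k - 1) * d) / 2;
  const int Cout = W.n_rows;
  cube Y(Cout, T, B);
  for (int s = 0; s < B; ++s) {
    mat& ys = const_cast<mat&>(Y.slice(s));
    ys.each_col() = b;
    for (int j = 0; j < k; ++j) {
      const int off = j * d - padl;
      int t0, t1;
      if (!tap_range(off, T, t0, t1)) continue;
      ys.cols(t0, t1) +=
          W.cols(j * C, (j + 1) * C - 1) * X.slice(s).cols(t0 + off, t1 + off);
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& dY, const arma::cube& X,
                      const arma::mat& W, const int k, const int d) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int padl = ((k - 1) * d) / 2;
  const int Cout = W.n_rows;
  cube dX(C, T, B, fill::zeros);
  mat dW(Cout, k * C, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& dys = dY.slice(s);
    db += sum(dys, 1);
    for (int j = 0; j < k; ++j) {
      const int off = j * d - padl;
      int t0, t1;
      if (!tap_range(off, T, t0, t1)) continue;
      const mat Wj = W.cols(j * C, (j + 1) * C - 1);
      dX.slice(s).cols(t0 + off, t1 + off) += Wj.t() * dys.cols(t0, t1);
      dW.cols(j * C, (j + 1) * C - 1) +=
          dys.cols(t0, t1) * X.slice(s).cols(t0 + off, t1 + off).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
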