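// Compiled kernels for the CNN engine: im2col convolution (the gemm itself
// goes through the BLAS via Armadillo), ReLU, pool-by-2 and global average
// pooling, forward and backward. Tensors arrive as R arrays laid out
// (time, batch, channel), which matches Armadillo cube memory order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X (T, N, C), W (k*C x F), b (F). Same padding (floor/ceil split).
// Returns Y (T, N, F) and the im2col matrix M ((T*N) x (k*C + 1), trailing
// ones column so the bias add rides the gemm).
// [[Rcpp::export]]
List conv1d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                    const arma::vec& b, const int k) {
  const int T = X.n_rows, N = X.n_cols, C = X.n_slices;
  const int pad = (k - 1) / 2;
  arma::cube Xp(T + k - 1, N, C, arma::fill::zeros);
  Xp.rows(pad, pad + T - 1) = X;
  arma::mat M(T * N, k * C + 1);
  M.col(k * C).ones();
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = Xp.slice(c);
    for (int dd = 0; dd < k; ++dd) {
      M.col(dd * C + c) = arma::vectorise(s.rows(dd, dd + T - 1));
    }
  }
  arma::mat Wb = arma::join_cols(W, b.t());
  arma::mat Ym = M * Wb;
  NumericVector Y(Ym.begin(), Ym.end());
  Y.attr("dim") = IntegerVector::create(T, N, W.n_cols);
  return List::create(_["out"] = Y, _["M"] = M);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& dY, const arma::mat& M,
                    const arma::mat& W, const int k) {
  const int T = dY.n_rows, N = dY.n_cols, F = dY.n_slices;
  const int C = (M.n_cols - 1) / k;
  const int pad = (k - 1) / 2;
  const arma::mat dYm(const_cast<double*>(dY.memptr()), T * N, F, false);
  arma::mat dWb = M.t() * dYm;
  arma::mat dM = dYm * W.t();
  arma::cube dXp(T + k - 1, N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& s = dXp.slice(c);
    for (int dd = 0; dd < k; ++dd) {
      s.rows(dd, dd + T - 1) += arma::reshape(dM.col(dd * C + c), T, N);
    }
  }
  arma::cube dXc = dXp.rows(pad, pad + T - 1);
  NumericVector dX(dXc.begin(), dXc.end());
  dX.attr("dim") = IntegerVector::create(T, N, C);
  return List::create(_["dX"] = dX,
                      _["dW"] = dWb.rows(0, k * C - 1),
                      _["db"] = arma::vec(dWb.row(k * C).t()));
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector X) {
  NumericVector Y(X.size());
  for (R_xlen_t i = 0; i < X.size(); ++i) Y[i] = X[i] > 0 ? X[i] : 0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dY, NumericVector Y) {
  NumericVector dX(dY.size());
  for (R_xlen_t i = 0; i < dY.size(); ++i) dX[i] = Y[i] > 0 ? dY[i] : 0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}

// pool-by-2 along the first axis; ties keep the earlier sample
// [[Rcpp::export]]
List maxpool1d_fwd_cpp(const arma::cube& X) {
  const int T = X.n_rows, N = X.n_cols, C = X.n_slices, H = T / 2;
  arma::cube Y(H, N, C);
  LogicalVector take1(H * N * C);
  R_xlen_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < H; ++h, ++q) {
        const double a = X(2 * h, n, c), bv = X(2 * h + 1, n, c);
        const bool first = a >= bv;
        Y(h, n, c) = first ? a : bv;
        take1[q] = first;
      }
  NumericVector Yo(Y.begin(), Y.end());
  Yo.attr("dim") = IntegerVector::create(H, N, C);
  take1.attr("dim") = IntegerVector::create(H, N, C);
  return List::create(_["out"] = Yo, _["take1"] = take1);
}

// [[Rcpp::export]]
NumericVector maxpool1d_bwd_cpp(const arma::cube& dY, LogicalVector take1) {
  const int H = dY.n_rows, N = dY.n_cols, C = dY.n_slices;
  arma::cube dX(2 * H, N, C, arma::fill::zeros);
  R_xlen_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < H; ++h, ++q) {
        dX(2 * h + (take1[q] ? 0 : 1), n, c) = dY(h, n, c);
      }
  NumericVector o(dX.begin(), dX.end());
  o.attr("dim") = IntegerVector::create(2 * H, N, C);
  return o;
}

// (T, N, C) -> (N, C) mean over time
// [[Rcpp::export]]
NumericMatrix gap_fwd_cpp(const arma::cube& X) {
  const int T = X.n_rows, N = X.n_cols, C = X.n_slices;
  NumericMatrix Y(N, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = X.slice(c);
    arma::rowvec m = arma::mean(s, 0);
    for (int n = 0; n < N; ++n) Y(n, c) = m[n];
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector gap_bwd_cpp(const arma::mat& dY, const int T) {
  const int N = dY.n_rows, C = dY.n_cols;
  arma::cube dX(T, N, C);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      dX.slice(c).col(n).fill(dY(n, c) / T);
  NumericVector o(dX.begin(), dX.end());
  o.attr("dim") = IntegerVector::create(T, N, C);
  return o;
}
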