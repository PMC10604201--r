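// Batched 1-D neural-network primitives for the dilated residual
// regressor: dilated/strided convolution forward and backward passes,
// non-overlapping average pooling, global average pooling, ReLU, and a
// plain LSTM forward recursion for the recurrent baselines.
//
// Layout: a batch is a cube (channels x length x batch); convolution
// weights are a cube (filters x in_channels x kernel_taps) so each kernel
// tap is one GEMM against a (possibly dilated) column range.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat pad_cols(const mat& x, int pad_l, int pad_r) {
  if (pad_l == 0 && pad_r == 0) return x;
  mat xp(x.n_rows, x.n_cols + pad_l + pad_r, fill::zeros);
  xp.cols(pad_l, pad_l + x.n_cols - 1) = x;
  return xp;
}

static inline int out_len(int L, int k, int dil, int stride,
                          int pad_l, int pad_r) {
  int span = (k - 1) * dil;
  int lp = L + pad_l + pad_r;
  if (lp - span - 1 < 0) Rcpp::stop("input shorter than the receptive span");
  return (lp - span - 1) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv1d_fw")]]
arma::cube conv1d_fw(const arma::cube& x, const arma::cube& W,
                     const arma::vec& b, int dil, int stride,
                     int pad_l, int pad_r) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int F = W.n_rows, k = W.n_slices;
  if ((int)W.n_cols != C) Rcpp::stop("channel mismatch: x has %d, W expects %d",
                                     C, (int)W.n_cols);
  const int Lout = out_len(L, k, dil, stride, pad_l, pad_r);
  cube y(F, Lout, N);
  mat gather(C, Lout);
  for (int n = 0; n < N; n++) {
    mat xp = pad_cols(x.slice(n), pad_l, pad_r);
    mat acc(F, Lout, fill::zeros);
    for (int j = 0; j < k; j++) {
      const int off = j * dil;
      if (stride == 1) {
        acc += W.slice(j) * xp.cols(off, off + Lout - 1);
      } else {
        for (int o = 0; o < Lout; o++) gather.col(o) = xp.col(o * stride + off);
        acc += W.slice(j) * gather;
      }
    }
    acc.each_col() += b;
    y.slice(n) = acc;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv1d_bw")]]
Rcpp::List conv1d_bw(const arma::cube& x, const arma::cube& W,
                     const arma::cube& dy, int dil, int stride,
                     int pad_l, int pad_r) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int F = W.n_rows, k = W.n_slices;
  const int Lout = dy.n_cols;
  cube dx(C, L, N, fill::zeros);
  cube dW(F, C, k, fill::zeros);
  vec db(F, fill::zeros);
  mat gather(C, Lout);
  for (int n = 0; n < N; n++) {
    mat xp = pad_cols(x.slice(n), pad_l, pad_r);
    mat dxp(C, xp.n_cols, fill::zeros);
    const mat& dyn = dy.slice(n);
    db += sum(dyn, 1);
    for (int j = 0; j < k; j++) {
      const int off = j * dil;
      if (stride == 1) {
        dW.slice(j) += dyn * xp.cols(off, off + Lout - 1).t();
        dxp.cols(off, off + Lout - 1) += W.slice(j).t() * dyn;
      } else {
        for (int o = 0; o < Lout; o++) gather.col(o) = xp.col(o * stride + off);
        dW.slice(j) += dyn * gather.t();
        mat dg = W.slice(j).t() * dyn;
        for (int o = 0; o < Lout; o++) dxp.col(o * stride + off) += dg.col(o);
      }
    }
    dx.slice(n) = dxp.cols(pad_l, pad_l + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".cpp_avgpool_fw")]]
arma::cube avgpool_fw(const arma::cube& x, int width) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Lout = L / width;
  if (Lout < 1) Rcpp::stop("input shorter than the pooling width");
  cube y(C, Lout, N, fill::zeros);
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < Lout; o++) {
      y.slice(n).col(o) =
        mean(x.slice(n).cols(o * width, o * width + width - 1), 1);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_avgpool_bw")]]
arma::cube avgpool_bw(const arma::cube& dy, int width, int L) {
  const int C = dy.n_rows, Lout = dy.n_cols, N = dy.n_slices;
  cube dx(C, L, N, fill::zeros);
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < Lout; o++) {
      vec g = dy.slice(n).col(o) / width;
      for (int j = 0; j < width; j++) dx.slice(n).col(o * width + j) = g;
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_relu_fw")]]
arma::cube relu_fw(const arma::cube& x) {
  cube y = x;
  y.transform([](double v) { return v > 0 ? v : 0.0; });
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bw")]]
arma::cube relu_bw(const arma::cube& y, const arma::cube& dy) {
  cube dx = dy;
  for (uword i = 0; i < y.n_elem; i++) if (y(i) <= 0) dx(i) = 0;
  return dx;
}

// [[Rcpp::export(name = ".cpp_gap_fw")]]
arma::mat gap_fw(const arma::cube& x) {
  const int C = x.n_rows, N = x.n_slices;
  mat g(C, N);
  for (int n = 0; n < N; n++) g.col(n) = mean(x.slice(n), 1);
  return g;
}

// [[Rcpp::export(name = ".cpp_gap_bw")]]
arma::cube gap_bw(const arma::mat& dg, int L) {
  const int C = dg.n_rows, N = dg.n_cols;
  cube dx(C, L, N);
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < L; o++) dx.slice(n).col(o) = dg.col(n) / L;
  }
  return dx;
}

// Plain LSTM forward recursion over one sequence. Gate order along the
// first dimension of Wx/Wh/b: input, forget, candidate, output.
// [[Rcpp::export(name = ".cpp_lstm_fw")]]
arma::mat lstm_fw(const arma::mat& x, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b) {
  const int L = x.n_cols;
  const int H = Wh.n_cols;
  mat hs(H, L);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int t = 0; t < L; t++) {
    vec z = Wx * x.col(t) + Wh * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    hs.col(t) = h;
  }
  return hs;
}
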