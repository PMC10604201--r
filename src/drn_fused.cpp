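// Fused single-precision training engine for the dilated residual
// regressor. The modular double-precision path in R (.drn_forward /
// .drn_backward) defines the reference semantics; this engine computes
// the same forward pass and gradients in float32 with batch-wide
// im2col + GEMM and no intermediate R copies, which is what makes
// CPU training of the network practical. Parameter layout matches the
// column-major order of the flattened R parameter list exactly.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Geom {
  int n_blk, k_blk, d_blk, k_dwn, filters_c, s_c, n_den, L0, C0;
  // derived per stage
  std::vector<int> C_in, F, L_in, L_down, L_pool;
  int C_last, L_last;
};

static void same_pads_s1(int k, int dil, int& pl, int& pr) {
  int span = (k - 1) * dil;
  pl = span / 2; pr = span - pl;
}

static void same_pads_s2(int k, int L, int& pl, int& pr, int& Lout) {
  int span = k - 1;
  Lout = (L + 1) / 2;
  int pad = (Lout - 1) * 2 + span + 1 - L;
  if (pad < 0) pad = 0;
  pl = pad / 2; pr = pad - pl;
}

static Geom make_geom(const Rcpp::List& g) {
  Geom geo;
  geo.n_blk = g["n_blk"]; geo.k_blk = g["kernel_blk"]; geo.d_blk = g["d_blk"];
  geo.k_dwn = g["kernel_dwn"]; geo.filters_c = g["filters_c"];
  geo.s_c = g["s_c"]; geo.n_den = g["n_den"];
  geo.L0 = g["input_len"]; geo.C0 = g["input_channels"];
  int L = geo.L0;
  for (int s = 0; s < geo.n_blk; s++) {
    // F_s = 2^(filters_c + s) with 0-based s; C_in is the previous stage's F
    int C = (s == 0) ? geo.C0 : (1 << (geo.filters_c + s - 1));
    geo.C_in.push_back(C);
    geo.F.push_back(1 << (geo.filters_c + s));
    geo.L_in.push_back(L);
    int pl, pr, Ld;
    same_pads_s2(geo.k_dwn, L, pl, pr, Ld);
    geo.L_down.push_back(Ld);
    int Lp = Ld / geo.s_c;
    if (Lp < 1) Rcpp::stop("input too short for the configured stages");
    geo.L_pool.push_back(Lp);
    L = Lp;
  }
  geo.C_last = geo.F[geo.n_blk - 1];
  geo.L_last = L;
  return geo;
}

// im2col over a batch-blocked activation X (C, L*N) -> (C*k, Lout*N)
static void im2col(const fmat& X, int C, int L, int N, int k, int dil,
                   int stride, int pad_l, int Lout, fmat& out) {
  out.set_size(C * k, Lout * N);
  const float* xp = X.memptr();
  float* op = out.memptr();
  const size_t ccol = (size_t)C;
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < Lout; o++) {
      float* dst = op + ((size_t)(n * Lout + o)) * (C * k);
      for (int j = 0; j < k; j++) {
        int src_col = o * stride + j * dil - pad_l;
        if (src_col >= 0 && src_col < L) {
          std::memcpy(dst + j * C, xp + ((size_t)(n * L + src_col)) * ccol,
                      ccol * sizeof(float));
        } else {
          std::memset(dst + j * C, 0, ccol * sizeof(float));
        }
      }
    }
  }
}

// scatter-add the im2col gradient back to activation shape
static void col2im_add(const fmat& dXC, int C, int L, int N, int k, int dil,
                       int stride, int pad_l, int Lout, fmat& dX) {
  const float* gp = dXC.memptr();
  float* dp = dX.memptr();
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < Lout; o++) {
      const float* src = gp + ((size_t)(n * Lout + o)) * (C * k);
      for (int j = 0; j < k; j++) {
        int dst_col = o * stride + j * dil - pad_l;
        if (dst_col >= 0 && dst_col < L) {
          float* dst = dp + ((size_t)(n * L + dst_col)) * C;
          const float* s = src + j * C;
          for (int c = 0; c < C; c++) dst[c] += s[c];
        }
      }
    }
  }
}

struct ConvPars { fmat W; fvec b; };

// zero entries of d where the activation a is non-positive (ReLU mask)
static inline void relu_mask(fmat& d, const fmat& a) {
  float* dp = d.memptr();
  const float* ap = a.memptr();
  const size_t n = d.n_elem;
  for (size_t i = 0; i < n; i++) if (ap[i] <= 0.0f) dp[i] = 0.0f;
}

// reads one conv layer (W stored column-major as (F, C, k)) from theta
static ConvPars read_conv(const double* th, size_t& off, int F, int C, int k) {
  ConvPars cp;
  cp.W.set_size(F, C * k);
  for (size_t i = 0; i < (size_t)F * C * k; i++) cp.W(i) = (float)th[off + i];
  off += (size_t)F * C * k;
  cp.b.set_size(F);
  for (int i = 0; i < F; i++) cp.b(i) = (float)th[off + i];
  off += F;
  return cp;
}

static void write_grad(std::vector<double>& g, size_t& off, const fmat& dW,
                       const fvec& db) {
  for (size_t i = 0; i < dW.n_elem; i++) g[off + i] = (double)dW(i);
  off += dW.n_elem;
  for (size_t i = 0; i < db.n_elem; i++) g[off + i] = (double)db(i);
  off += db.n_elem;
}

struct Net {
  Geom geo;
  // stages x branches x {conv1, conv2}; stages x down
  std::vector<std::array<std::array<ConvPars, 2>, 3>> blocks;
  std::vector<ConvPars> down;
  fmat W1; fvec b1; fmat W2; fvec b2;
};

static Net read_net(const Rcpp::NumericVector& theta, const Rcpp::List& g) {
  Net net;
  net.geo = make_geom(g);
  const Geom& geo = net.geo;
  const double* th = theta.begin();
  size_t off = 0;
  for (int s = 0; s < geo.n_blk; s++) {
    std::array<std::array<ConvPars, 2>, 3> brs;
    for (int b = 0; b < 3; b++) {
      brs[b][0] = read_conv(th, off, geo.F[s], geo.C_in[s], geo.k_blk);
      brs[b][1] = read_conv(th, off, geo.F[s], geo.F[s], geo.k_blk);
    }
    net.blocks.push_back(brs);
    net.down.push_back(read_conv(th, off, geo.F[s], geo.F[s], geo.k_dwn));
  }
  net.W1.set_size(geo.n_den, geo.C_last);
  for (size_t i = 0; i < net.W1.n_elem; i++) net.W1(i) = (float)th[off + i];
  off += net.W1.n_elem;
  net.b1.set_size(geo.n_den);
  for (int i = 0; i < geo.n_den; i++) net.b1(i) = (float)th[off + i];
  off += geo.n_den;
  net.W2.set_size(1, geo.n_den);
  for (int i = 0; i < geo.n_den; i++) net.W2(i) = (float)th[off + i];
  off += geo.n_den;
  net.b2.set_size(1);
  net.b2(0) = (float)th[off];
  off += 1;
  if (off != (size_t)theta.size()) {
    Rcpp::stop("parameter vector length %d does not match geometry (%d)",
               (int)theta.size(), (int)off);
  }
  return net;
}

struct StageCache {
  fmat X;                       // stage input (C_in, L_in*N)
  fmat A1[3], A2[3];            // branch activations (F, L_in*N)
  fmat Y;                       // block output (F, L_in*N)
  fmat D;                       // post-relu downsample (F, L_down*N)
};

struct FwdOut {
  frowvec out;
  std::vector<StageCache> st;
  fmat G, A1h;
};

static void avgpool(const fmat& X, int C, int L, int N, int w, fmat& P) {
  int Lp = L / w;
  P.zeros(C, (size_t)Lp * N);
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < Lp; o++) {
      for (int j = 0; j < w; j++) {
        P.unsafe_col((size_t)n * Lp + o) +=
          X.unsafe_col((size_t)n * L + o * w + j);
      }
      P.unsafe_col((size_t)n * Lp + o) /= (float)w;
    }
  }
}

static void forward(const Net& net, fmat x0, int N, bool keep, FwdOut& fo) {
  const Geom& geo = net.geo;
  fmat X = std::move(x0);
  if (keep) fo.st.resize(geo.n_blk);
  fmat XC, H;
  int pl1, pr1;
  same_pads_s1(geo.k_blk, geo.d_blk, pl1, pr1);
  for (int s = 0; s < geo.n_blk; s++) {
    const int C = geo.C_in[s], F = geo.F[s], L = geo.L_in[s];
    fmat Y(F, (size_t)L * N, fill::zeros);
    StageCache* sc = keep ? &fo.st[s] : nullptr;
    for (int b = 0; b < 3; b++) {
      im2col(X, C, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, XC);
      fmat A1 = net.blocks[s][b][0].W * XC;
      A1.each_col() += net.blocks[s][b][0].b;
      A1.transform([](float v) { return v > 0 ? v : 0.0f; });
      im2col(A1, F, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, XC);
      fmat A2 = net.blocks[s][b][1].W * XC;
      A2.each_col() += net.blocks[s][b][1].b;
      A2.transform([](float v) { return v > 0 ? v : 0.0f; });
      Y += A2;
      if (keep) { sc->A1[b] = std::move(A1); sc->A2[b] = std::move(A2); }
    }
    Y.each_row() += mean(X, 0);
    int pl, pr, Ld;
    same_pads_s2(geo.k_dwn, L, pl, pr, Ld);
    im2col(Y, F, L, N, geo.k_dwn, 1, 2, pl, Ld, XC);
    fmat D = net.down[s].W * XC;
    D.each_col() += net.down[s].b;
    D.transform([](float v) { return v > 0 ? v : 0.0f; });
    fmat P;
    avgpool(D, F, Ld, N, geo.s_c, P);
    if (keep) {
      sc->X = std::move(X);
      sc->Y = std::move(Y);
      sc->D = std::move(D);
    }
    X = std::move(P);
  }
  // head
  fo.G.set_size(geo.C_last, N);
  for (int n = 0; n < N; n++) {
    fo.G.col(n) = mean(X.cols((size_t)n * geo.L_last,
                              (size_t)(n + 1) * geo.L_last - 1), 1);
  }
  fmat Z1 = net.W1 * fo.G;
  Z1.each_col() += net.b1;
  Z1.transform([](float v) { return v > 0 ? v : 0.0f; });
  fo.A1h = std::move(Z1);
  fo.out = net.W2 * fo.A1h + net.b2(0);
}

} // namespace

// [[Rcpp::export(name = ".cpp_drn_predict")]]
Rcpp::NumericVector drn_predict(const Rcpp::NumericVector& theta,
                                const Rcpp::List& geom,
                                const Rcpp::NumericMatrix& x) {
  Net net = read_net(theta, geom);
  const int N = x.nrow(), L = x.ncol();
  if (L != net.geo.L0 * net.geo.C0) {
    Rcpp::stop("shape error: windows have %d samples, model expects %d",
               L, net.geo.L0 * net.geo.C0);
  }
  fmat x0(net.geo.C0, (size_t)net.geo.L0 * N);
  for (int n = 0; n < N; n++) {
    for (int l = 0; l < net.geo.L0; l++) x0(0, (size_t)n * net.geo.L0 + l) = (float)x(n, l);
  }
  FwdOut fo;
  forward(net, std::move(x0), N, false, fo);
  Rcpp::NumericVector out(N);
  for (int n = 0; n < N; n++) out[n] = fo.out(n);
  return out;
}

// [[Rcpp::export(name = ".cpp_drn_fw_bw")]]
Rcpp::List drn_fw_bw(const Rcpp::NumericVector& theta,
                     const Rcpp::List& geom,
                     const Rcpp::NumericMatrix& x,
                     const Rcpp::NumericVector& y) {
  Net net = read_net(theta, geom);
  const Geom& geo = net.geo;
  const int N = x.nrow();
  if (x.ncol() != geo.L0 * geo.C0) Rcpp::stop("shape error");
  fmat x0(geo.C0, (size_t)geo.L0 * N);
  for (int n = 0; n < N; n++) {
    for (int l = 0; l < geo.L0; l++) x0(0, (size_t)n * geo.L0 + l) = (float)x(n, l);
  }
  FwdOut fo;
  forward(net, std::move(x0), N, true, fo);

  double loss = 0;
  frowvec dout(N);
  for (int n = 0; n < N; n++) {
    double e = (double)fo.out(n) - y[n];
    loss += std::abs(e);
    dout(n) = (float)((e > 0) - (e < 0)) / (float)N;
  }
  loss /= N;

  std::vector<double> grad(theta.size(), 0.0);

  // head backward
  fmat dZ2(dout.memptr(), 1, N, false);
  fmat dW2 = dZ2 * fo.A1h.t();
  fvec db2(1); db2(0) = accu(dZ2);
  fmat dA1h = net.W2.t() * dZ2;
  relu_mask(dA1h, fo.A1h);
  fmat dW1 = dA1h * fo.G.t();
  fvec db1 = sum(dA1h, 1);
  fmat dG = net.W1.t() * dA1h;

  // unpool head GAP
  fmat dX(geo.C_last, (size_t)geo.L_last * N);
  for (int n = 0; n < N; n++) {
    for (int o = 0; o < geo.L_last; o++) {
      dX.col((size_t)n * geo.L_last + o) = dG.col(n) / (float)geo.L_last;
    }
  }

  // per-stage grad storage (written to flat vector at the end, in order)
  std::vector<std::array<std::array<std::pair<fmat, fvec>, 2>, 3>> gblocks(geo.n_blk);
  std::vector<std::pair<fmat, fvec>> gdown(geo.n_blk);

  fmat XC;
  int pl1, pr1;
  same_pads_s1(geo.k_blk, geo.d_blk, pl1, pr1);
  for (int s = geo.n_blk - 1; s >= 0; s--) {
    const int C = geo.C_in[s], F = geo.F[s], L = geo.L_in[s];
    StageCache& sc = fo.st[s];
    int pl, pr, Ld;
    same_pads_s2(geo.k_dwn, L, pl, pr, Ld);
    // unpool
    fmat dD(F, (size_t)Ld * N, fill::zeros);
    int Lp = geo.L_pool[s];
    {
      const float* sp = dX.memptr();
      float* dp = dD.memptr();
      const float inv = 1.0f / (float)geo.s_c;
      for (int n = 0; n < N; n++) {
        for (int o = 0; o < Lp; o++) {
          const float* src = sp + ((size_t)n * Lp + o) * F;
          for (int j = 0; j < geo.s_c; j++) {
            float* dst = dp + ((size_t)n * Ld + o * geo.s_c + j) * F;
            for (int c = 0; c < F; c++) dst[c] = src[c] * inv;
          }
        }
      }
    }
    relu_mask(dD, sc.D);
    // downsample conv backward
    im2col(sc.Y, F, L, N, geo.k_dwn, 1, 2, pl, Ld, XC);
    gdown[s].first = dD * XC.t();
    gdown[s].second = sum(dD, 1);
    fmat dXCd = net.down[s].W.t() * dD;
    fmat dY(F, (size_t)L * N, fill::zeros);
    col2im_add(dXCd, F, L, N, geo.k_dwn, 1, 2, pl, Ld, dY);
    // shortcut: channel-mean broadcast
    frowvec dms = sum(dY, 0) / (float)C;
    fmat dXs(C, (size_t)L * N, fill::zeros);
    dXs.each_row() += dms;
    // branches
    for (int b = 0; b < 3; b++) {
      fmat dH2 = dY;
      relu_mask(dH2, sc.A2[b]);
      im2col(sc.A1[b], F, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, XC);
      gblocks[s][b][1].first = dH2 * XC.t();
      gblocks[s][b][1].second = sum(dH2, 1);
      fmat dXC2 = net.blocks[s][b][1].W.t() * dH2;
      fmat dA1(F, (size_t)L * N, fill::zeros);
      col2im_add(dXC2, F, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, dA1);
      relu_mask(dA1, sc.A1[b]);
      im2col(sc.X, C, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, XC);
      gblocks[s][b][0].first = dA1 * XC.t();
      gblocks[s][b][0].second = sum(dA1, 1);
      fmat dXC1 = net.blocks[s][b][0].W.t() * dA1;
      col2im_add(dXC1, C, L, N, geo.k_blk, geo.d_blk, 1, pl1, L, dXs);
    }
    dX = std::move(dXs);
  }

  // write grads in the canonical flat order
  size_t off = 0;
  for (int s = 0; s < geo.n_blk; s++) {
    for (int b = 0; b < 3; b++) {
      write_grad(grad, off, gblocks[s][b][0].first, gblocks[s][b][0].second);
      write_grad(grad, off, gblocks[s][b][1].first, gblocks[s][b][1].second);
    }
    write_grad(grad, off, gdown[s].first, gdown[s].second);
  }
  write_grad(grad, off, dW1, db1);
  write_grad(grad, off, dW2, db2);

  Rcpp::NumericVector preds(N);
  for (int n = 0; n < N; n++) preds[n] = fo.out(n);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("preds") = preds,
                            Rcpp::Named("grad") = Rcpp::NumericVector(grad.begin(), grad.end()));
}
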