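// Single-precision fused training/inference step for the network graph.
// One call runs forward (+ optionally backward) for a whole batch with all
// activations held as float32 inside C++ — the precision the major deep
// learning frameworks train in — which halves memory traffic relative to
// R's doubles. Parameters and gradients cross the R boundary as doubles.
// Dropout masks draw from R's RNG so runs are reproducible under set.seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

static fmat as_fmat(SEXP x) {
  NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static fvec as_fvec(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

struct Cache {
  fmat M;        // im2col (+ones) for conv; input for dense
  fcube act;     // relu output / pre-pool input etc.
  fcube mask;    // dropout keep mask (scaled); maxpool take-first mask
  fmat xhat;     // batchnorm
  fvec inv;
  arma::uvec idims;
};

// ---- primitive ops (float) ----
static fcube conv1d_f(const fcube& X, const fmat& W, const fvec& b, int k,
                      fmat& M_out) {
  const int T = X.n_rows, N = X.n_cols, C = X.n_slices;
  const int pad = (k - 1) / 2;
  fcube Xp(T + k - 1, N, C, arma::fill::zeros);
  Xp.rows(pad, pad + T - 1) = X;
  fmat M(T * N, k * C + 1);
  M.col(k * C).ones();
  for (int c = 0; c < C; ++c) {
    const fmat& s = Xp.slice(c);
    for (int dd = 0; dd < k; ++dd)
      M.col(dd * C + c) = arma::vectorise(s.rows(dd, dd + T - 1));
  }
  fmat Wb = arma::join_cols(W, b.t());
  fmat Ym = M * Wb;
  M_out = std::move(M);
  return fcube(Ym.memptr(), T, N, W.n_cols);
}

static fcube conv1d_b(const fcube& dY, const fmat& M, const fmat& W, int k,
                      fmat& dW, fvec& db) {
  const int T = dY.n_rows, N = dY.n_cols, F = dY.n_slices;
  const int C = (M.n_cols - 1) / k;
  const int pad = (k - 1) / 2;
  const fmat dYm(const_cast<float*>(dY.memptr()), T * N, F, false);
  fmat dWb = M.t() * dYm;
  dW = dWb.rows(0, k * C - 1);
  db = dWb.row(k * C).t();
  fmat dM = dYm * W.t();
  fcube dXp(T + k - 1, N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat& s = dXp.slice(c);
    for (int dd = 0; dd < k; ++dd)
      s.rows(dd, dd + T - 1) += arma::reshape(dM.col(dd * C + c), T, N);
  }
  return dXp.rows(pad, pad + T - 1);
}

// reshape (R, Wd, N) single-channel image -> (Wd, Ho*N, kh) channel view
static fcube img_to_chan(const fcube& X, int kh) {
  const int R = X.n_rows, Wd = X.n_cols, N = X.n_slices, Ho = R / kh;
  fcube out(Wd, Ho * N, kh);
  for (int dh = 0; dh < kh; ++dh)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < Ho; ++h)
        for (int w = 0; w < Wd; ++w)
          out(w, h + Ho * n, dh) = X(kh * h + dh, w, n);
  return out;
}
static fcube img_from_chan(const fcube& Xc, int kh, int Ho, int N) {
  const int Wd = Xc.n_rows;
  fcube out(kh * Ho, Wd, N);
  for (int dh = 0; dh < kh; ++dh)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < Ho; ++h)
        for (int w = 0; w < Wd; ++w)
          out(kh * h + dh, w, n) = Xc(w, h + Ho * n, dh);
  return out;
}

static fcube maxpool_f(const fcube& X, fcube& take1) {
  const int T = X.n_rows, N = X.n_cols, C = X.n_slices, H = T / 2;
  fcube Y(H, N, C);
  take1.set_size(H, N, C);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < H; ++h) {
        const float a = X(2 * h, n, c), b = X(2 * h + 1, n, c);
        const bool first = a >= b;
        Y(h, n, c) = first ? a : b;
        take1(h, n, c) = first ? 1.0f : 0.0f;
      }
  return Y;
}
static fcube maxpool_b(const fcube& dY, const fcube& take1) {
  const int H = dY.n_rows, N = dY.n_cols, C = dY.n_slices;
  fcube dX(2 * H, N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int h = 0; h < H; ++h) {
        if (take1(h, n, c) > 0.5f) dX(2 * h, n, c) = dY(h, n, c);
        else dX(2 * h + 1, n, c) = dY(h, n, c);
      }
  return dX;
}

// batchnorm over last (slice) axis of a cube viewed as (m x C)
static void bn_f(fmat& Xm, const fvec& gamma, const fvec& beta,
                 arma::vec& rmean, arma::vec& rvar, bool train,
                 fmat& xhat, fvec& inv, double momentum, double eps) {
  const int C = Xm.n_cols;
  xhat.set_size(Xm.n_rows, C);
  inv.set_size(C);
  for (int c = 0; c < C; ++c) {
    double mu, va;
    if (train) {
      mu = arma::mean(arma::conv_to<arma::vec>::from(Xm.col(c)));
      arma::vec xc = arma::conv_to<arma::vec>::from(Xm.col(c)) - mu;
      va = arma::mean(arma::square(xc));
      rmean[c] = momentum * rmean[c] + (1 - momentum) * mu;
      rvar[c] = momentum * rvar[c] + (1 - momentum) * va;
    } else {
      mu = rmean[c];
      va = rvar[c];
    }
    const float iv = 1.0f / std::sqrt((float)(va + eps));
    inv[c] = iv;
    xhat.col(c) = (Xm.col(c) - (float)mu) * iv;
    Xm.col(c) = xhat.col(c) * gamma[c] + beta[c];
  }
}
static fmat bn_b(const fmat& dYm, const fmat& xhat, const fvec& inv,
                 const fvec& gamma, bool train, fvec& dgamma, fvec& dbeta) {
  const int m = dYm.n_rows, C = dYm.n_cols;
  fmat dX(m, C);
  dgamma.set_size(C);
  dbeta.set_size(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = arma::dot(dYm.col(c), xhat.col(c));
    dbeta[c] = arma::accu(dYm.col(c));
    if (train) {
      fvec dxhat = dYm.col(c) * gamma[c];
      const float mdx = arma::mean(dxhat);
      const float mdxx = arma::mean(dxhat % xhat.col(c));
      dX.col(c) = (dxhat - mdx - xhat.col(c) * mdxx) * inv[c];
    } else {
      dX.col(c) = dYm.col(c) * gamma[c] * inv[c];
    }
  }
  return dX;
}

struct NodeP {
  std::string op;
  int in1 = 0, in2 = 0;
  int kernel = 0, kh = 0, kw = 0, filters = 0, units = 0;
  double rate = 0;
  std::string name, activation;
};

// [[Rcpp::export]]
List mignet_step_cpp(List nodes, List params, List state, NumericVector Xr,
                     IntegerVector y, NumericVector w, bool train,
                     bool backward, std::string head_act,
                     bool dropout_on = true, double bn_momentum = 0.99) {
  IntegerVector xdim = Xr.attr("dim");
  const int T0 = xdim[0], N = xdim[1], C0 = xdim[2];
  fcube X0(T0, N, C0);
  std::copy(Xr.begin(), Xr.end(), X0.begin());

  const int nn = nodes.size();
  std::vector<NodeP> np(nn);
  for (int i = 0; i < nn; ++i) {
    List nd = nodes[i];
    NodeP& p = np[i];
    p.op = as<std::string>(nd["op"]);
    IntegerVector in_ = nd["in_"];
    p.in1 = in_[0];
    p.in2 = in_.size() > 1 ? in_[1] : 0;
    p.name = as<std::string>(nd["name"]);
    if (nd.containsElementNamed("kernel")) p.kernel = as<int>(nd["kernel"]);
    if (nd.containsElementNamed("kh")) p.kh = as<int>(nd["kh"]);
    if (nd.containsElementNamed("kw")) p.kw = as<int>(nd["kw"]);
    if (nd.containsElementNamed("rate")) p.rate = as<double>(nd["rate"]);
    if (nd.containsElementNamed("activation"))
      p.activation = as<std::string>(nd["activation"]);
  }

  std::vector<fcube> outs(nn + 1);
  outs[0] = X0;
  std::vector<Cache> caches(nn);
  List new_state = clone(state);
  fmat Z;  // head input as (N x F)

  auto getW = [&](const std::string& nm) { return as_fmat(params[nm + "_W"]); };
  auto getb = [&](const std::string& nm) { return as_fvec(params[nm + "_b"]); };

  for (int i = 0; i < nn; ++i) {
    NodeP& p = np[i];
    fcube& xin = outs[p.in1];
    Cache& cc = caches[i];
    if (p.op == "conv1d") {
      outs[i + 1] = conv1d_f(xin, getW(p.name), getb(p.name), p.kernel, cc.M);
    } else if (p.op == "conv2d") {
      const int R = xin.n_rows, Wd = xin.n_cols, Nn = xin.n_slices;
      const int Ho = R / p.kh;
      fcube Xc = img_to_chan(xin, p.kh);
      fcube Y = conv1d_f(Xc, getW(p.name), getb(p.name), p.kw, cc.M);
      cc.idims = {(arma::uword)R, (arma::uword)Wd, (arma::uword)Nn,
                  (arma::uword)Ho};
      outs[i + 1] = fcube(Y.memptr(), Wd * Ho, Nn, Y.n_slices);
    } else if (p.op == "relu") {
      fcube Y = xin;
      Y.transform([](float v) { return v > 0 ? v : 0.0f; });
      cc.act = Y;
      outs[i + 1] = std::move(Y);
    } else if (p.op == "maxpool1d") {
      outs[i + 1] = maxpool_f(xin, cc.mask);
    } else if (p.op == "dropout") {
      if (train && dropout_on && p.rate > 0) {
        fcube keep(xin.n_rows, xin.n_cols, xin.n_slices);
        const float scale = 1.0f / (1.0f - (float)p.rate);
        for (arma::uword q = 0; q < keep.n_elem; ++q)
          keep[q] = (unif_rand() >= p.rate) ? scale : 0.0f;
        cc.mask = keep;
        outs[i + 1] = xin % keep;
      } else {
        outs[i + 1] = xin;
      }
    } else if (p.op == "batchnorm") {
      const int C = xin.n_slices;
      fmat Xm(const_cast<float*>(xin.memptr()), xin.n_elem / C, C);
      fmat Ym = Xm;  // copy
      arma::vec rmean = as<arma::vec>(new_state[p.name + "_mean"]);
      arma::vec rvar = as<arma::vec>(new_state[p.name + "_var"]);
      bn_f(Ym, as_fvec(params[p.name + "_gamma"]),
           as_fvec(params[p.name + "_beta"]), rmean, rvar, train, cc.xhat,
           cc.inv, bn_momentum, 1e-3);
      if (train) {
        new_state[p.name + "_mean"] = rmean;
        new_state[p.name + "_var"] = rvar;
      }
      outs[i + 1] = fcube(Ym.memptr(), xin.n_rows, xin.n_cols, C);
    } else if (p.op == "gap") {
      const int T = xin.n_rows, C = xin.n_slices;
      fcube Y(1, xin.n_cols, C);
      for (int c = 0; c < C; ++c)
        Y.slice(c).row(0) = arma::mean(xin.slice(c), 0);
      cc.idims = {(arma::uword)T};
      outs[i + 1] = std::move(Y);
    } else if (p.op == "dense") {
      // input (1, N, C) -> treat as (N x C)
      const int C = xin.n_slices, Nn = xin.n_cols;
      fmat Xm(Nn, C);
      for (int c = 0; c < C; ++c) Xm.col(c) = xin.slice(c).row(0).t();
      cc.M = Xm;
      fmat W = getW(p.name);
      fvec b = getb(p.name);
      fmat Ym = Xm * W;
      Ym.each_row() += b.t();
      fcube Y(1, Nn, W.n_cols);
      for (arma::uword c = 0; c < W.n_cols; ++c) Y.slice(c).row(0) = Ym.col(c).t();
      outs[i + 1] = std::move(Y);
    } else if (p.op == "fuse_stack") {
      fcube& A = outs[p.in1];
      fcube& B = outs[p.in2];
      fcube Ap = maxpool_f(A, cc.mask);
      const int Tb = B.n_rows, Nn = B.n_cols, Ca = Ap.n_slices,
                Cb = B.n_slices;
      fcube img(Ca + Cb, Tb, Nn);
      for (int n = 0; n < Nn; ++n)
        for (int t = 0; t < Tb; ++t) {
          for (int c = 0; c < Ca; ++c) img(c, t, n) = Ap(t, n, c);
          for (int c = 0; c < Cb; ++c) img(Ca + c, t, n) = B(t, n, c);
        }
      cc.idims = {(arma::uword)Ca, (arma::uword)Cb, (arma::uword)Tb,
                  (arma::uword)Nn};
      outs[i + 1] = std::move(img);
    } else if (p.op == "head") {
      fcube& zin = outs[p.in1];
      const int F = zin.n_slices;
      Z.set_size(N, F);
      for (int c = 0; c < F; ++c) Z.col(c) = zin.slice(c).row(0).t();
      outs[i + 1] = zin;
    } else {
      stop("unknown op: " + p.op);
    }
  }

  // ---- head loss (double precision) ----
  arma::vec p_true(N);
  arma::mat dZ;  // N x F
  double loss = 0;
  int correct = 0;
  const double eps = 1e-12;
  if (head_act == "sigmoid") {
    dZ.set_size(N, 1);
    for (int n = 0; n < N; ++n) {
      const double z = Z(n, 0);
      const double pp = 1.0 / (1.0 + std::exp(-z));
      p_true[n] = pp;
      loss += -w[n] * (y[n] * std::log(pp + eps) +
                       (1 - y[n]) * std::log(1 - pp + eps));
      dZ(n, 0) = w[n] * (pp - y[n]) / N;
    }
  } else {
    dZ.set_size(N, 2);
    for (int n = 0; n < N; ++n) {
      const double m = std::max(Z(n, 0), Z(n, 1));
      const double e0 = std::exp(Z(n, 0) - m), e1 = std::exp(Z(n, 1) - m);
      const double p1 = e1 / (e0 + e1);
      p_true[n] = p1;
      const double picked = y[n] == 1 ? p1 : 1 - p1;
      loss += -w[n] * std::log(picked + eps);
      dZ(n, 0) = ((1 - p1) - (1 - y[n])) * w[n] / N;
      dZ(n, 1) = (p1 - y[n]) * w[n] / N;
    }
  }
  loss /= N;
  for (int n = 0; n < N; ++n) correct += (p_true[n] >= 0.5) == (y[n] == 1);

  List grads;
  if (backward) {
    std::vector<fcube> douts(nn + 1);
    std::vector<bool> have(nn + 1, false);
    auto add_grad = [&](int slot, fcube&& g) {
      if (!have[slot]) {
        douts[slot] = std::move(g);
        have[slot] = true;
      } else {
        douts[slot] += g;
      }
    };
    // seed gradient at the head input
    {
      fcube g(1, N, dZ.n_cols);
      for (arma::uword c = 0; c < dZ.n_cols; ++c)
        g.slice(c).row(0) = arma::conv_to<fvec>::from(dZ.col(c)).t();
      douts[nn] = std::move(g);
      have[nn] = true;
    }
    for (int i = nn - 1; i >= 0; --i) {
      if (!have[i + 1]) continue;
      NodeP& p = np[i];
      Cache& cc = caches[i];
      fcube& dY = douts[i + 1];
      if (p.op == "head") {
        add_grad(p.in1, std::move(dY));
      } else if (p.op == "conv1d") {
        fmat dW;
        fvec db;
        fcube dX = conv1d_b(dY, cc.M, as_fmat(params[p.name + "_W"]),
                            p.kernel, dW, db);
        grads[p.name + "_W"] = wrap(arma::conv_to<arma::mat>::from(dW));
        grads[p.name + "_b"] = wrap(arma::conv_to<arma::vec>::from(db));
        add_grad(p.in1, std::move(dX));
      } else if (p.op == "conv2d") {
        const int R = cc.idims[0], Wd = cc.idims[1], Nn = cc.idims[2],
                  Ho = cc.idims[3];
        fcube dYc(dY.memptr(), Wd, Ho * Nn, dY.n_slices);
        fmat dW;
        fvec db;
        fcube dXc = conv1d_b(dYc, cc.M, as_fmat(params[p.name + "_W"]),
                             p.kw, dW, db);
        grads[p.name + "_W"] = wrap(arma::conv_to<arma::mat>::from(dW));
        grads[p.name + "_b"] = wrap(arma::conv_to<arma::vec>::from(db));
        add_grad(p.in1, img_from_chan(dXc, p.kh, Ho, Nn));
      } else if (p.op == "relu") {
        fcube dX = dY;
        for (arma::uword q = 0; q < dX.n_elem; ++q)
          if (cc.act[q] <= 0) dX[q] = 0;
        add_grad(p.in1, std::move(dX));
      } else if (p.op == "maxpool1d") {
        add_grad(p.in1, maxpool_b(dY, cc.mask));
      } else if (p.op == "dropout") {
        if (cc.mask.n_elem > 0) add_grad(p.in1, dY % cc.mask);
        else add_grad(p.in1, std::move(dY));
      } else if (p.op == "batchnorm") {
        const int C = dY.n_slices;
        fmat dYm(const_cast<float*>(dY.memptr()), dY.n_elem / C, C);
        fvec dgamma, dbeta;
        fmat dXm = bn_b(dYm, cc.xhat, cc.inv,
                        as_fvec(params[p.name + "_gamma"]), train, dgamma,
                        dbeta);
        grads[p.name + "_gamma"] = wrap(arma::conv_to<arma::vec>::from(dgamma));
        grads[p.name + "_beta"] = wrap(arma::conv_to<arma::vec>::from(dbeta));
        add_grad(p.in1, fcube(dXm.memptr(), dY.n_rows, dY.n_cols, C));
      } else if (p.op == "gap") {
        const int T = cc.idims[0], C = dY.n_slices, Nn = dY.n_cols;
        fcube dX(T, Nn, C);
        for (int c = 0; c < C; ++c)
          for (int n = 0; n < Nn; ++n)
            dX.slice(c).col(n).fill(dY(0, n, c) / T);
        add_grad(p.in1, std::move(dX));
      } else if (p.op == "dense") {
        const int F = dY.n_slices, Nn = dY.n_cols;
        fmat dYm(Nn, F);
        for (int c = 0; c < F; ++c) dYm.col(c) = dY.slice(c).row(0).t();
        fmat W = as_fmat(params[p.name + "_W"]);
        fmat dW = cc.M.t() * dYm;
        fvec db = arma::sum(dYm, 0).t();
        fmat dXm = dYm * W.t();
        grads[p.name + "_W"] = wrap(arma::conv_to<arma::mat>::from(dW));
        grads[p.name + "_b"] = wrap(arma::conv_to<arma::vec>::from(db));
        fcube dX(1, Nn, W.n_rows);
        for (arma::uword c = 0; c < W.n_rows; ++c)
          dX.slice(c).row(0) = dXm.col(c).t();
        add_grad(p.in1, std::move(dX));
      } else if (p.op == "fuse_stack") {
        const int Ca = cc.idims[0], Cb = cc.idims[1], Tb = cc.idims[2],
                  Nn = cc.idims[3];
        fcube dAp(Tb, Nn, Ca), dB(Tb, Nn, Cb);
        for (int n = 0; n < Nn; ++n)
          for (int t = 0; t < Tb; ++t) {
            for (int c = 0; c < Ca; ++c) dAp(t, n, c) = dY(c, t, n);
            for (int c = 0; c < Cb; ++c) dB(t, n, c) = dY(Ca + c, t, n);
          }
        add_grad(p.in1, maxpool_b(dAp, cc.mask));
        add_grad(p.in2, std::move(dB));
      }
    }
  }

  return List::create(_["loss"] = loss, _["p"] = p_true,
                      _["correct"] = correct, _["grads"] = grads,
                      _["state"] = new_state);
}
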