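// Core compute engine for the patient-conditioned 1-D residual CNN.
//
// The whole forward/backward pass runs here in single precision so that
// training the 23-conv-layer network on 22,500-sample epochs is feasible on
// one CPU. R owns the parameters (a nested list of double matrices/vectors);
// each call converts them once, which is negligible next to the conv work.
//
// Layout conventions:
//   activations: arma::fcube (time x channels x batch) — time-major, so the
//     convolution inner loops are contiguous axpy/dot operations; with the
//     small channel counts of this architecture that beats im2col + gemm by
//     a wide margin on one CPU.
//   conv weight: (C_out x C_in*K), column index = tap*C_in + channel
//   batch norm:  per-channel over (time x batch)
//
// Pre-activation residual blocks: BN-ReLU-Conv(stride) / BN-ReLU-[Dropout]-Conv,
// with a kernel-1 projection shortcut (same stride) whenever shape changes.
// The one-hot patient code is tiled along time and concatenated on the
// channel axis between the penultimate and final block.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-4f;

struct BNPar   { fvec g, b; };
struct BNState { fvec m, v; };
struct ConvPar { fmat W; fvec b; int K; };
struct BNCache { fcube xhat; fvec invstd; };

struct BlockPar {
  BNPar bn1, bn2;
  ConvPar c1, c2, proj;
  bool has_proj;
  int stride;
};

struct BlockCache {
  BNCache b1, b2;
  fcube a1;     // post bn1+relu (input of conv1 and projection)
  fcube a2;     // post bn2+relu (pre dropout)
  fcube dmask;  // dropout multiplier (empty when dropout off)
};

// ---------- small helpers ----------

static inline int out_len(int T, int stride) { return (T + stride - 1) / stride; }
static inline int pad_left_of(int T, int K, int stride) {
  return std::max((out_len(T, stride) - 1) * stride + K - T, 0) / 2;
}

static fmat to_f(SEXP x) { return conv_to<fmat>::from(Rcpp::as<mat>(x)); }
static fvec to_fv(SEXP x) { return conv_to<fvec>::from(Rcpp::as<vec>(x)); }

static BNPar parse_bn(const List& l) {
  BNPar p; p.g = to_fv(l["g"]); p.b = to_fv(l["b"]); return p;
}
static BNState parse_bn_state(const List& l) {
  BNState s; s.m = to_fv(l["m"]); s.v = to_fv(l["v"]); return s;
}
static ConvPar parse_conv(const List& l, int Cin) {
  ConvPar c; c.W = to_f(l["W"]); c.b = to_fv(l["b"]);
  c.K = c.W.n_cols / Cin;
  return c;
}

// ---------- convolution (direct, time-major) ----------

static fcube conv_fwd(const fcube& X, const ConvPar& cp, int stride) {
  const int T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const int Cout = cp.W.n_rows, K = cp.K;
  const int Tout = out_len(T, stride);
  const int pad_left = pad_left_of(T, K, stride);
  fcube Y(Tout, Cout, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      float* __restrict y = Y.slice(n).colptr(co);
      std::fill(y, y + Tout, cp.b(co));
      for (int k = 0; k < K; ++k) {
        const int off = k - pad_left;
        if (off > T - 1) continue;
        const int j_lo = off < 0 ? (-off + stride - 1) / stride : 0;
        int j_hi = (T - 1 - off) / stride;
        if (j_hi > Tout - 1) j_hi = Tout - 1;
        if (j_lo > j_hi) continue;
        const int len = j_hi - j_lo + 1;
        for (int c = 0; c < Cin; ++c) {
          const float w = cp.W(co, k * Cin + c);
          const float* __restrict x =
            X.slice(n).colptr(c) + (ptrdiff_t)j_lo * stride + off;
          float* __restrict yj = y + j_lo;
          if (stride == 1)
            for (int i = 0; i < len; ++i) yj[i] += w * x[i];
          else
            for (int i = 0; i < len; ++i) yj[i] += w * x[(ptrdiff_t)i * stride];
        }
      }
    }
  }
  return Y;
}

static fcube conv_bwd(const fcube& X, const ConvPar& cp, int stride,
                      const fcube& dY, fmat& dW, fvec& db) {
  const int T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const int Cout = cp.W.n_rows, K = cp.K;
  const int Tout = dY.n_rows;
  const int pad_left = pad_left_of(T, K, stride);
  dW.zeros(Cout, Cin * K);
  db.zeros(Cout);
  fcube dX(T, Cin, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const float* __restrict dy = dY.slice(n).colptr(co);
      double acc_b = 0.0;
      for (int j = 0; j < Tout; ++j) acc_b += dy[j];
      db(co) += (float)acc_b;
      for (int k = 0; k < K; ++k) {
        const int off = k - pad_left;
        if (off > T - 1) continue;
        const int j_lo = off < 0 ? (-off + stride - 1) / stride : 0;
        int j_hi = (T - 1 - off) / stride;
        if (j_hi > Tout - 1) j_hi = Tout - 1;
        if (j_lo > j_hi) continue;
        const int len = j_hi - j_lo + 1;
        const float* __restrict dyj = dy + j_lo;
        for (int c = 0; c < Cin; ++c) {
          const float* __restrict x =
            X.slice(n).colptr(c) + (ptrdiff_t)j_lo * stride + off;
          float* __restrict dx =
            dX.slice(n).colptr(c) + (ptrdiff_t)j_lo * stride + off;
          const float w = cp.W(co, k * Cin + c);
          float acc;
          if (stride == 1) {
            // 8 partial sums keep the reduction vectorizable
            float p0 = 0, p1 = 0, p2 = 0, p3 = 0,
                  p4 = 0, p5 = 0, p6 = 0, p7 = 0;
            int i = 0;
            for (; i + 8 <= len; i += 8) {
              p0 += dyj[i] * x[i];         p1 += dyj[i + 1] * x[i + 1];
              p2 += dyj[i + 2] * x[i + 2]; p3 += dyj[i + 3] * x[i + 3];
              p4 += dyj[i + 4] * x[i + 4]; p5 += dyj[i + 5] * x[i + 5];
              p6 += dyj[i + 6] * x[i + 6]; p7 += dyj[i + 7] * x[i + 7];
            }
            acc = ((p0 + p1) + (p2 + p3)) + ((p4 + p5) + (p6 + p7));
            for (; i < len; ++i) acc += dyj[i] * x[i];
            for (int i2 = 0; i2 < len; ++i2) dx[i2] += w * dyj[i2];
          } else {
            acc = 0.0f;
            for (int i = 0; i < len; ++i) {
              acc += dyj[i] * x[(ptrdiff_t)i * stride];
              dx[(ptrdiff_t)i * stride] += w * dyj[i];
            }
          }
          dW(co, k * Cin + c) += acc;
        }
      }
    }
  }
  return dX;
}

// ---------- batch norm / relu / dropout ----------

static void bn_train_fwd(fcube& A, const BNPar& p, BNState& st, float momentum,
                         BNCache& cache) {
  const int T = A.n_rows, C = A.n_cols, N = A.n_slices;
  const double m = (double)T * N;
  cache.xhat.set_size(T, C, N);
  cache.invstd.set_size(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const float* a = A.slice(n).colptr(c);
      for (int t = 0; t < T; ++t) { s += a[t]; s2 += (double)a[t] * a[t]; }
    }
    const double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    const float inv = 1.0f / std::sqrt((float)v + BN_EPS);
    cache.invstd(c) = inv;
    const float muf = (float)mu, g = p.g(c), b = p.b(c);
    for (int n = 0; n < N; ++n) {
      float* a = A.slice(n).colptr(c);
      float* xh = cache.xhat.slice(n).colptr(c);
      for (int t = 0; t < T; ++t) {
        xh[t] = (a[t] - muf) * inv;
        a[t] = g * xh[t] + b;
      }
    }
    st.m(c) = (1.0f - momentum) * st.m(c) + momentum * muf;
    st.v(c) = (1.0f - momentum) * st.v(c) + momentum * (float)v;
  }
}

static void bn_eval_fwd(fcube& A, const BNPar& p, const BNState& st) {
  const int T = A.n_rows, C = A.n_cols, N = A.n_slices;
  for (int c = 0; c < C; ++c) {
    const float scale = p.g(c) / std::sqrt(st.v(c) + BN_EPS);
    const float shift = p.b(c) - st.m(c) * scale;
    for (int n = 0; n < N; ++n) {
      float* a = A.slice(n).colptr(c);
      for (int t = 0; t < T; ++t) a[t] = a[t] * scale + shift;
    }
  }
}

static fcube bn_bwd(const fcube& dY, const BNCache& cc, const BNPar& p,
                    fvec& dg, fvec& dbeta) {
  const int T = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  const double m = (double)T * N;
  dg.set_size(C); dbeta.set_size(C);
  fcube dX(T, C, N);
  for (int c = 0; c < C; ++c) {
    double s_dy = 0.0, s_dyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const float* dy = dY.slice(n).colptr(c);
      const float* xh = cc.xhat.slice(n).colptr(c);
      for (int t = 0; t < T; ++t) {
        s_dy += dy[t];
        s_dyx += (double)dy[t] * xh[t];
      }
    }
    dg(c) = (float)s_dyx;
    dbeta(c) = (float)s_dy;
    const float g = p.g(c), inv = cc.invstd(c);
    const float m1 = (float)(g * s_dy / m);     // mean of dxhat
    const float m2 = (float)(g * s_dyx / m);    // mean of dxhat*xhat
    for (int n = 0; n < N; ++n) {
      const float* dy = dY.slice(n).colptr(c);
      const float* xh = cc.xhat.slice(n).colptr(c);
      float* dx = dX.slice(n).colptr(c);
      for (int t = 0; t < T; ++t)
        dx[t] = (g * dy[t] - m1 - xh[t] * m2) * inv;
    }
  }
  return dX;
}

static void relu_inplace(fcube& A) {
  float* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// gradient of relu given its *output* a (mask = a > 0)
static void relu_bwd_inplace(fcube& dA, const fcube& a) {
  float* d = dA.memptr();
  const float* p = a.memptr();
  const uword n = dA.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] <= 0.0f) d[i] = 0.0f;
}

static void dropout_mask(fcube& mask, float rate, std::mt19937& gen) {
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float keep = 1.0f - rate;
  float* p = mask.memptr();
  const uword n = mask.n_elem;
  for (uword i = 0; i < n; ++i)
    p[i] = (unif(gen) < keep) ? 1.0f / keep : 0.0f;
}

// ---------- network assembly ----------

struct Net {
  BNPar bn_in;   BNState bn_in_st;
  ConvPar c0;    int stride0;
  std::vector<BlockPar> blocks;
  std::vector<BNState> bn1_st, bn2_st;
  BNPar bn_fin;  BNState bn_fin_st;
  fvec Ws, Wt;
  float bs, bt;
  int n_patients;
};

static Net parse_net(const List& par, const List& state, const List& arch) {
  Net net;
  const int Cin = 4;
  net.bn_in = parse_bn(par["bn_in"]);
  net.bn_in_st = parse_bn_state(state["bn_in"]);
  net.c0 = parse_conv(par["conv0"], Cin);
  net.stride0 = Rcpp::as<int>(arch["stride0"]);
  net.n_patients = Rcpp::as<int>(arch["n_patients"]);
  const List blocks = par["blocks"];
  const List bstate = state["blocks"];
  const Rcpp::IntegerVector strides = arch["block_strides"];
  const Rcpp::IntegerVector cins = arch["block_cin"];
  for (int i = 0; i < blocks.size(); ++i) {
    const List bl = blocks[i];
    const List bs = bstate[i];
    BlockPar bp;
    bp.bn1 = parse_bn(bl["bn1"]);
    bp.bn2 = parse_bn(bl["bn2"]);
    bp.c1 = parse_conv(bl["conv1"], cins[i]);
    bp.c2 = parse_conv(bl["conv2"], bp.c1.W.n_rows);
    bp.has_proj = bl.containsElementNamed("proj") &&
      !Rf_isNull(bl["proj"]);
    if (bp.has_proj) bp.proj = parse_conv(bl["proj"], cins[i]);
    bp.stride = strides[i];
    net.blocks.push_back(bp);
    net.bn1_st.push_back(parse_bn_state(bs["bn1"]));
    net.bn2_st.push_back(parse_bn_state(bs["bn2"]));
  }
  net.bn_fin = parse_bn(par["bn_fin"]);
  net.bn_fin_st = parse_bn_state(state["bn_fin"]);
  const List head = par["head"];
  net.Ws = to_fv(head["Ws"]);
  net.Wt = to_fv(head["Wt"]);
  net.bs = Rcpp::as<double>(head["bs"]);
  net.bt = Rcpp::as<double>(head["bt"]);
  return net;
}

static fcube concat_onehot(const fcube& H, const fmat& onehot) {
  const int T = H.n_rows, C = H.n_cols, N = H.n_slices, P = onehot.n_rows;
  fcube out(T, C + P, N);
  for (int n = 0; n < N; ++n) {
    out.slice(n).cols(0, C - 1) = H.slice(n);
    for (int p = 0; p < P; ++p)
      out.slice(n).col(C + p).fill(onehot(p, n));
  }
  return out;
}

static List bn_grad_list(const fvec& dg, const fvec& db) {
  return List::create(Named("g") = conv_to<vec>::from(dg),
                      Named("b") = conv_to<vec>::from(db));
}
static List conv_grad_list(const fmat& dW, const fvec& db) {
  return List::create(Named("W") = conv_to<mat>::from(dW),
                      Named("b") = conv_to<vec>::from(db));
}
static List bn_state_list(const BNState& st) {
  return List::create(Named("m") = conv_to<vec>::from(st.m),
                      Named("v") = conv_to<vec>::from(st.v));
}

// Forward (and optionally backward) over one batch.
//
// training = false: returns s_hat, t_hat only (running BN stats, no dropout).
// training = true : requires labels s, t, tmask; returns predictions, loss
//                   components, parameter gradients and updated BN state.
// [[Rcpp::export]]
List cpp_net_run(List par, List state, List arch,
                 arma::cube X_, arma::mat onehot_,
                 bool training,
                 double dropout_rate, int rng_seed,
                 Rcpp::NumericVector s_lab, Rcpp::NumericVector t_lab,
                 Rcpp::NumericVector t_mask, double huber_weight) {
  Net net = parse_net(par, state, arch);
  const int N = X_.n_slices;
  const int nb = net.blocks.size();
  const int concat_before = nb - 1;   // one-hot join before the final block
  const float momentum = Rcpp::as<double>(arch["bn_momentum"]);
  const bool use_dropout = training && dropout_rate > 0.0;
  std::mt19937 gen((unsigned)rng_seed);   // dropout stream, seeded from R

  // transpose each (channels x time) slice into time-major layout
  fcube h(X_.n_cols, X_.n_rows, N);
  for (int n = 0; n < N; ++n)
    h.slice(n) = conv_to<fmat>::from(X_.slice(n).t());
  fmat onehot = conv_to<fmat>::from(onehot_);

  // --- input BN (no relu: raw voltages are signed) + first conv ---
  BNCache bn_in_c;
  fcube y0;
  if (training) bn_train_fwd(h, net.bn_in, net.bn_in_st, momentum, bn_in_c);
  else          bn_eval_fwd(h, net.bn_in, net.bn_in_st);
  if (training) y0 = h;                       // conv0 input cache
  h = conv_fwd(h, net.c0, net.stride0);

  std::vector<BlockCache> bc(training ? nb : 0);

  for (int i = 0; i < nb; ++i) {
    if (i == concat_before)
      h = concat_onehot(h, onehot);
    BlockPar& bp = net.blocks[i];
    fcube a1 = h;                              // BN operates on a copy
    if (training) bn_train_fwd(a1, bp.bn1, net.bn1_st[i], momentum, bc[i].b1);
    else          bn_eval_fwd(a1, bp.bn1, net.bn1_st[i]);
    relu_inplace(a1);

    fcube sc;
    if (bp.has_proj) sc = conv_fwd(a1, bp.proj, bp.stride);
    else             sc = h;

    fcube u = conv_fwd(a1, bp.c1, bp.stride);
    if (training) bc[i].a1 = std::move(a1);

    if (training) bn_train_fwd(u, bp.bn2, net.bn2_st[i], momentum, bc[i].b2);
    else          bn_eval_fwd(u, bp.bn2, net.bn2_st[i]);
    relu_inplace(u);
    if (training) bc[i].a2 = u;
    if (use_dropout) {
      bc[i].dmask.set_size(arma::size(u));
      dropout_mask(bc[i].dmask, (float)dropout_rate, gen);
      u %= bc[i].dmask;
    }
    h = conv_fwd(u, bp.c2, 1);
    h += sc;
  }

  // --- final BN-ReLU, global average pool, two affine heads ---
  BNCache bn_fin_c;
  if (training) bn_train_fwd(h, net.bn_fin, net.bn_fin_st, momentum, bn_fin_c);
  else          bn_eval_fwd(h, net.bn_fin, net.bn_fin_st);
  relu_inplace(h);
  const int Tf = h.n_rows, Cf = h.n_cols;
  fmat G(Cf, N);
  for (int n = 0; n < N; ++n)
    G.col(n) = mean(h.slice(n), 0).t();

  fvec z_s = G.t() * net.Ws + net.bs;
  fvec z_t = G.t() * net.Wt + net.bt;
  fvec s_hat = 1.0f / (1.0f + exp(-z_s));
  s_hat.clamp(1e-7f, 1.0f - 1e-7f);   // keep the probability inside (0,1)

  Rcpp::NumericVector s_hat_r(N), t_hat_r(N);
  for (int n = 0; n < N; ++n) { s_hat_r[n] = s_hat(n); t_hat_r[n] = z_t(n); }

  if (!training) {
    return List::create(Named("s_hat") = s_hat_r, Named("t_hat") = t_hat_r);
  }

  // --- loss and output gradients ---
  const float eps = 1e-7f;
  double ce_sum = 0.0, hub_sum = 0.0;
  fvec dz_s(N), dz_t(N);
  for (int n = 0; n < N; ++n) {
    const double s = s_lab[n];
    double p = s_hat(n);
    p = std::min(std::max(p, (double)eps), 1.0 - (double)eps);
    ce_sum += -s * std::log(p) - (1.0 - s) * std::log(1.0 - p);
    dz_s(n) = (float)((p - s) / N);
    double hub = 0.0, dh_ = 0.0;
    if (t_mask[n] > 0.5) {
      const double d = (double)z_t(n) - t_lab[n];
      if (std::fabs(d) <= 1.0) { hub = 0.5 * d * d; dh_ = d; }
      else { hub = std::fabs(d) - 0.5; dh_ = (d > 0) ? 1.0 : -1.0; }
    }
    hub_sum += hub;
    dz_t(n) = (float)(huber_weight * dh_ / N);
  }
  const double loss_ce = ce_sum / N;
  const double loss_hub = hub_sum / N;
  const double loss_total = loss_ce + huber_weight * loss_hub;

  // --- backward: heads and GAP ---
  fvec dWs = G * dz_s;
  fvec dWt = G * dz_t;
  const double dbs = accu(dz_s), dbt = accu(dz_t);
  fmat dG = net.Ws * dz_s.t() + net.Wt * dz_t.t();   // Cf x N

  fcube dh(Tf, Cf, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cf; ++c)
      dh.slice(n).col(c).fill(dG(c, n) / (float)Tf);
  relu_bwd_inplace(dh, h);
  fvec dg_fin, db_fin;
  dh = bn_bwd(dh, bn_fin_c, net.bn_fin, dg_fin, db_fin);

  // --- backward through blocks ---
  List block_grads(nb);
  for (int i = nb - 1; i >= 0; --i) {
    BlockPar& bp = net.blocks[i];
    fmat dW2, dW1, dWp;
    fvec db2, db1, dbp;

    fcube d_in2 = bc[i].a2;       // conv2 input = a2 (% dmask)
    if (use_dropout) d_in2 %= bc[i].dmask;
    fcube da2 = conv_bwd(d_in2, bp.c2, 1, dh, dW2, db2);
    d_in2.reset();
    if (use_dropout) da2 %= bc[i].dmask;
    relu_bwd_inplace(da2, bc[i].a2);
    bc[i].a2.reset();
    bc[i].dmask.reset();
    fvec dg2, dbeta2;
    fcube du = bn_bwd(da2, bc[i].b2, bp.bn2, dg2, dbeta2);
    da2.reset();
    bc[i].b2.xhat.reset();

    fvec dg1, dbeta1;
    fcube da1 = conv_bwd(bc[i].a1, bp.c1, bp.stride, du, dW1, db1);
    du.reset();

    fcube dh_prev;
    if (bp.has_proj) {
      fcube da1p = conv_bwd(bc[i].a1, bp.proj, bp.stride, dh, dWp, dbp);
      da1 += da1p;
    } else {
      dh_prev = dh;               // identity shortcut
    }
    relu_bwd_inplace(da1, bc[i].a1);
    bc[i].a1.reset();
    fcube dx = bn_bwd(da1, bc[i].b1, bp.bn1, dg1, dbeta1);
    da1.reset();
    bc[i].b1.xhat.reset();
    if (bp.has_proj) dh = std::move(dx);
    else { dh = std::move(dh_prev); dh += dx; }

    List bg = List::create(
      Named("bn1") = bn_grad_list(dg1, dbeta1),
      Named("conv1") = conv_grad_list(dW1, db1),
      Named("bn2") = bn_grad_list(dg2, dbeta2),
      Named("conv2") = conv_grad_list(dW2, db2));
    if (bp.has_proj) bg["proj"] = conv_grad_list(dWp, dbp);
    block_grads[i] = bg;

    if (i == concat_before) {
      // strip the one-hot columns from the gradient
      const int C = dh.n_cols - net.n_patients;
      fcube trimmed(dh.n_rows, C, dh.n_slices);
      for (uword n = 0; n < dh.n_slices; ++n)
        trimmed.slice(n) = dh.slice(n).cols(0, C - 1);
      dh = std::move(trimmed);
    }
  }

  fmat dW0; fvec db0;
  fcube dy0 = conv_bwd(y0, net.c0, net.stride0, dh, dW0, db0);
  fvec dg_in, db_in;
  bn_bwd(dy0, bn_in_c, net.bn_in, dg_in, db_in);

  // --- assemble return ---
  List bstate_out(nb);
  for (int i = 0; i < nb; ++i)
    bstate_out[i] = List::create(Named("bn1") = bn_state_list(net.bn1_st[i]),
                                 Named("bn2") = bn_state_list(net.bn2_st[i]));
  List grads = List::create(
    Named("bn_in") = bn_grad_list(dg_in, db_in),
    Named("conv0") = conv_grad_list(dW0, db0),
    Named("blocks") = block_grads,
    Named("bn_fin") = bn_grad_list(dg_fin, db_fin),
    Named("head") = List::create(
      Named("Ws") = conv_to<vec>::from(dWs), Named("bs") = dbs,
      Named("Wt") = conv_to<vec>::from(dWt), Named("bt") = dbt));
  List state_out = List::create(
    Named("bn_in") = bn_state_list(net.bn_in_st),
    Named("blocks") = bstate_out,
    Named("bn_fin") = bn_state_list(net.bn_fin_st));
  return List::create(
    Named("s_hat") = s_hat_r, Named("t_hat") = t_hat_r,
    Named("loss_total") = loss_total, Named("loss_ce") = loss_ce,
    Named("loss_huber") = loss_hub,
    Named("grads") = grads, Named("state") = state_out);
}
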