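// Generative adversarial imputation core: per-phylum-cluster 1D-CNN feature
// extraction, bidirectional tanh-RNN generator with temporal-decay
// combination factors, LSTM discriminator with real/fake and timepoint
// heads, hand-derived backpropagation and Adam. All subjects are batched
// into matrix operations (rows = subject, or subject x timepoint for the
// convolutions) so one epoch is a few dozen small GEMMs.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG_CLAMP = 1e-7;

// ---------------------------------------------------------------- layouts

struct GenConfig {
  int kernel, f1, f2, hidden, pool;
  double slope, dropout;
  bool use_cnn;
};

struct GenLayout {
  int k, n, h, d, S, B; // B = S * k rows in the convolution batch
  GenConfig cfg;
  std::vector<int> psize, q1, q2, feat, foff;
  std::vector<bool> cnn;
  std::vector<uvec> idx; // 0-based taxon indices per cluster
  std::vector<int> oW1, ob1, oW2, ob2;
  int oWxf, oWhf, obhf, oWof, obof;
  int oWxb, oWhb, obhb, oWob, obob;
  int olam, total;
};

static int ceil_div(int a, int b) { return (a + b - 1) / b; }

static GenLayout make_gen_layout(const Rcpp::List& clusters, int k, int n,
                                 int S, const GenConfig& cfg) {
  GenLayout L;
  L.k = k; L.n = n; L.h = cfg.hidden; L.S = S; L.B = S * k; L.cfg = cfg;
  int off = 0, d = 0;
  for (int c = 0; c < clusters.size(); ++c) {
    ivec id = Rcpp::as<ivec>(clusters[c]); // 1-based from R
    uvec u(id.n_elem);
    for (uword j = 0; j < id.n_elem; ++j) u[j] = (uword)(id[j] - 1);
    L.idx.push_back(u);
    int p = (int)u.n_elem;
    bool conv = cfg.use_cnn && p >= cfg.kernel;
    L.psize.push_back(p); L.cnn.push_back(conv);
    int q1 = conv ? ceil_div(p, cfg.pool) : 0;
    int q2 = conv ? ceil_div(q1, cfg.pool) : 0;
    int ft = conv ? cfg.f2 * q2 : p;
    L.q1.push_back(q1); L.q2.push_back(q2); L.feat.push_back(ft);
    L.foff.push_back(d);
    d += ft;
    if (conv) {
      L.oW1.push_back(off); off += cfg.kernel * cfg.f1;
      L.ob1.push_back(off); off += cfg.f1;
      L.oW2.push_back(off); off += cfg.kernel * cfg.f1 * cfg.f2;
      L.ob2.push_back(off); off += cfg.f2;
    } else {
      L.oW1.push_back(-1); L.ob1.push_back(-1);
      L.oW2.push_back(-1); L.ob2.push_back(-1);
    }
  }
  L.d = d;
  int h = L.h;
  L.oWxf = off; off += d * h;
  L.oWhf = off; off += h * h;
  L.obhf = off; off += h;
  L.oWof = off; off += h * n;
  L.obof = off; off += n;
  L.oWxb = off; off += d * h;
  L.oWhb = off; off += h * h;
  L.obhb = off; off += h;
  L.oWob = off; off += h * n;
  L.obob = off; off += n;
  L.olam = off; off += 4; // wlf, blf, wlb, blb
  L.total = off;
  return L;
}

struct DiscLayout {
  int k, n, u;
  int oWg, oUg, obg, owr, obr, oWt, obt, total;
};

static DiscLayout make_disc_layout(int k, int n, int u) {
  DiscLayout L; L.k = k; L.n = n; L.u = u;
  int off = 0;
  L.oWg = off; off += n * 4 * u;
  L.oUg = off; off += u * 4 * u;
  L.obg = off; off += 4 * u;
  L.owr = off; off += u;
  L.obr = off; off += 1;
  L.oWt = off; off += u * k;
  L.obt = off; off += k;
  L.total = off;
  return L;
}

static mat view(vec& th, int off, int r, int c) {
  return mat(th.memptr() + off, r, c, false, true);
}
static vec vview(vec& th, int off, int len) {
  return vec(th.memptr() + off, len, false, true);
}

static GenConfig gen_config(const Rcpp::List& cfg) {
  GenConfig g;
  g.kernel  = Rcpp::as<int>(cfg["kernel_size"]);
  g.f1      = Rcpp::as<Rcpp::IntegerVector>(cfg["conv_filters"])[0];
  g.f2      = Rcpp::as<Rcpp::IntegerVector>(cfg["conv_filters"])[1];
  g.hidden  = Rcpp::as<int>(cfg["rnn_hidden"]);
  g.pool    = Rcpp::as<int>(cfg["pool_size"]);
  g.slope   = Rcpp::as<double>(cfg["leaky_relu_slope"]);
  g.dropout = Rcpp::as<double>(cfg["dropout_rate"]);
  g.use_cnn = Rcpp::as<bool>(cfg["use_cnn"]);
  return g;
}

// ------------------------------------------------------------------- init

static void glorot(mat M, std::mt19937_64& rng, int fan_in, int fan_out) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> U(-lim, lim);
  for (uword i = 0; i < M.n_elem; ++i) M[i] = U(rng);
}

// out_bias: initial value of each direction's output bias; the pooled
// per-taxon mean clr halved makes the untrained generator a cohort-mean
// imputer (the two directions sum under the lambda = 1 start)
static vec init_gen(const GenLayout& L, std::mt19937_64& rng,
                    const vec& out_bias) {
  vec th(L.total, fill::zeros);
  const GenConfig& c = L.cfg;
  for (size_t ci = 0; ci < L.idx.size(); ++ci) {
    if (!L.cnn[ci]) continue;
    glorot(view(th, L.oW1[ci], c.kernel, c.f1), rng, c.kernel,
           c.kernel * c.f1);
    glorot(view(th, L.oW2[ci], c.kernel * c.f1, c.f2), rng,
           c.kernel * c.f1, c.kernel * c.f2);
  }
  // input weights start well below the Glorot limit: clr-scale features
  // span roughly +/- 8 (presence/absence contrasts), and a unit-variance
  // init saturates the tanh cells at the first step
  glorot(view(th, L.oWxf, L.d, L.h), rng, 36 * L.d, L.h);
  glorot(view(th, L.oWhf, L.h, L.h), rng, L.h, L.h);
  glorot(view(th, L.oWof, L.h, L.n), rng, L.h, L.n);
  glorot(view(th, L.oWxb, L.d, L.h), rng, 36 * L.d, L.h);
  glorot(view(th, L.oWhb, L.h, L.h), rng, L.h, L.h);
  glorot(view(th, L.oWob, L.h, L.n), rng, L.h, L.n);
  if (out_bias.n_elem == (uword)L.n) {
    vview(th, L.obof, L.n) = out_bias;
    vview(th, L.obob, L.n) = out_bias;
  }
  // decay biases start at ln 2 so both combination factors begin at 1/2:
  // the untrained generator averages the forward and backward carries
  th[L.olam + 1] = std::log(2.0);
  th[L.olam + 3] = std::log(2.0);
  return th;
}

static vec init_disc(const DiscLayout& L, std::mt19937_64& rng) {
  vec th(L.total, fill::zeros);
  glorot(view(th, L.oWg, L.n, 4 * L.u), rng, L.n, 4 * L.u);
  glorot(view(th, L.oUg, L.u, 4 * L.u), rng, L.u, 4 * L.u);
  glorot(view(th, L.oWt, L.u, L.k), rng, L.u, L.k);
  vview(th, L.obg, 4 * L.u).subvec(L.u, 2 * L.u - 1).fill(1.0); // forget bias
  glorot(view(th, L.owr, L.u, 1), rng, L.u, 1);
  return th;
}

// ------------------------------------------------------------- workspaces

// batch row index for (subject s, timepoint i): s + S * i; convolution
// positions are stacked below the batch (row b + B * j for position j)
struct ClusterWs {
  mat Z;        // B x p cluster input (fixed given the data)
  mat Zcol;     // (B*p) x kernel im2col of Z (fixed)
  mat A1, L1;   // (B*p) x f1 pre/post activation
  mat P1, M1;   // (B*q1) x f1 pooled values and winner offsets
  mat P1col;    // (B*q1) x (kernel*f1) im2col of P1
  mat A2, L2;   // (B*q1) x f2
  mat P2, M2;   // (B*q2) x f2
  mat dA1, dP1, dP1col, dA2; // backward scratch
};

// Missing timepoints feed the nearest observed sample of the direction
// (last-observation-carried inputs, as in the GRU-D family) rather than
// zero vectors: on the clr scale zero means "average abundance", so zero
// inputs are ambiguous, and the carries are fixed given data + mask so the
// im2col workspaces stay precomputable. Each direction has its own filled
// input and feature pipeline; the CNN weights are shared.
struct GenWs {
  std::vector<ClusterWs> cwf, cwb; // per-direction cluster pipelines
  cube Cf, Cb;                     // (S, n, k) carried inputs per direction
  mat Ff, Fb;                      // B x d features per direction
  mat dropf, dropb;                // dropout multipliers
  cube Hf, Hb;                     // (S, h, k)
  cube XF, XB, XT, XBAR;           // (S, n, k)
  mat lamf, lamb, Uf, Ub;          // S x k
};

// X arrives as cube (k, n, S); internally we use (S, n, k) slices
static cube to_snk(const cube& X) {
  int k = X.n_rows, n = X.n_cols, S = X.n_slices;
  cube Y(S, n, k);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < n; ++j) Y(s, j, i) = X(i, j, s);
  return Y;
}
static cube to_kns(const cube& Y) {
  int S = Y.n_rows, n = Y.n_cols, k = Y.n_slices;
  cube X(k, n, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < n; ++j) X(i, j, s) = Y(s, j, i);
  return X;
}

static void init_dir_ws(std::vector<ClusterWs>& cws, const GenLayout& L,
                        const cube& Xfill /* (S,n,k) */) {
  int B = L.B, kn = L.cfg.kernel, half = kn / 2;
  cws.resize(L.idx.size());
  for (size_t c = 0; c < L.idx.size(); ++c) {
    ClusterWs& cw = cws[c];
    int p = L.psize[c];
    cw.Z.set_size(B, p);
    for (int i = 0; i < L.k; ++i)
      for (int j = 0; j < p; ++j)
        cw.Z.col(j).subvec(L.S * i, L.S * i + L.S - 1) =
            Xfill.slice(i).col(L.idx[c][j]);
    if (L.cnn[c]) {
      int q1 = L.q1[c], q2 = L.q2[c];
      cw.Zcol.zeros(B * p, kn);
      for (int j = 0; j < p; ++j)
        for (int t = 0; t < kn; ++t) {
          int src = j + t - half;
          if (src >= 0 && src < p)
            cw.Zcol.col(t).subvec(B * j, B * j + B - 1) = cw.Z.col(src);
        }
      cw.A1.set_size(B * p, L.cfg.f1); cw.L1.set_size(B * p, L.cfg.f1);
      cw.P1.set_size(B * q1, L.cfg.f1); cw.M1.set_size(B * q1, L.cfg.f1);
      cw.P1col.zeros(B * q1, kn * L.cfg.f1); // borders stay zero
      cw.A2.set_size(B * q1, L.cfg.f2); cw.L2.set_size(B * q1, L.cfg.f2);
      cw.P2.set_size(B * q2, L.cfg.f2); cw.M2.set_size(B * q2, L.cfg.f2);
      cw.dA1.set_size(B * p, L.cfg.f1);
      cw.dP1.set_size(B * q1, L.cfg.f1);
      cw.dP1col.set_size(B * q1, kn * L.cfg.f1);
      cw.dA2.set_size(B * q1, L.cfg.f2);
    }
  }
}

static void build_cluster_inputs(GenWs& W, const GenLayout& L,
                                 const cube& Xs /* (S,n,k) */,
                                 const mat& E) {
  int S = L.S, k = L.k;
  // per-direction observed-value carries; a subject's leading (forward) or
  // trailing (backward) gap takes its nearest observed sample overall
  cube Xf = Xs, Xb = Xs;
  for (int s = 0; s < S; ++s) {
    int first = -1, last = -1;
    for (int i = 0; i < k; ++i) if (E(s, i) == 1) { if (first < 0) first = i; last = i; }
    if (first < 0) continue; // fully missing subject: keep zeros
    int src = first;
    for (int i = 0; i < k; ++i) {
      if (E(s, i) == 1) src = i;
      else Xf.slice(i).row(s) = Xs.slice(src).row(s);
    }
    src = last;
    for (int i = k - 1; i >= 0; --i) {
      if (E(s, i) == 1) src = i;
      else Xb.slice(i).row(s) = Xs.slice(src).row(s);
    }
  }
  init_dir_ws(W.cwf, L, Xf);
  init_dir_ws(W.cwb, L, Xb);
  W.Cf = Xf; W.Cb = Xb;
  W.Ff.set_size(L.B, L.d); W.Fb.set_size(L.B, L.d);
  W.dropf.ones(L.B, L.d); W.dropb.ones(L.B, L.d);
  W.Hf.set_size(S, L.h, k); W.Hb.set_size(S, L.h, k);
  W.XF.set_size(S, L.n, k); W.XB.set_size(S, L.n, k);
  W.XT.set_size(S, L.n, k); W.XBAR.set_size(S, L.n, k);
  W.lamf.set_size(S, k); W.lamb.set_size(S, k);
}

static void leaky_fwd(mat& out, const mat& a, double slope) {
  out = a;
  for (uword i = 0; i < out.n_elem; ++i)
    if (out[i] < 0) out[i] *= slope;
}

// max-pool over position blocks (ceil semantics); rows are b + B*j
static void pool_fwd(mat& P, mat& M, const mat& Lr, int B, int q,
                     int src_len, int pool) {
  for (int j = 0; j < q; ++j) {
    int a = j * pool;
    P.rows(B * j, B * j + B - 1) = Lr.rows(B * a, B * a + B - 1);
    M.rows(B * j, B * j + B - 1).zeros();
    for (int r = 1; r < pool && a + r < src_len; ++r) {
      for (uword f = 0; f < Lr.n_cols; ++f)
        for (int b = 0; b < B; ++b) {
          double cand = Lr(B * (a + r) + b, f);
          if (cand > P(B * j + b, f)) {
            P(B * j + b, f) = cand;
            M(B * j + b, f) = (double)r;
          }
        }
    }
  }
}

static void cnn_forward(vec& th, const GenLayout& L,
                        std::vector<ClusterWs>& cws, mat& F, mat& drop,
                        bool training, std::mt19937_64& rng) {
  const GenConfig& cf = L.cfg;
  int B = L.B, half = cf.kernel / 2;
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  for (size_t c = 0; c < L.idx.size(); ++c) {
    ClusterWs& cw = cws[c];
    int p = L.psize[c];
    if (!L.cnn[c]) {
      F.cols(L.foff[c], L.foff[c] + p - 1) = cw.Z;
      continue;
    }
    int q1 = L.q1[c], q2 = L.q2[c];
    mat W1 = view(th, L.oW1[c], cf.kernel, cf.f1);
    vec b1 = vview(th, L.ob1[c], cf.f1);
    mat W2 = view(th, L.oW2[c], cf.kernel * cf.f1, cf.f2);
    vec b2 = vview(th, L.ob2[c], cf.f2);
    cw.A1 = cw.Zcol * W1;
    cw.A1.each_row() += b1.t();
    leaky_fwd(cw.L1, cw.A1, cf.slope);
    pool_fwd(cw.P1, cw.M1, cw.L1, B, q1, p, cf.pool);
    for (int j = 0; j < q1; ++j)
      for (int t = 0; t < cf.kernel; ++t) {
        int src = j + t - half;
        if (src >= 0 && src < q1)
          cw.P1col.submat(B * j, t * cf.f1, B * j + B - 1,
                          (t + 1) * cf.f1 - 1) =
              cw.P1.rows(B * src, B * src + B - 1);
      }
    cw.A2 = cw.P1col * W2;
    cw.A2.each_row() += b2.t();
    leaky_fwd(cw.L2, cw.A2, cf.slope);
    pool_fwd(cw.P2, cw.M2, cw.L2, B, q2, q1, cf.pool);
    for (int j = 0; j < q2; ++j)
      F.cols(L.foff[c] + j * cf.f2, L.foff[c] + (j + 1) * cf.f2 - 1) =
          cw.P2.rows(B * j, B * j + B - 1);
    // inverted dropout on the flattened CNN features (training only)
    int ft = L.feat[c];
    if (training && cf.dropout > 0) {
      for (int j = 0; j < ft; ++j) {
        double* dcol = drop.colptr(L.foff[c] + j);
        for (int b = 0; b < B; ++b)
          dcol[b] = (U01(rng) < cf.dropout) ? 0.0 : 1.0 / (1.0 - cf.dropout);
      }
      F.cols(L.foff[c], L.foff[c] + ft - 1) %=
          drop.cols(L.foff[c], L.foff[c] + ft - 1);
    } else {
      drop.cols(L.foff[c], L.foff[c] + ft - 1).ones();
    }
  }
}

static void gen_forward(vec& th, const GenLayout& L, GenWs& W,
                        const cube& Xs, const mat& E, const mat& Df,
                        const mat& Db, bool training,
                        std::mt19937_64& rng) {
  int S = L.S, k = L.k;
  cnn_forward(th, L, W.cwf, W.Ff, W.dropf, training, rng);
  cnn_forward(th, L, W.cwb, W.Fb, W.dropb, training, rng);

  int h = L.h, n = L.n;
  mat Wxf = view(th, L.oWxf, L.d, h), Whf = view(th, L.oWhf, h, h);
  vec bhf = vview(th, L.obhf, h);
  mat Wof = view(th, L.oWof, h, n); vec bof = vview(th, L.obof, n);
  mat Wxb = view(th, L.oWxb, L.d, h), Whb = view(th, L.oWhb, h, h);
  vec bhb = vview(th, L.obhb, h);
  mat Wob = view(th, L.oWob, h, n); vec bob = vview(th, L.obob, n);
  vec lam = vview(th, L.olam, 4);

  // residual one-step-ahead outputs: each direction predicts its carried
  // nearest observation plus a correction read from the hidden state of
  // the PREVIOUS (forward) / NEXT (backward) step, so reconstruction on
  // observed samples trains temporal prediction rather than input copying
  // and the untrained generator already interpolates between neighbours
  mat Hprev(S, h, fill::zeros);
  for (int i = 0; i < k; ++i) {
    mat Fi = W.Ff.rows(S * i, S * i + S - 1);
    W.XF.slice(i) = W.Cf.slice(i) + Hprev * Wof + repmat(bof.t(), S, 1);
    W.Hf.slice(i) = tanh(Fi * Wxf + Hprev * Whf +
                         repmat(bhf.t(), S, 1));
    Hprev = W.Hf.slice(i);
  }
  Hprev.zeros();
  for (int i = k - 1; i >= 0; --i) {
    mat Fi = W.Fb.rows(S * i, S * i + S - 1);
    W.XB.slice(i) = W.Cb.slice(i) + Hprev * Wob + repmat(bob.t(), S, 1);
    W.Hb.slice(i) = tanh(Fi * Wxb + Hprev * Whb +
                         repmat(bhb.t(), S, 1));
    Hprev = W.Hb.slice(i);
  }

  W.Uf = lam[0] * Df + lam[1];
  W.Ub = lam[2] * Db + lam[3];
  W.lamf = exp(-clamp(W.Uf, 0.0, datum::inf));
  W.lamb = exp(-clamp(W.Ub, 0.0, datum::inf));
  for (int i = 0; i < k; ++i) {
    W.XT.slice(i) = W.XF.slice(i).each_col() % W.lamf.col(i) +
                    W.XB.slice(i).each_col() % W.lamb.col(i);
    W.XBAR.slice(i) = Xs.slice(i).each_col() % E.col(i) +
                      W.XT.slice(i).each_col() % (1.0 - E.col(i));
  }
}

static void leaky_bwd_inplace(mat& dA, const mat& A, double slope) {
  for (uword i = 0; i < dA.n_elem; ++i)
    if (A[i] <= 0) dA[i] *= slope;
}

static void cnn_backward(vec& th, const GenLayout& L,
                         const std::vector<ClusterWs>& cws, const mat& drop,
                         const mat& dF, vec& grad);

// dXF/dXB/dXT: gradients on the per-direction and combined outputs
static void gen_backward(vec& th, const GenLayout& L, const GenWs& W,
                         const mat& Df, const mat& Db, cube& dXF, cube& dXB,
                         const cube& dXT, vec& grad) {
  const GenConfig& cf = L.cfg;
  int S = L.S, k = L.k, h = L.h, n = L.n;
  mat Wxf = view(th, L.oWxf, L.d, h), Whf = view(th, L.oWhf, h, h);
  mat Wof = view(th, L.oWof, h, n);
  mat Wxb = view(th, L.oWxb, L.d, h), Whb = view(th, L.oWhb, h, h);
  mat Wob = view(th, L.oWob, h, n);

  mat gWxf = view(grad, L.oWxf, L.d, h), gWhf = view(grad, L.oWhf, h, h);
  vec gbhf = vview(grad, L.obhf, h);
  mat gWof = view(grad, L.oWof, h, n); vec gbof = vview(grad, L.obof, n);
  mat gWxb = view(grad, L.oWxb, L.d, h), gWhb = view(grad, L.oWhb, h, h);
  vec gbhb = vview(grad, L.obhb, h);
  mat gWob = view(grad, L.oWob, h, n); vec gbob = vview(grad, L.obob, n);
  vec glam = vview(grad, L.olam, 4);

  // combination factors
  mat dlamf(S, k), dlamb(S, k);
  for (int i = 0; i < k; ++i) {
    dlamf.col(i) = sum(dXT.slice(i) % W.XF.slice(i), 1);
    dlamb.col(i) = sum(dXT.slice(i) % W.XB.slice(i), 1);
    dXF.slice(i) += dXT.slice(i).each_col() % W.lamf.col(i);
    dXB.slice(i) += dXT.slice(i).each_col() % W.lamb.col(i);
  }
  mat duf = -dlamf % W.lamf; duf.elem(find(W.Uf <= 0)).zeros();
  mat dub = -dlamb % W.lamb; dub.elem(find(W.Ub <= 0)).zeros();
  glam[0] += accu(duf % Df);
  glam[1] += accu(duf);
  glam[2] += accu(dub % Db);
  glam[3] += accu(dub);

  mat dFf(L.B, L.d, fill::zeros), dFb(L.B, L.d, fill::zeros);
  mat dH(S, h, fill::zeros);
  for (int i = k - 1; i >= 0; --i) {
    const mat& Hi = W.Hf.slice(i);
    gbof += sum(dXF.slice(i), 0).t();
    // the output at i+1 consumed the hidden state of i
    if (i + 1 < k) {
      gWof += Hi.t() * dXF.slice(i + 1);
      dH += dXF.slice(i + 1) * Wof.t();
    }
    mat dpre = dH % (1.0 - Hi % Hi);
    mat Hprev = (i > 0) ? W.Hf.slice(i - 1) : mat(S, h, fill::zeros);
    gWxf += W.Ff.rows(S * i, S * i + S - 1).t() * dpre;
    gWhf += Hprev.t() * dpre;
    gbhf += sum(dpre, 0).t();
    dFf.rows(S * i, S * i + S - 1) += dpre * Wxf.t();
    dH = dpre * Whf.t();
  }
  dH.zeros();
  for (int i = 0; i < k; ++i) {
    const mat& Hi = W.Hb.slice(i);
    gbob += sum(dXB.slice(i), 0).t();
    // the output at i-1 consumed the hidden state of i
    if (i > 0) {
      gWob += Hi.t() * dXB.slice(i - 1);
      dH += dXB.slice(i - 1) * Wob.t();
    }
    mat dpre = dH % (1.0 - Hi % Hi);
    mat Hnext = (i < k - 1) ? W.Hb.slice(i + 1) : mat(S, h, fill::zeros);
    gWxb += W.Fb.rows(S * i, S * i + S - 1).t() * dpre;
    gWhb += Hnext.t() * dpre;
    gbhb += sum(dpre, 0).t();
    dFb.rows(S * i, S * i + S - 1) += dpre * Wxb.t();
    dH = dpre * Whb.t();
  }

  cnn_backward(th, L, W.cwf, W.dropf, dFf, grad);
  cnn_backward(th, L, W.cwb, W.dropb, dFb, grad);
}

// shared CNN weights accumulate gradients from both direction pipelines
static void cnn_backward(vec& th, const GenLayout& L,
                         const std::vector<ClusterWs>& cws, const mat& drop,
                         const mat& dF, vec& grad) {
  const GenConfig& cf = L.cfg;
  int B = L.B, half = cf.kernel / 2;
  for (size_t c = 0; c < L.idx.size(); ++c) {
    if (!L.cnn[c]) continue; // raw features: gradient stops at the input
    const ClusterWs& cw = cws[c];
    int p = L.psize[c], q1 = L.q1[c], q2 = L.q2[c];
    mat W2 = view(th, L.oW2[c], cf.kernel * cf.f1, cf.f2);
    mat gW1 = view(grad, L.oW1[c], cf.kernel, cf.f1);
    vec gb1 = vview(grad, L.ob1[c], cf.f1);
    mat gW2 = view(grad, L.oW2[c], cf.kernel * cf.f1, cf.f2);
    vec gb2 = vview(grad, L.ob2[c], cf.f2);

    // dropout + unflatten + unpool 2
    mat& dA2 = const_cast<ClusterWs&>(cw).dA2;
    dA2.zeros();
    for (int j = 0; j < q2; ++j) {
      mat dPj =
          dF.cols(L.foff[c] + j * cf.f2, L.foff[c] + (j + 1) * cf.f2 - 1) %
          drop.cols(L.foff[c] + j * cf.f2,
                    L.foff[c] + (j + 1) * cf.f2 - 1);
      for (int f = 0; f < cf.f2; ++f)
        for (int b = 0; b < B; ++b) {
          int src = j * cf.pool + (int)cw.M2(B * j + b, f);
          dA2(B * src + b, f) += dPj(b, f);
        }
    }
    leaky_bwd_inplace(dA2, cw.A2, cf.slope);
    gb2 += sum(dA2, 0).t();
    gW2 += cw.P1col.t() * dA2;
    mat& dP1col = const_cast<ClusterWs&>(cw).dP1col;
    dP1col = dA2 * W2.t();
    mat& dP1 = const_cast<ClusterWs&>(cw).dP1;
    dP1.zeros();
    for (int j = 0; j < q1; ++j)
      for (int t = 0; t < cf.kernel; ++t) {
        int src = j + t - half;
        if (src < 0 || src >= q1) continue;
        dP1.rows(B * src, B * src + B - 1) +=
            dP1col.submat(B * j, t * cf.f1, B * j + B - 1,
                          (t + 1) * cf.f1 - 1);
      }
    // unpool 1 -> LeakyReLU' -> conv1
    mat& dA1 = const_cast<ClusterWs&>(cw).dA1;
    dA1.zeros();
    for (int j = 0; j < q1; ++j)
      for (int f = 0; f < cf.f1; ++f)
        for (int b = 0; b < B; ++b) {
          int src = j * cf.pool + (int)cw.M1(B * j + b, f);
          dA1(B * src + b, f) += dP1(B * j + b, f);
        }
    leaky_bwd_inplace(dA1, cw.A1, cf.slope);
    gb1 += sum(dA1, 0).t();
    gW1 += cw.Zcol.t() * dA1;
  }
}

// ------------------------------------------------------- discriminator

struct DiscWs {
  cube I, Fg, G, O, C, H; // (S, u, k)
  cube probs;             // (S, k, k): slice i = softmax at timestep i
  vec p, u_pre;           // S
};

static void disc_alloc(DiscWs& W, int S, int u, int k) {
  W.I.set_size(S, u, k); W.Fg.set_size(S, u, k); W.G.set_size(S, u, k);
  W.O.set_size(S, u, k); W.C.set_size(S, u, k); W.H.set_size(S, u, k);
  W.probs.set_size(S, k, k);
  W.p.set_size(S); W.u_pre.set_size(S);
}

// Y: cube (S, n, k)
static void disc_forward(vec& th, const DiscLayout& L, DiscWs& W,
                         const cube& Y) {
  int S = Y.n_rows, u = L.u, k = L.k;
  mat Wg = view(th, L.oWg, L.n, 4 * u), Ug = view(th, L.oUg, u, 4 * u);
  vec bg = vview(th, L.obg, 4 * u);
  vec wr = vview(th, L.owr, u);
  mat Wt = view(th, L.oWt, u, k);
  vec bt = vview(th, L.obt, k);

  mat Hprev(S, u, fill::zeros), Cprev(S, u, fill::zeros);
  for (int i = 0; i < k; ++i) {
    mat A = Y.slice(i) * Wg + Hprev * Ug + repmat(bg.t(), S, 1);
    mat ig = 1.0 / (1.0 + exp(-A.cols(0, u - 1)));
    mat fg = 1.0 / (1.0 + exp(-A.cols(u, 2 * u - 1)));
    mat gg = tanh(A.cols(2 * u, 3 * u - 1));
    mat og = 1.0 / (1.0 + exp(-A.cols(3 * u, 4 * u - 1)));
    mat cc = fg % Cprev + ig % gg;
    mat hh = og % tanh(cc);
    W.I.slice(i) = ig; W.Fg.slice(i) = fg; W.G.slice(i) = gg;
    W.O.slice(i) = og; W.C.slice(i) = cc; W.H.slice(i) = hh;
    mat logit = hh * Wt + repmat(bt.t(), S, 1);
    logit.each_col() -= max(logit, 1);
    mat ex = exp(logit);
    W.probs.slice(i) = ex.each_col() / sum(ex, 1);
    Hprev = hh; Cprev = cc;
  }
  W.u_pre = W.H.slice(k - 1) * wr + th[L.obr];
  W.p = 1.0 / (1.0 + exp(-W.u_pre));
}

// du_p: per-subject dLoss/d(pre-sigmoid logit); dLogits (S,k,k) or empty
static void disc_backward_full(vec& th, const DiscLayout& L, const DiscWs& W,
                               const cube& Y, const vec& du_p,
                               const cube& dLogits, vec& grad, cube* dY) {
  int S = W.H.n_rows, u = L.u, k = L.k;
  mat Wg = view(th, L.oWg, L.n, 4 * u), Ug = view(th, L.oUg, u, 4 * u);
  mat Wt = view(th, L.oWt, u, k);
  mat gWg = view(grad, L.oWg, L.n, 4 * u), gUg = view(grad, L.oUg, u, 4 * u);
  vec gbg = vview(grad, L.obg, 4 * u);
  vec gwr = vview(grad, L.owr, u);
  mat gWt = view(grad, L.oWt, u, k);
  vec gbt = vview(grad, L.obt, k);
  vec wr = vview(th, L.owr, u);

  gwr += W.H.slice(k - 1).t() * du_p;
  grad[L.obr] += accu(du_p);
  if (dY) dY->zeros(S, L.n, k);
  mat dC(S, u, fill::zeros), dHn(S, u, fill::zeros);
  for (int i = k - 1; i >= 0; --i) {
    mat dh = dHn;
    if (i == k - 1) dh += du_p * wr.t();
    if (dLogits.n_elem) {
      gWt += W.H.slice(i).t() * dLogits.slice(i);
      gbt += sum(dLogits.slice(i), 0).t();
      dh += dLogits.slice(i) * Wt.t();
    }
    mat tc = tanh(W.C.slice(i));
    mat do_ = dh % tc;
    dC += dh % W.O.slice(i) % (1.0 - tc % tc);
    mat Cprev = (i > 0) ? W.C.slice(i - 1) : mat(S, u, fill::zeros);
    mat Hprev = (i > 0) ? W.H.slice(i - 1) : mat(S, u, fill::zeros);
    mat dA(S, 4 * u);
    dA.cols(0, u - 1) =
        dC % W.G.slice(i) % W.I.slice(i) % (1.0 - W.I.slice(i));
    dA.cols(u, 2 * u - 1) =
        dC % Cprev % W.Fg.slice(i) % (1.0 - W.Fg.slice(i));
    dA.cols(2 * u, 3 * u - 1) =
        dC % W.I.slice(i) % (1.0 - W.G.slice(i) % W.G.slice(i));
    dA.cols(3 * u, 4 * u - 1) = do_ % W.O.slice(i) % (1.0 - W.O.slice(i));
    gWg += Y.slice(i).t() * dA;
    gUg += Hprev.t() * dA;
    gbg += sum(dA, 0).t();
    if (dY) dY->slice(i) = dA * Wg.t();
    dHn = dA * Ug.t();
    dC %= W.Fg.slice(i);
  }
}

// ----------------------------------------------------------- loss pieces

static vec clamp_p(const vec& p) {
  return clamp(p, LOG_CLAMP, 1.0 - LOG_CLAMP);
}

struct GenLossOut { double lossG, lossR, lossC, total; };

// lossR + lossC (+ lossG via the discriminator) and the generator gradient
static GenLossOut gen_loss_backward(vec& thG, vec& thD, const GenLayout& L,
                                    const DiscLayout& DL, GenWs& W,
                                    DiscWs& DW, const cube& Xs,
                                    const mat& E, const mat& Df,
                                    const mat& Db, bool use_disc,
                                    vec& grad) {
  int S = L.S, k = L.k, n = L.n;
  GenLossOut out{0, 0, 0, 0};
  vec ne = sum(E, 1);
  cube dXF(S, n, k, fill::zeros), dXB(S, n, k, fill::zeros),
       dXT(S, n, k, fill::zeros);
  for (int i = 0; i < k; ++i) {
    mat diffR = W.XT.slice(i) - Xs.slice(i);
    vec wR(S);
    for (int s = 0; s < S; ++s)
      wR[s] = (E(s, i) == 1 && ne[s] > 0) ? 1.0 / (ne[s] * S) : 0.0;
    mat adiff = abs(diffR);
    out.lossR += accu(adiff.each_col() % wR);
    mat sdiff = sign(diffR);
    dXT.slice(i) += sdiff.each_col() % wR;
    mat diffC = W.XF.slice(i) - W.XB.slice(i);
    out.lossC += accu(abs(diffC)) / (double)(k * S);
    dXF.slice(i) += sign(diffC) / (double)(k * S);
    dXB.slice(i) -= sign(diffC) / (double)(k * S);
  }
  if (use_disc) {
    cube Yfake(S, n, k);
    for (int i = 0; i < k; ++i)
      Yfake.slice(i) = W.XBAR.slice(i).each_col() % (1.0 - E.col(i));
    disc_forward(thD, DL, DW, Yfake);
    vec p = clamp_p(DW.p);
    out.lossG = accu(-log(p)) / S;
    vec dummy(DL.total, fill::zeros);
    cube dY;
    disc_backward_full(thD, DL, DW, Yfake, (DW.p - 1.0) / S, cube(), dummy,
                       &dY);
    for (int i = 0; i < k; ++i)
      dXT.slice(i) += dY.slice(i).each_col() % (1.0 - E.col(i));
  }
  gen_backward(thG, L, W, Df, Db, dXF, dXB, dXT, grad);
  out.total = out.lossG + out.lossR + out.lossC;
  return out;
}

struct DiscLossOut { double lossD, lossT, total; };

// lossD on both branches + timepoint cross-entropy on the real branch
static DiscLossOut disc_loss_backward(vec& thD, const DiscLayout& DL,
                                      DiscWs& DWr, DiscWs& DWf,
                                      const cube& Yreal, const cube& Yfake,
                                      vec& grad) {
  int S = Yreal.n_rows, k = DL.k;
  disc_forward(thD, DL, DWr, Yreal);
  disc_forward(thD, DL, DWf, Yfake);
  vec pr = clamp_p(DWr.p), pf = clamp_p(DWf.p);
  DiscLossOut out;
  out.lossD = (accu(-log(pr)) + accu(-log(1.0 - pf))) / S;
  cube dLog = DWr.probs;
  double lt = 0;
  for (int i = 0; i < k; ++i) {
    for (int s = 0; s < S; ++s)
      lt += -std::log(std::max(DWr.probs(s, i, i), LOG_CLAMP));
    dLog.slice(i).col(i) -= 1.0;
  }
  out.lossT = lt / S;
  disc_backward_full(thD, DL, DWr, Yreal, (DWr.p - 1.0) / S, dLog / S, grad,
                     nullptr);
  disc_backward_full(thD, DL, DWf, Yfake, DWf.p / S, cube(), grad, nullptr);
  out.total = out.lossD + out.lossT;
  return out;
}

// ------------------------------------------------------------ R bindings

// [[Rcpp::export]]
Rcpp::List cpp_gen_init(Rcpp::List clusters, int k, int n, Rcpp::List cfg,
                        int seed, arma::vec out_bias) {
  GenConfig gc = gen_config(cfg);
  GenLayout L = make_gen_layout(clusters, k, n, 1, gc);
  std::mt19937_64 rng(seed);
  vec th = init_gen(L, rng, out_bias);
  return Rcpp::List::create(Rcpp::Named("theta") = th,
                            Rcpp::Named("d") = L.d,
                            Rcpp::Named("n_params") = L.total);
}

// [[Rcpp::export]]
Rcpp::List cpp_disc_init(int k, int n, int units, int seed) {
  DiscLayout L = make_disc_layout(k, n, units);
  std::mt19937_64 rng(seed);
  vec th = init_disc(L, rng);
  return Rcpp::List::create(Rcpp::Named("theta") = th,
                            Rcpp::Named("n_params") = L.total);
}

// X: cube (k, n, S); E, Df, Db: S x k matrices
// [[Rcpp::export]]
Rcpp::List cpp_gen_forward(arma::vec theta, arma::cube X, arma::mat E,
                           arma::mat Df, arma::mat Db, Rcpp::List clusters,
                           Rcpp::List cfg, bool training, int seed) {
  GenConfig gc = gen_config(cfg);
  GenLayout L = make_gen_layout(clusters, X.n_rows, X.n_cols, X.n_slices,
                                gc);
  if (theta.n_elem != (uword)L.total) Rcpp::stop("parameter size mismatch");
  std::mt19937_64 rng(seed);
  cube Xs = to_snk(X);
  GenWs W;
  build_cluster_inputs(W, L, Xs, E);
  gen_forward(theta, L, W, Xs, E, Df, Db, training, rng);
  if (!W.XBAR.is_finite()) Rcpp::stop("non-finite generator output");
  // forward-direction features back in (k, d, S) order for inspection
  cube F(L.k, L.d, L.S);
  for (int i = 0; i < L.k; ++i)
    for (int s = 0; s < L.S; ++s)
      F.slice(s).row(i) = W.Ff.row(s + L.S * i);
  return Rcpp::List::create(
      Rcpp::Named("x_tilde_f") = to_kns(W.XF),
      Rcpp::Named("x_tilde_b") = to_kns(W.XB),
      Rcpp::Named("x_tilde") = to_kns(W.XT),
      Rcpp::Named("x_bar") = to_kns(W.XBAR),
      Rcpp::Named("lambda_f") = W.lamf, Rcpp::Named("lambda_b") = W.lamb,
      Rcpp::Named("features") = F);
}

// [[Rcpp::export]]
Rcpp::List cpp_disc_forward(arma::vec theta, arma::cube Y, int units) {
  int k = Y.n_rows, n = Y.n_cols, S = Y.n_slices;
  DiscLayout L = make_disc_layout(k, n, units);
  if (theta.n_elem != (uword)L.total) Rcpp::stop("parameter size mismatch");
  DiscWs W;
  disc_alloc(W, S, units, k);
  disc_forward(theta, L, W, to_snk(Y));
  // probs out as (k, k, S): row = timestep, col = class
  cube probs(k, k, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) probs(i, j, s) = W.probs(s, j, i);
  return Rcpp::List::create(Rcpp::Named("p_real") = W.p,
                            Rcpp::Named("timepoint_probs") = probs);
}

// [[Rcpp::export]]
Rcpp::List cpp_gen_loss_grad(arma::vec thetaG, arma::vec thetaD,
                             arma::cube X, arma::mat E, arma::mat Df,
                             arma::mat Db, Rcpp::List clusters,
                             Rcpp::List cfg, int disc_units, bool use_disc,
                             bool training, int seed) {
  GenConfig gc = gen_config(cfg);
  GenLayout L = make_gen_layout(clusters, X.n_rows, X.n_cols, X.n_slices,
                                gc);
  DiscLayout DL = make_disc_layout(X.n_rows, X.n_cols, disc_units);
  std::mt19937_64 rng(seed);
  cube Xs = to_snk(X);
  GenWs W;
  build_cluster_inputs(W, L, Xs, E);
  DiscWs DW;
  disc_alloc(DW, L.S, disc_units, L.k);
  gen_forward(thetaG, L, W, Xs, E, Df, Db, training, rng);
  vec grad(L.total, fill::zeros);
  GenLossOut out = gen_loss_backward(thetaG, thetaD, L, DL, W, DW, Xs, E,
                                     Df, Db, use_disc, grad);
  return Rcpp::List::create(
      Rcpp::Named("total") = out.total, Rcpp::Named("lossG") = out.lossG,
      Rcpp::Named("lossR") = out.lossR, Rcpp::Named("lossC") = out.lossC,
      Rcpp::Named("grad") = grad);
}

// Yreal/Yfake as cubes (k, n, S)
// [[Rcpp::export]]
Rcpp::List cpp_disc_loss_grad(arma::vec thetaD, arma::cube Yreal,
                              arma::cube Yfake, int disc_units) {
  int k = Yreal.n_rows, n = Yreal.n_cols, S = Yreal.n_slices;
  DiscLayout L = make_disc_layout(k, n, disc_units);
  vec grad(L.total, fill::zeros);
  DiscWs DWr, DWf;
  disc_alloc(DWr, S, disc_units, k);
  disc_alloc(DWf, S, disc_units, k);
  DiscLossOut out = disc_loss_backward(thetaD, L, DWr, DWf, to_snk(Yreal),
                                       to_snk(Yfake), grad);
  return Rcpp::List::create(
      Rcpp::Named("total") = out.total, Rcpp::Named("lossD") = out.lossD,
      Rcpp::Named("lossT") = out.lossT, Rcpp::Named("grad") = grad);
}

// -------------------------------------------------------------- training

struct Adam {
  vec m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Adam(int npar, double lr_) : m(npar, fill::zeros), v(npar, fill::zeros),
                               lr(lr_) {}
  void step(vec& th, const vec& g) {
    ++t;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double a = lr * std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    th -= a * (m / (sqrt(v) + eps));
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_train(arma::cube X, arma::mat E, arma::mat Df, arma::mat Db,
                     Rcpp::List clusters, Rcpp::List cfg, int disc_units,
                     bool use_disc, double lr, int d_steps, int patience,
                     int max_epochs, int seed, arma::vec out_bias) {
  GenConfig gc = gen_config(cfg);
  int k = X.n_rows, n = X.n_cols, S = X.n_slices;
  GenLayout L = make_gen_layout(clusters, k, n, S, gc);
  DiscLayout DL = make_disc_layout(k, n, disc_units);
  std::mt19937_64 rng(seed);
  vec thG = init_gen(L, rng, out_bias);
  vec thD = init_disc(DL, rng);
  Adam optG(L.total, lr), optD(DL.total, lr);

  cube Xs = to_snk(X);
  GenWs W;
  build_cluster_inputs(W, L, Xs, E);
  DiscWs DW, DWr, DWf;
  disc_alloc(DW, S, disc_units, k);
  disc_alloc(DWr, S, disc_units, k);
  disc_alloc(DWf, S, disc_units, k);

  // real branch input x (.) e is constant across epochs
  cube Yreal(S, n, k);
  for (int i = 0; i < k; ++i)
    Yreal.slice(i) = Xs.slice(i).each_col() % E.col(i);

  mat hist(max_epochs, 7);
  double best = datum::inf;
  int best_epoch = 0, since = 0, epoch = 0;
  bool cap_hit = true;
  vec gradG(L.total), gradD(DL.total);

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    double eLossD = 0, eLossT = 0;
    // one generator pass per epoch: it is reused for the discriminator
    // iterations (the generator is fixed during them) and the G update
    gen_forward(thG, L, W, Xs, E, Df, Db, true, rng);
    if (use_disc) {
      cube Yfake(S, n, k);
      for (int i = 0; i < k; ++i)
        Yfake.slice(i) = W.XBAR.slice(i).each_col() % (1.0 - E.col(i));
      for (int it = 0; it < d_steps; ++it) {
        gradD.zeros();
        DiscLossOut dout = disc_loss_backward(thD, DL, DWr, DWf, Yreal,
                                              Yfake, gradD);
        eLossD = dout.lossD; eLossT = dout.lossT;
        if (!gradD.is_finite())
          Rcpp::stop("discriminator divergence (NaN) at epoch %d", epoch);
        optD.step(thD, gradD);
      }
    }
    gradG.zeros();
    GenLossOut gout = gen_loss_backward(thG, thD, L, DL, W, DW, Xs, E, Df,
                                        Db, use_disc, gradG);
    if (!std::isfinite(gout.total) || !gradG.is_finite())
      Rcpp::stop("generator divergence (NaN) at epoch %d", epoch);
    optG.step(thG, gradG);

    hist(epoch - 1, 0) = eLossD;
    hist(epoch - 1, 1) = eLossT;
    hist(epoch - 1, 2) = eLossD + eLossT;
    hist(epoch - 1, 3) = gout.lossG;
    hist(epoch - 1, 4) = gout.lossR;
    hist(epoch - 1, 5) = gout.lossC;
    hist(epoch - 1, 6) = gout.total;

    if (gout.total < best) {
      best = gout.total; best_epoch = epoch; since = 0;
    } else {
      ++since;
    }
    if (since >= patience) { cap_hit = false; break; }
    if (epoch % 500 == 0) Rcpp::checkUserInterrupt();
  }
  int ran = std::min(epoch, max_epochs);
  // the final weights are kept: the plateau criterion only decides when to
  // stop (the adversarial term drifts as the discriminator strengthens, so
  // the minimum of the total is not the best reconstruction)
  return Rcpp::List::create(
      Rcpp::Named("theta_g") = thG, Rcpp::Named("theta_d") = thD,
      Rcpp::Named("history") = hist.rows(0, ran - 1),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_loss") = best,
      Rcpp::Named("epochs_run") = ran,
      Rcpp::Named("max_epochs_hit") = cap_hit);
}
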