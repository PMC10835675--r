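// Dual-encoder transformer core: forward, backward, attention extraction and
// input-embedding gradients.  Templated on the floating type so training can
// run in single precision while exactness tests use double.
//
// Conventions shared with the R side:
//   * token ids are 0-based; sequences arrive as padded integer matrices plus
//     a length vector, and each sequence is truncated to its true length
//     before any computation, so padding can never leak into results;
//   * parameters travel as a flat named list ("tok_emb", "f1.Wq", ...,
//     "head.Wh", ...); gradients come back under the same names;
//   * encoder blocks are post-layer-norm with GELU feed-forward sublayers;
//     the regression head is ReLU -> linear.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Cfg {
  int d, heads, layers, ffn, pooling;  // pooling: 0 = first token, 1 = mean
  bool use_pam, tie, sym_head;
  double dropout;
};

Cfg read_cfg(const List& c) {
  Cfg cfg;
  cfg.d = as<int>(c["d_model"]);
  cfg.heads = as<int>(c["n_heads"]);
  cfg.layers = as<int>(c["n_layers"]);
  cfg.ffn = as<int>(c["ffn_dim"]);
  cfg.pooling = as<int>(c["pooling_code"]);
  cfg.use_pam = as<bool>(c["use_pam"]);
  cfg.tie = as<bool>(c["tie_encoders"]);
  cfg.sym_head = as<bool>(c["symmetric_head"]);
  cfg.dropout = as<double>(c["dropout"]);
  if (cfg.d % cfg.heads != 0) stop("d_model must be divisible by n_heads");
  return cfg;
}

template <typename eT>
arma::Mat<eT> getM(const List& p, const std::string& nm) {
  NumericMatrix m = p[nm];
  arma::mat dm(m.begin(), m.nrow(), m.ncol(), false);
  return arma::conv_to<arma::Mat<eT>>::from(dm);
}

template <typename eT>
arma::Col<eT> getV(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  arma::vec dv(v.begin(), v.size(), false);
  return arma::conv_to<arma::Col<eT>>::from(dv);
}

template <typename eT>
struct LayerP {
  arma::Mat<eT> Wq, Wk, Wv, Wo, W1, W2;
  arma::Col<eT> bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
};

template <typename eT>
struct ParamsT {
  arma::Mat<eT> tok_emb;             // vocab x d
  std::vector<LayerP<eT>> f, r;      // encoder stacks
  arma::Mat<eT> Wh;                  // zdim x hidden
  arma::Col<eT> bh, Wout;            // hidden
  eT bout;
};

template <typename eT>
LayerP<eT> load_layer(const List& p, const std::string& pre) {
  LayerP<eT> L;
  L.Wq = getM<eT>(p, pre + ".Wq"); L.bq = getV<eT>(p, pre + ".bq");
  L.Wk = getM<eT>(p, pre + ".Wk"); L.bk = getV<eT>(p, pre + ".bk");
  L.Wv = getM<eT>(p, pre + ".Wv"); L.bv = getV<eT>(p, pre + ".bv");
  L.Wo = getM<eT>(p, pre + ".Wo"); L.bo = getV<eT>(p, pre + ".bo");
  L.W1 = getM<eT>(p, pre + ".W1"); L.b1 = getV<eT>(p, pre + ".b1");
  L.W2 = getM<eT>(p, pre + ".W2"); L.b2 = getV<eT>(p, pre + ".b2");
  L.g1 = getV<eT>(p, pre + ".ln1.g"); L.be1 = getV<eT>(p, pre + ".ln1.b");
  L.g2 = getV<eT>(p, pre + ".ln2.g"); L.be2 = getV<eT>(p, pre + ".ln2.b");
  return L;
}

template <typename eT>
ParamsT<eT> load_params(const List& p, const Cfg& cfg) {
  ParamsT<eT> P;
  P.tok_emb = getM<eT>(p, "tok_emb");
  for (int i = 1; i <= cfg.layers; ++i)
    P.f.push_back(load_layer<eT>(p, "f" + std::to_string(i)));
  if (cfg.use_pam && !cfg.tie)
    for (int i = 1; i <= cfg.layers; ++i)
      P.r.push_back(load_layer<eT>(p, "r" + std::to_string(i)));
  P.Wh = getM<eT>(p, "head.Wh");
  P.bh = getV<eT>(p, "head.bh");
  P.Wout = getV<eT>(p, "head.Wout");
  P.bout = (eT)as<double>(p["head.bout"]);
  return P;
}

template <typename eT>
LayerP<eT> zeros_layer(const LayerP<eT>& L) {
  LayerP<eT> G;
  G.Wq.zeros(arma::size(L.Wq)); G.bq.zeros(arma::size(L.bq));
  G.Wk.zeros(arma::size(L.Wk)); G.bk.zeros(arma::size(L.bk));
  G.Wv.zeros(arma::size(L.Wv)); G.bv.zeros(arma::size(L.bv));
  G.Wo.zeros(arma::size(L.Wo)); G.bo.zeros(arma::size(L.bo));
  G.W1.zeros(arma::size(L.W1)); G.b1.zeros(arma::size(L.b1));
  G.W2.zeros(arma::size(L.W2)); G.b2.zeros(arma::size(L.b2));
  G.g1.zeros(arma::size(L.g1)); G.be1.zeros(arma::size(L.be1));
  G.g2.zeros(arma::size(L.g2)); G.be2.zeros(arma::size(L.be2));
  return G;
}

template <typename eT>
ParamsT<eT> zeros_params(const ParamsT<eT>& P) {
  ParamsT<eT> G;
  G.tok_emb.zeros(arma::size(P.tok_emb));
  for (auto& L : P.f) G.f.push_back(zeros_layer(L));
  for (auto& L : P.r) G.r.push_back(zeros_layer(L));
  G.Wh.zeros(arma::size(P.Wh));
  G.bh.zeros(arma::size(P.bh));
  G.Wout.zeros(arma::size(P.Wout));
  G.bout = (eT)0;
  return G;
}

template <typename eT>
void store_layer(List& out, const std::string& pre, const LayerP<eT>& L) {
  out[pre + ".Wq"] = wrap(arma::conv_to<arma::mat>::from(L.Wq));
  out[pre + ".bq"] = wrap(arma::conv_to<arma::vec>::from(L.bq));
  out[pre + ".Wk"] = wrap(arma::conv_to<arma::mat>::from(L.Wk));
  out[pre + ".bk"] = wrap(arma::conv_to<arma::vec>::from(L.bk));
  out[pre + ".Wv"] = wrap(arma::conv_to<arma::mat>::from(L.Wv));
  out[pre + ".bv"] = wrap(arma::conv_to<arma::vec>::from(L.bv));
  out[pre + ".Wo"] = wrap(arma::conv_to<arma::mat>::from(L.Wo));
  out[pre + ".bo"] = wrap(arma::conv_to<arma::vec>::from(L.bo));
  out[pre + ".W1"] = wrap(arma::conv_to<arma::mat>::from(L.W1));
  out[pre + ".b1"] = wrap(arma::conv_to<arma::vec>::from(L.b1));
  out[pre + ".W2"] = wrap(arma::conv_to<arma::mat>::from(L.W2));
  out[pre + ".b2"] = wrap(arma::conv_to<arma::vec>::from(L.b2));
  out[pre + ".ln1.g"] = wrap(arma::conv_to<arma::vec>::from(L.g1));
  out[pre + ".ln1.b"] = wrap(arma::conv_to<arma::vec>::from(L.be1));
  out[pre + ".ln2.g"] = wrap(arma::conv_to<arma::vec>::from(L.g2));
  out[pre + ".ln2.b"] = wrap(arma::conv_to<arma::vec>::from(L.be2));
}

template <typename eT>
List params_to_list(const ParamsT<eT>& P, const Cfg& cfg) {
  List out;
  out["tok_emb"] = wrap(arma::conv_to<arma::mat>::from(P.tok_emb));
  for (int i = 1; i <= cfg.layers; ++i)
    store_layer(out, "f" + std::to_string(i), P.f[i - 1]);
  if (cfg.use_pam && !cfg.tie)
    for (int i = 1; i <= cfg.layers; ++i)
      store_layer(out, "r" + std::to_string(i), P.r[i - 1]);
  out["head.Wh"] = wrap(arma::conv_to<arma::mat>::from(P.Wh));
  out["head.bh"] = wrap(arma::conv_to<arma::vec>::from(P.bh));
  out["head.Wout"] = wrap(arma::conv_to<arma::vec>::from(P.Wout));
  out["head.bout"] = (double)P.bout;
  return out;
}

// ---- elementwise pieces ----------------------------------------------------

template <typename eT>
struct LNCache {
  arma::Mat<eT> xhat;
  arma::Col<eT> inv_sd;
};

template <typename eT>
arma::Mat<eT> ln_fwd(const arma::Mat<eT>& X, const arma::Col<eT>& g,
                     const arma::Col<eT>& b, LNCache<eT>& c) {
  const eT eps = (eT)1e-5;
  arma::Col<eT> mu = arma::mean(X, 1);
  arma::Mat<eT> Xc = X.each_col() - mu;
  arma::Col<eT> var = arma::mean(arma::square(Xc), 1);
  c.inv_sd = (eT)1 / arma::sqrt(var + eps);
  c.xhat = Xc.each_col() % c.inv_sd;
  arma::Mat<eT> Y = c.xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

template <typename eT>
arma::Mat<eT> ln_bwd(const arma::Mat<eT>& dY, const arma::Col<eT>& g,
                     const LNCache<eT>& c, arma::Col<eT>& dg, arma::Col<eT>& db) {
  dg += arma::sum(dY % c.xhat, 0).t();
  db += arma::sum(dY, 0).t();
  arma::Mat<eT> dxhat = dY.each_row() % g.t();
  arma::Col<eT> m1 = arma::mean(dxhat, 1);
  arma::Col<eT> m2 = arma::mean(dxhat % c.xhat, 1);
  arma::Mat<eT> dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv_sd;
  return dX;
}

template <typename eT>
arma::Mat<eT> gelu(const arma::Mat<eT>& X) {
  arma::Mat<eT> Y = X;
  Y.transform([](eT x) {
    double xd = (double)x;
    return (eT)(0.5 * xd * (1.0 + std::erf(xd * M_SQRT1_2)));
  });
  return Y;
}

template <typename eT>
arma::Mat<eT> dgelu(const arma::Mat<eT>& X) {
  arma::Mat<eT> Y = X;
  Y.transform([](eT x) {
    double xd = (double)x;
    double Phi = 0.5 * (1.0 + std::erf(xd * M_SQRT1_2));
    double phi = std::exp(-0.5 * xd * xd) / std::sqrt(2.0 * M_PI);
    return (eT)(Phi + xd * phi);
  });
  return Y;
}

template <typename eT>
arma::Mat<eT> dropmask(int nr, int nc, double p, std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  arma::Mat<eT> M(nr, nc);
  const eT scale = (eT)(1.0 / (1.0 - p));
  for (arma::uword j = 0; j < M.n_cols; ++j)
    for (arma::uword i = 0; i < M.n_rows; ++i)
      M(i, j) = unif(rng) < p ? (eT)0 : scale;
  return M;
}

// ---- encoder block ---------------------------------------------------------

template <typename eT>
struct LCache {
  arma::Mat<eT> Xin, Q, K, V, Hcat, X1, Fpre, Fact;
  arma::Cube<eT> A;
  LNCache<eT> ln1, ln2;
  arma::Mat<eT> mask1, mask2;
};

template <typename eT>
arma::Mat<eT> layer_fwd(const arma::Mat<eT>& Xin, const LayerP<eT>& P,
                        const Cfg& cfg, LCache<eT>& c, std::mt19937* rng) {
  const int T = Xin.n_rows, d = cfg.d, H = cfg.heads, dh = d / H;
  const eT scale = (eT)(1.0 / std::sqrt((double)dh));
  c.Xin = Xin;
  c.Q = Xin * P.Wq; c.Q.each_row() += P.bq.t();
  c.K = Xin * P.Wk; c.K.each_row() += P.bk.t();
  c.V = Xin * P.Wv; c.V.each_row() += P.bv.t();
  c.A.set_size(T, T, H);
  c.Hcat.set_size(T, d);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = (h + 1) * dh - 1;
    arma::Mat<eT> S = c.Q.cols(c0, c1) * c.K.cols(c0, c1).t() * scale;
    arma::Col<eT> mx = arma::max(S, 1);
    S.each_col() -= mx;
    S = arma::exp(S);
    arma::Col<eT> sm = arma::sum(S, 1);
    S.each_col() /= sm;
    c.A.slice(h) = S;
    c.Hcat.cols(c0, c1) = S * c.V.cols(c0, c1);
  }
  arma::Mat<eT> O = c.Hcat * P.Wo;
  O.each_row() += P.bo.t();
  if (rng != nullptr && cfg.dropout > 0) {
    c.mask1 = dropmask<eT>(T, d, cfg.dropout, *rng);
    O %= c.mask1;
  }
  arma::Mat<eT> res1 = Xin + O;
  c.X1 = ln_fwd(res1, P.g1, P.be1, c.ln1);
  c.Fpre = c.X1 * P.W1;
  c.Fpre.each_row() += P.b1.t();
  c.Fact = gelu(c.Fpre);
  arma::Mat<eT> G = c.Fact * P.W2;
  G.each_row() += P.b2.t();
  if (rng != nullptr && cfg.dropout > 0) {
    c.mask2 = dropmask<eT>(T, d, cfg.dropout, *rng);
    G %= c.mask2;
  }
  arma::Mat<eT> res2 = c.X1 + G;
  return ln_fwd(res2, P.g2, P.be2, c.ln2);
}

template <typename eT>
arma::Mat<eT> layer_bwd(const arma::Mat<eT>& dXout, const LayerP<eT>& P,
                        const Cfg& cfg, const LCache<eT>& c, LayerP<eT>& G) {
  const int T = c.Xin.n_rows, d = cfg.d, H = cfg.heads, dh = d / H;
  const eT scale = (eT)(1.0 / std::sqrt((double)dh));
  arma::Mat<eT> dres2 = ln_bwd(dXout, P.g2, c.ln2, G.g2, G.be2);
  arma::Mat<eT> dG = dres2;
  if (c.mask2.n_elem > 0) dG %= c.mask2;
  arma::Mat<eT> dX1 = dres2;
  G.W2 += c.Fact.t() * dG;
  G.b2 += arma::sum(dG, 0).t();
  arma::Mat<eT> dFpre = (dG * P.W2.t()) % dgelu(c.Fpre);
  G.W1 += c.X1.t() * dFpre;
  G.b1 += arma::sum(dFpre, 0).t();
  dX1 += dFpre * P.W1.t();
  arma::Mat<eT> dres1 = ln_bwd(dX1, P.g1, c.ln1, G.g1, G.be1);
  arma::Mat<eT> dXin = dres1;
  arma::Mat<eT> dO = dres1;
  if (c.mask1.n_elem > 0) dO %= c.mask1;
  G.Wo += c.Hcat.t() * dO;
  G.bo += arma::sum(dO, 0).t();
  arma::Mat<eT> dH = dO * P.Wo.t();
  arma::Mat<eT> dQ(T, d), dK(T, d), dV(T, d);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = (h + 1) * dh - 1;
    const arma::Mat<eT>& A = c.A.slice(h);
    arma::Mat<eT> dHh = dH.cols(c0, c1);
    arma::Mat<eT> dA = dHh * c.V.cols(c0, c1).t();
    dV.cols(c0, c1) = A.t() * dHh;
    arma::Mat<eT> tmp = dA;
    tmp.each_col() -= arma::sum(dA % A, 1);     // softmax Jacobian, rowwise
    arma::Mat<eT> dS = A % tmp;
    dQ.cols(c0, c1) = dS * c.K.cols(c0, c1) * scale;
    dK.cols(c0, c1) = dS.t() * c.Q.cols(c0, c1) * scale;
  }
  dXin += dQ * P.Wq.t() + dK * P.Wk.t() + dV * P.Wv.t();
  G.Wq += c.Xin.t() * dQ; G.bq += arma::sum(dQ, 0).t();
  G.Wk += c.Xin.t() * dK; G.bk += arma::sum(dK, 0).t();
  G.Wv += c.Xin.t() * dV; G.bv += arma::sum(dV, 0).t();
  return dXin;
}

// ---- per-sequence forward / backward --------------------------------------

template <typename eT>
struct SeqWork {
  std::vector<LCache<eT>> cf, cr;
  arma::Col<eT> z, h1pre, h1;
  int Tf = 0, Tr = 0;
  eT y = 0;
};

template <typename eT>
arma::Col<eT> pool(const arma::Mat<eT>& X, int pooling) {
  if (pooling == 0) return X.row(0).t();
  return arma::mean(X, 0).t();
}

template <typename eT>
eT seq_forward(const arma::Mat<eT>& X0f, const arma::Mat<eT>& X0r,
               const ParamsT<eT>& P, const Cfg& cfg, SeqWork<eT>& w,
               std::mt19937* rng) {
  w.Tf = X0f.n_rows;
  w.cf.assign(cfg.layers, LCache<eT>());
  arma::Mat<eT> X = X0f;
  for (int l = 0; l < cfg.layers; ++l) X = layer_fwd(X, P.f[l], cfg, w.cf[l], rng);
  arma::Col<eT> u = pool(X, cfg.pooling);
  if (cfg.use_pam) {
    w.Tr = X0r.n_rows;
    w.cr.assign(cfg.layers, LCache<eT>());
    const std::vector<LayerP<eT>>& enc_r = cfg.tie ? P.f : P.r;
    arma::Mat<eT> Xr = X0r;
    for (int l = 0; l < cfg.layers; ++l) Xr = layer_fwd(Xr, enc_r[l], cfg, w.cr[l], rng);
    arma::Col<eT> v = pool(Xr, cfg.pooling);
    if (cfg.sym_head) w.z = u + v;
    else w.z = arma::join_cols(u, v);
  } else {
    w.z = u;
  }
  w.h1pre = P.Wh.t() * w.z + P.bh;
  w.h1 = arma::clamp(w.h1pre, (eT)0, std::numeric_limits<eT>::max());
  w.y = arma::dot(P.Wout, w.h1) + P.bout;
  return w.y;
}

template <typename eT>
void seq_backward(eT dy, const ParamsT<eT>& P, const Cfg& cfg, SeqWork<eT>& w,
                  ParamsT<eT>& G, arma::Mat<eT>& dX0f, arma::Mat<eT>& dX0r) {
  G.Wout += dy * w.h1;
  G.bout += dy;
  arma::Col<eT> dh1 = dy * P.Wout;
  for (arma::uword i = 0; i < dh1.n_elem; ++i)
    if (w.h1pre(i) <= (eT)0) dh1(i) = (eT)0;
  G.Wh += w.z * dh1.t();
  G.bh += dh1;
  arma::Col<eT> dz = P.Wh * dh1;
  arma::Col<eT> du, dv;
  if (cfg.use_pam) {
    if (cfg.sym_head) { du = dz; dv = dz; }
    else { du = dz.head(cfg.d); dv = dz.tail(cfg.d); }
  } else {
    du = dz;
  }
  auto unpool = [&](const arma::Col<eT>& dp, int T) {
    arma::Mat<eT> dX(T, cfg.d, arma::fill::zeros);
    if (cfg.pooling == 0) dX.row(0) = dp.t();
    else dX.each_row() += dp.t() / (eT)T;
    return dX;
  };
  arma::Mat<eT> dX = unpool(du, w.Tf);
  for (int l = cfg.layers - 1; l >= 0; --l)
    dX = layer_bwd(dX, P.f[l], cfg, w.cf[l], G.f[l]);
  dX0f = dX;
  if (cfg.use_pam) {
    const std::vector<LayerP<eT>>& enc_r = cfg.tie ? P.f : P.r;
    std::vector<LayerP<eT>>& grd_r = cfg.tie ? G.f : G.r;
    arma::Mat<eT> dXr = unpool(dv, w.Tr);
    for (int l = cfg.layers - 1; l >= 0; --l)
      dXr = layer_bwd(dXr, enc_r[l], cfg, w.cr[l], grd_r[l]);
    dX0r = dXr;
  }
}

// Build input embeddings for one sequence: token embedding (scaled by
// sqrt(d_model), the canonical balance against the unit-amplitude
// sinusoidal positional term) + positional encoding.
template <typename eT>
arma::Mat<eT> build_x0(const arma::Mat<eT>& tok_emb, const arma::Mat<eT>& PE,
                       const IntegerMatrix& ids, int seq, int len) {
  const eT scale = (eT)std::sqrt((double)tok_emb.n_cols);
  arma::Mat<eT> X(len, tok_emb.n_cols);
  for (int t = 0; t < len; ++t)
    X.row(t) = tok_emb.row(ids(seq, t)) * scale + PE.row(t);
  return X;
}

// ---- batch drivers ---------------------------------------------------------

template <typename eT>
List train_batch_t(const List& params, const List& cfg_r, const NumericMatrix& PE_r,
                   const IntegerMatrix& fwd, const IntegerMatrix& rev,
                   const IntegerVector& lens, const NumericVector& targets,
                   bool train, int seed) {
  Cfg cfg = read_cfg(cfg_r);
  if (!train) cfg.dropout = 0.0;
  ParamsT<eT> P = load_params<eT>(params, cfg);
  ParamsT<eT> G = zeros_params(P);
  arma::Mat<eT> PE = arma::conv_to<arma::Mat<eT>>::from(
      arma::mat(const_cast<double*>(PE_r.begin()), PE_r.nrow(), PE_r.ncol(), false));
  const int B = fwd.nrow();
  NumericVector preds(B);
  double loss = 0.0;
  SeqWork<eT> w;
  for (int s = 0; s < B; ++s) {
    const int len = lens[s];
    arma::Mat<eT> X0f = build_x0(P.tok_emb, PE, fwd, s, len);
    arma::Mat<eT> X0r;
    if (cfg.use_pam) X0r = build_x0(P.tok_emb, PE, rev, s, len);
    std::mt19937 rng((unsigned)(seed) + 7919u * (unsigned)s);
    std::mt19937* rp = (train && cfg.dropout > 0) ? &rng : nullptr;
    eT y = seq_forward(X0f, X0r, P, cfg, w, rp);
    preds[s] = (double)y;
    const double resid = (double)y - targets[s];
    loss += resid * resid / B;
    eT dy = (eT)(2.0 * resid / B);
    arma::Mat<eT> dX0f, dX0r;
    seq_backward(dy, P, cfg, w, G, dX0f, dX0r);
    const eT emb_scale = (eT)std::sqrt((double)cfg.d);
    for (int t = 0; t < len; ++t) {
      G.tok_emb.row(fwd(s, t)) += dX0f.row(t) * emb_scale;
      if (cfg.use_pam) G.tok_emb.row(rev(s, t)) += dX0r.row(t) * emb_scale;
    }
  }
  return List::create(_["loss"] = loss, _["preds"] = preds,
                      _["grads"] = params_to_list(G, cfg));
}

template <typename eT>
NumericVector predict_batch_t(const List& params, const List& cfg_r,
                              const NumericMatrix& PE_r, const IntegerMatrix& fwd,
                              const IntegerMatrix& rev, const IntegerVector& lens) {
  Cfg cfg = read_cfg(cfg_r);
  cfg.dropout = 0.0;
  ParamsT<eT> P = load_params<eT>(params, cfg);
  arma::Mat<eT> PE = arma::conv_to<arma::Mat<eT>>::from(
      arma::mat(const_cast<double*>(PE_r.begin()), PE_r.nrow(), PE_r.ncol(), false));
  const int B = fwd.nrow();
  NumericVector preds(B);
  SeqWork<eT> w;
  for (int s = 0; s < B; ++s) {
    const int len = lens[s];
    arma::Mat<eT> X0f = build_x0(P.tok_emb, PE, fwd, s, len);
    arma::Mat<eT> X0r;
    if (cfg.use_pam) X0r = build_x0(P.tok_emb, PE, rev, s, len);
    preds[s] = (double)seq_forward(X0f, X0r, P, cfg, w, nullptr);
  }
  return preds;
}

template <typename eT>
List attention_batch_t(const List& params, const List& cfg_r,
                       const NumericMatrix& PE_r, const IntegerMatrix& fwd,
                       const IntegerMatrix& rev, const IntegerVector& lens) {
  Cfg cfg = read_cfg(cfg_r);
  cfg.dropout = 0.0;
  ParamsT<eT> P = load_params<eT>(params, cfg);
  arma::Mat<eT> PE = arma::conv_to<arma::Mat<eT>>::from(
      arma::mat(const_cast<double*>(PE_r.begin()), PE_r.nrow(), PE_r.ncol(), false));
  const int B = fwd.nrow();
  arma::cube sf(cfg.layers, cfg.heads, B, arma::fill::zeros);
  arma::cube sr(cfg.layers, cfg.heads, B, arma::fill::zeros);
  arma::cube cf2(cfg.layers, cfg.heads, B, arma::fill::zeros);
  arma::cube cr2(cfg.layers, cfg.heads, B, arma::fill::zeros);
  SeqWork<eT> w;
  for (int s = 0; s < B; ++s) {
    const int len = lens[s];
    arma::Mat<eT> X0f = build_x0(P.tok_emb, PE, fwd, s, len);
    arma::Mat<eT> X0r;
    if (cfg.use_pam) X0r = build_x0(P.tok_emb, PE, rev, s, len);
    seq_forward(X0f, X0r, P, cfg, w, nullptr);
    for (int l = 0; l < cfg.layers; ++l)
      for (int h = 0; h < cfg.heads; ++h) {
        // accumulate in double so conservation holds to the softmax's own
        // rounding, not the (much larger) float summation error
        arma::mat Af = arma::conv_to<arma::mat>::from(w.cf[l].A.slice(h));
        sf(l, h, s) = arma::accu(Af);
        cf2(l, h, s) = arma::accu(Af % Af);
        if (cfg.use_pam) {
          arma::mat Ar = arma::conv_to<arma::mat>::from(w.cr[l].A.slice(h));
          sr(l, h, s) = arma::accu(Ar);
          cr2(l, h, s) = arma::accu(Ar % Ar);
        }
      }
  }
  return List::create(_["forward"] = sf, _["reverse"] = sr,
                      _["forward_conc"] = cf2, _["reverse_conc"] = cr2);
}

template <typename eT>
List embed_grad_batch_t(const List& params, const List& cfg_r,
                        const arma::cube& Xf, const arma::cube& Xr,
                        const IntegerVector& lens) {
  Cfg cfg = read_cfg(cfg_r);
  cfg.dropout = 0.0;
  ParamsT<eT> P = load_params<eT>(params, cfg);
  const int B = Xf.n_slices;
  NumericVector preds(B);
  arma::cube dXf(arma::size(Xf), arma::fill::zeros);
  arma::cube dXr;
  if (cfg.use_pam) dXr.zeros(arma::size(Xr));
  SeqWork<eT> w;
  ParamsT<eT> G = zeros_params(P);
  for (int s = 0; s < B; ++s) {
    const int len = lens[s];
    arma::Mat<eT> X0f = arma::conv_to<arma::Mat<eT>>::from(
        Xf.slice(s).rows(0, len - 1));
    arma::Mat<eT> X0r;
    if (cfg.use_pam)
      X0r = arma::conv_to<arma::Mat<eT>>::from(Xr.slice(s).rows(0, len - 1));
    preds[s] = (double)seq_forward(X0f, X0r, P, cfg, w, nullptr);
    arma::Mat<eT> gf, gr;
    seq_backward((eT)1, P, cfg, w, G, gf, gr);
    dXf.slice(s).rows(0, len - 1) = arma::conv_to<arma::mat>::from(gf);
    if (cfg.use_pam)
      dXr.slice(s).rows(0, len - 1) = arma::conv_to<arma::mat>::from(gr);
  }
  return List::create(_["preds"] = preds, _["dXf"] = dXf, _["dXr"] = dXr);
}

}  // namespace

// [[Rcpp::export]]
List dqf_train_batch(List params, List cfg, NumericMatrix PE, IntegerMatrix fwd,
                     IntegerMatrix rev, IntegerVector lens, NumericVector targets,
                     bool train, int seed, bool single_precision) {
  if (single_precision)
    return train_batch_t<float>(params, cfg, PE, fwd, rev, lens, targets, train, seed);
  return train_batch_t<double>(params, cfg, PE, fwd, rev, lens, targets, train, seed);
}

// [[Rcpp::export]]
NumericVector dqf_predict_batch(List params, List cfg, NumericMatrix PE,
                                IntegerMatrix fwd, IntegerMatrix rev,
                                IntegerVector lens, bool single_precision) {
  if (single_precision)
    return predict_batch_t<float>(params, cfg, PE, fwd, rev, lens);
  return predict_batch_t<double>(params, cfg, PE, fwd, rev, lens);
}

// [[Rcpp::export]]
List dqf_attention_batch(List params, List cfg, NumericMatrix PE,
                         IntegerMatrix fwd, IntegerMatrix rev, IntegerVector lens,
                         bool single_precision) {
  if (single_precision)
    return attention_batch_t<float>(params, cfg, PE, fwd, rev, lens);
  return attention_batch_t<double>(params, cfg, PE, fwd, rev, lens);
}

// [[Rcpp::export]]
List dqf_embed_grad_batch(List params, List cfg, arma::cube Xf, arma::cube Xr,
                          IntegerVector lens, bool single_precision) {
  if (single_precision)
    return embed_grad_batch_t<float>(params, cfg, Xf, Xr, lens);
  return embed_grad_batch_t<double>(params, cfg, Xf, Xr, lens);
}
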