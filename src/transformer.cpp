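// Image-to-sequence transformer: forward pass, backpropagation and greedy
// decoding. The architecture follows the standard encoder-decoder attention
// design: the flattened CNN feature grid is projected to d_model, position
// information is added, N encoder layers (self-attention + FFN) produce the
// memory, and N decoder layers (causal self-attention, cross-attention,
// FFN) predict the next token. Post-layer-norm residual blocks, ReLU FFN,
// inverted dropout, sparse categorical cross-entropy with pad masking.
//
// Everything is double precision; a private mt19937_64 stream drives
// dropout so a (seed, batch) pair is bit-reproducible.

#include <RcppArmadillo.h>
#include <map>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Hyper {
  int n_layers, n_heads, d_model, d_ff, vocab, pad_id, start_id, end_id;
  double dropout;
  bool learned_pos;
};

Hyper read_hyper(const List& cfg) {
  Hyper h;
  h.n_layers = as<int>(cfg["n_layers"]);
  h.n_heads = as<int>(cfg["n_heads"]);
  h.d_model = as<int>(cfg["d_model"]);
  h.d_ff = as<int>(cfg["d_ff"]);
  h.vocab = as<int>(cfg["vocab_size"]);
  h.pad_id = as<int>(cfg["pad_id"]);
  h.start_id = as<int>(cfg["start_id"]);
  h.end_id = as<int>(cfg["end_id"]);
  h.dropout = as<double>(cfg["dropout"]);
  h.learned_pos = as<std::string>(cfg["positional"]) == "learned";
  return h;
}

mat sinusoidal_pe(int len, int d) {
  mat pe(len, d, arma::fill::zeros);
  for (int p = 0; p < len; ++p) {
    for (int i = 0; i < d; i += 2) {
      double angle = p / std::pow(10000.0, (double)i / d);
      pe(p, i) = std::sin(angle);
      if (i + 1 < d) pe(p, i + 1) = std::cos(angle);
    }
  }
  return pe;
}

struct ParamStore {
  std::map<std::string, mat> p;
  const mat& operator[](const std::string& k) const {
    auto it = p.find(k);
    if (it == p.end()) stop("missing parameter: " + k);
    return it->second;
  }
};

ParamStore read_params(const List& params) {
  ParamStore ps;
  CharacterVector nm = params.names();
  for (int i = 0; i < params.size(); ++i) {
    ps.p[as<std::string>(nm[i])] = as<mat>(params[i]);
  }
  return ps;
}

struct GradStore {
  std::map<std::string, mat> g;
  mat& at(const std::string& k, const mat& like) {
    auto it = g.find(k);
    if (it == g.end()) {
      it = g.emplace(k, mat(like.n_rows, like.n_cols,
                            arma::fill::zeros)).first;
    }
    return it->second;
  }
};

// ---- building blocks --------------------------------------------------------

struct LNCache { mat xhat; vec inv_std; };

mat ln_forward(const mat& X, const mat& g, const mat& b, LNCache& c) {
  const double eps = 1e-5;
  vec mu = arma::mean(X, 1);
  vec va = arma::var(X, 1, 1);  // population variance per row
  c.inv_std = 1.0 / arma::sqrt(va + eps);
  c.xhat = (X.each_col() - mu).each_col() % c.inv_std;
  mat Y = c.xhat.each_row() % g.row(0);
  Y.each_row() += b.row(0);
  return Y;
}

mat ln_backward(const mat& dY, const LNCache& c, const mat& g,
                mat& dg, mat& db) {
  dg.row(0) += arma::sum(dY % c.xhat, 0);
  db.row(0) += arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g.row(0);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv_std;
  return dX;
}

struct Dropout {
  std::mt19937_64* rng;
  double p;
  mat apply(const mat& X, mat& mask) {
    if (p <= 0.0) { mask.reset(); return X; }
    std::uniform_real_distribution<double> u(0.0, 1.0);
    mask.set_size(X.n_rows, X.n_cols);
    double scale = 1.0 / (1.0 - p);
    for (arma::uword j = 0; j < X.n_cols; ++j)
      for (arma::uword i = 0; i < X.n_rows; ++i)
        mask(i, j) = (u(*rng) < p) ? 0.0 : scale;
    return X % mask;
  }
  mat back(const mat& dY, const mat& mask) {
    if (mask.n_elem == 0) return dY;
    return dY % mask;
  }
};

struct MHACache {
  mat Xq, Xkv, Q, K, V, ctx;
  std::vector<mat> A;  // per-head softmax matrices
};

mat mha_forward(const mat& Xq, const mat& Xkv,
                const mat& Wq, const mat& Wk, const mat& Wv, const mat& Wo,
                int n_heads, bool causal, MHACache& c) {
  int d = Wq.n_cols, dk = d / n_heads;
  double scl = 1.0 / std::sqrt((double)dk);
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * Wq; c.K = Xkv * Wk; c.V = Xkv * Wv;
  c.ctx.set_size(Xq.n_rows, d);
  c.A.assign(n_heads, mat());
  for (int h = 0; h < n_heads; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    mat S = c.Q.cols(cs) * c.K.cols(cs).t() * scl;
    if (causal) {
      for (arma::uword i = 0; i < S.n_rows; ++i)
        for (arma::uword j = i + 1; j < S.n_cols; ++j)
          S(i, j) = -1e30;
    }
    S.each_col() -= arma::max(S, 1);
    mat E = arma::exp(S);
    c.A[h] = E.each_col() / arma::sum(E, 1);
    c.ctx.cols(cs) = c.A[h] * c.V.cols(cs);
  }
  return c.ctx * Wo;
}

void mha_backward(const mat& dOut, const MHACache& c,
                  const mat& Wq, const mat& Wk, const mat& Wv, const mat& Wo,
                  mat& dWq, mat& dWk, mat& dWv, mat& dWo,
                  mat& dXq, mat& dXkv, int n_heads) {
  int d = Wq.n_cols, dk = d / n_heads;
  double scl = 1.0 / std::sqrt((double)dk);
  dWo += c.ctx.t() * dOut;
  mat dctx = dOut * Wo.t();
  mat dQ(c.Q.n_rows, d, arma::fill::zeros);
  mat dK(c.K.n_rows, d, arma::fill::zeros);
  mat dV(c.V.n_rows, d, arma::fill::zeros);
  for (int h = 0; h < n_heads; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    const mat& A = c.A[h];
    mat dA = dctx.cols(cs) * c.V.cols(cs).t();
    dV.cols(cs) = A.t() * dctx.cols(cs);
    mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
    dQ.cols(cs) = dS * c.K.cols(cs) * scl;
    dK.cols(cs) = dS.t() * c.Q.cols(cs) * scl;
  }
  dWq += c.Xq.t() * dQ;
  dWk += c.Xkv.t() * dK;
  dWv += c.Xkv.t() * dV;
  dXq += dQ * Wq.t();
  dXkv += dK * Wk.t() + dV * Wv.t();
}

struct FFNCache { mat X, H; };

mat ffn_forward(const mat& X, const mat& W1, const mat& b1,
                const mat& W2, const mat& b2, FFNCache& c) {
  c.X = X;
  c.H = X * W1;
  c.H.each_row() += b1.row(0);
  c.H.transform([](double v) { return v > 0 ? v : 0.0; });
  mat Y = c.H * W2;
  Y.each_row() += b2.row(0);
  return Y;
}

mat ffn_backward(const mat& dY, const FFNCache& c,
                 const mat& W1, const mat& W2,
                 mat& dW1, mat& db1, mat& dW2, mat& db2) {
  dW2 += c.H.t() * dY;
  db2.row(0) += arma::sum(dY, 0);
  mat dH = dY * W2.t();
  dH.elem(arma::find(c.H == 0)).zeros();
  dW1 += c.X.t() * dH;
  db1.row(0) += arma::sum(dH, 0);
  return dH * W1.t();
}

std::string key(const char* pre, int l, const char* suf) {
  return std::string(pre) + std::to_string(l) + "_" + suf;
}

// Encoder forward; fills caches for backward when `train`.
struct EncCache {
  mat X0;                       // after projection + pos + dropout
  mat drop_in;
  std::vector<MHACache> att;
  std::vector<FFNCache> ffn;
  std::vector<LNCache> ln1, ln2;
  std::vector<mat> pre_ln1, pre_ln2;    // sublayer inputs (residual source)
  std::vector<mat> drop_att, drop_ffn;
  std::vector<mat> X_in;                // layer inputs
};

mat encoder_forward(const mat& feats, const ParamStore& P, const Hyper& h,
                    Dropout& dr, bool train, EncCache& c) {
  mat X = feats * P["enc_proj_W"];
  X.each_row() += P["enc_proj_b"].row(0);
  if (h.learned_pos) {
    X += P["enc_pos"].rows(0, X.n_rows - 1);
  } else {
    X += sinusoidal_pe(X.n_rows, h.d_model);
  }
  if (train) X = dr.apply(X, c.drop_in);
  c.X0 = X;
  c.att.resize(h.n_layers); c.ffn.resize(h.n_layers);
  c.ln1.resize(h.n_layers); c.ln2.resize(h.n_layers);
  c.pre_ln1.resize(h.n_layers); c.pre_ln2.resize(h.n_layers);
  c.drop_att.resize(h.n_layers); c.drop_ffn.resize(h.n_layers);
  c.X_in.resize(h.n_layers);
  for (int l = 0; l < h.n_layers; ++l) {
    c.X_in[l] = X;
    mat A = mha_forward(X, X, P[key("enc", l, "Wq")], P[key("enc", l, "Wk")],
                        P[key("enc", l, "Wv")], P[key("enc", l, "Wo")],
                        h.n_heads, false, c.att[l]);
    if (train) A = dr.apply(A, c.drop_att[l]);
    c.pre_ln1[l] = X + A;
    X = ln_forward(c.pre_ln1[l], P[key("enc", l, "ln1_g")],
                   P[key("enc", l, "ln1_b")], c.ln1[l]);
    mat F = ffn_forward(X, P[key("enc", l, "W1")], P[key("enc", l, "b1")],
                        P[key("enc", l, "W2")], P[key("enc", l, "b2")],
                        c.ffn[l]);
    if (train) F = dr.apply(F, c.drop_ffn[l]);
    c.pre_ln2[l] = X + F;
    // note: ffn input is the ln1 output, cached inside c.ffn[l].X
    X = ln_forward(c.pre_ln2[l], P[key("enc", l, "ln2_g")],
                   P[key("enc", l, "ln2_b")], c.ln2[l]);
  }
  return X;
}

mat encoder_backward(mat dX, const EncCache& c, const ParamStore& P,
                     const Hyper& h, Dropout& dr, GradStore& G) {
  for (int l = h.n_layers - 1; l >= 0; --l) {
    mat dpre2 = ln_backward(dX, c.ln2[l], P[key("enc", l, "ln2_g")],
                            G.at(key("enc", l, "ln2_g"),
                                 P[key("enc", l, "ln2_g")]),
                            G.at(key("enc", l, "ln2_b"),
                                 P[key("enc", l, "ln2_b")]));
    mat dF = dr.back(dpre2, c.drop_ffn[l]);
    mat dXmid = dpre2 + ffn_backward(dF, c.ffn[l],
                                     P[key("enc", l, "W1")],
                                     P[key("enc", l, "W2")],
                                     G.at(key("enc", l, "W1"),
                                          P[key("enc", l, "W1")]),
                                     G.at(key("enc", l, "b1"),
                                          P[key("enc", l, "b1")]),
                                     G.at(key("enc", l, "W2"),
                                          P[key("enc", l, "W2")]),
                                     G.at(key("enc", l, "b2"),
                                          P[key("enc", l, "b2")]));
    mat dpre1 = ln_backward(dXmid, c.ln1[l], P[key("enc", l, "ln1_g")],
                            G.at(key("enc", l, "ln1_g"),
                                 P[key("enc", l, "ln1_g")]),
                            G.at(key("enc", l, "ln1_b"),
                                 P[key("enc", l, "ln1_b")]));
    mat dA = dr.back(dpre1, c.drop_att[l]);
    mat dXin(dpre1.n_rows, dpre1.n_cols, arma::fill::zeros);
    mat dXkv(dpre1.n_rows, dpre1.n_cols, arma::fill::zeros);
    mha_backward(dA, c.att[l], P[key("enc", l, "Wq")],
                 P[key("enc", l, "Wk")], P[key("enc", l, "Wv")],
                 P[key("enc", l, "Wo")],
                 G.at(key("enc", l, "Wq"), P[key("enc", l, "Wq")]),
                 G.at(key("enc", l, "Wk"), P[key("enc", l, "Wk")]),
                 G.at(key("enc", l, "Wv"), P[key("enc", l, "Wv")]),
                 G.at(key("enc", l, "Wo"), P[key("enc", l, "Wo")]),
                 dXin, dXkv, h.n_heads);
    dX = dpre1 + dXin + dXkv;
  }
  // projection and positional gradients are applied by the caller,
  // which owns the raw feature matrix
  return dr.back(dX, c.drop_in);
}

struct DecCache {
  arma::ivec ids;
  mat drop_in;
  std::vector<MHACache> satt, xatt;
  std::vector<FFNCache> ffn;
  std::vector<LNCache> ln1, ln2, ln3;
  std::vector<mat> pre1, pre2, pre3;
  std::vector<mat> drop1, drop2, drop3;
};

mat decoder_forward(const arma::ivec& ids, const mat& memory,
                    const ParamStore& P, const Hyper& h, Dropout& dr,
                    bool train, DecCache& c, mat& dMem_placeholder) {
  (void)dMem_placeholder;
  int T = ids.n_elem;
  double scale = std::sqrt((double)h.d_model);
  mat Y(T, h.d_model);
  const mat& E = P["dec_emb"];
  for (int t = 0; t < T; ++t) Y.row(t) = E.row(ids[t]) * scale;
  if (h.learned_pos) {
    Y += P["dec_pos"].rows(0, T - 1);
  } else {
    Y += sinusoidal_pe(T, h.d_model);
  }
  if (train) Y = dr.apply(Y, c.drop_in);
  c.ids = ids;
  c.satt.resize(h.n_layers); c.xatt.resize(h.n_layers);
  c.ffn.resize(h.n_layers);
  c.ln1.resize(h.n_layers); c.ln2.resize(h.n_layers); c.ln3.resize(h.n_layers);
  c.pre1.resize(h.n_layers); c.pre2.resize(h.n_layers); c.pre3.resize(h.n_layers);
  c.drop1.resize(h.n_layers); c.drop2.resize(h.n_layers);
  c.drop3.resize(h.n_layers);
  for (int l = 0; l < h.n_layers; ++l) {
    mat S = mha_forward(Y, Y, P[key("dec", l, "sWq")], P[key("dec", l, "sWk")],
                        P[key("dec", l, "sWv")], P[key("dec", l, "sWo")],
                        h.n_heads, true, c.satt[l]);
    if (train) S = dr.apply(S, c.drop1[l]);
    c.pre1[l] = Y + S;
    Y = ln_forward(c.pre1[l], P[key("dec", l, "ln1_g")],
                   P[key("dec", l, "ln1_b")], c.ln1[l]);
    mat X = mha_forward(Y, memory, P[key("dec", l, "cWq")],
                        P[key("dec", l, "cWk")], P[key("dec", l, "cWv")],
                        P[key("dec", l, "cWo")], h.n_heads, false,
                        c.xatt[l]);
    if (train) X = dr.apply(X, c.drop2[l]);
    c.pre2[l] = Y + X;
    Y = ln_forward(c.pre2[l], P[key("dec", l, "ln2_g")],
                   P[key("dec", l, "ln2_b")], c.ln2[l]);
    mat F = ffn_forward(Y, P[key("dec", l, "W1")], P[key("dec", l, "b1")],
                        P[key("dec", l, "W2")], P[key("dec", l, "b2")],
                        c.ffn[l]);
    if (train) F = dr.apply(F, c.drop3[l]);
    c.pre3[l] = Y + F;
    Y = ln_forward(c.pre3[l], P[key("dec", l, "ln3_g")],
                   P[key("dec", l, "ln3_b")], c.ln3[l]);
  }
  return Y;
}

// returns dMemory; accumulates parameter grads
mat decoder_backward(mat dY, const DecCache& c, const ParamStore& P,
                     const Hyper& h, Dropout& dr, GradStore& G,
                     int memory_rows) {
  mat dMem(memory_rows, h.d_model, arma::fill::zeros);
  for (int l = h.n_layers - 1; l >= 0; --l) {
    mat dpre3 = ln_backward(dY, c.ln3[l], P[key("dec", l, "ln3_g")],
                            G.at(key("dec", l, "ln3_g"),
                                 P[key("dec", l, "ln3_g")]),
                            G.at(key("dec", l, "ln3_b"),
                                 P[key("dec", l, "ln3_b")]));
    mat dF = dr.back(dpre3, c.drop3[l]);
    mat dY2 = dpre3 + ffn_backward(dF, c.ffn[l], P[key("dec", l, "W1")],
                                   P[key("dec", l, "W2")],
                                   G.at(key("dec", l, "W1"),
                                        P[key("dec", l, "W1")]),
                                   G.at(key("dec", l, "b1"),
                                        P[key("dec", l, "b1")]),
                                   G.at(key("dec", l, "W2"),
                                        P[key("dec", l, "W2")]),
                                   G.at(key("dec", l, "b2"),
                                        P[key("dec", l, "b2")]));
    mat dpre2 = ln_backward(dY2, c.ln2[l], P[key("dec", l, "ln2_g")],
                            G.at(key("dec", l, "ln2_g"),
                                 P[key("dec", l, "ln2_g")]),
                            G.at(key("dec", l, "ln2_b"),
                                 P[key("dec", l, "ln2_b")]));
    mat dXatt = dr.back(dpre2, c.drop2[l]);
    mat dYq(dpre2.n_rows, h.d_model, arma::fill::zeros);
    mat dM(memory_rows, h.d_model, arma::fill::zeros);
    mha_backward(dXatt, c.xatt[l], P[key("dec", l, "cWq")],
                 P[key("dec", l, "cWk")], P[key("dec", l, "cWv")],
                 P[key("dec", l, "cWo")],
                 G.at(key("dec", l, "cWq"), P[key("dec", l, "cWq")]),
                 G.at(key("dec", l, "cWk"), P[key("dec", l, "cWk")]),
                 G.at(key("dec", l, "cWv"), P[key("dec", l, "cWv")]),
                 G.at(key("dec", l, "cWo"), P[key("dec", l, "cWo")]),
                 dYq, dM, h.n_heads);
    dMem += dM;
    mat dY3 = dpre2 + dYq;
    mat dpre1 = ln_backward(dY3, c.ln1[l], P[key("dec", l, "ln1_g")],
                            G.at(key("dec", l, "ln1_g"),
                                 P[key("dec", l, "ln1_g")]),
                            G.at(key("dec", l, "ln1_b"),
                                 P[key("dec", l, "ln1_b")]));
    mat dS = dr.back(dpre1, c.drop1[l]);
    mat dYs(dpre1.n_rows, h.d_model, arma::fill::zeros);
    mat dYkv(dpre1.n_rows, h.d_model, arma::fill::zeros);
    mha_backward(dS, c.satt[l], P[key("dec", l, "sWq")],
                 P[key("dec", l, "sWk")], P[key("dec", l, "sWv")],
                 P[key("dec", l, "sWo")],
                 G.at(key("dec", l, "sWq"), P[key("dec", l, "sWq")]),
                 G.at(key("dec", l, "sWk"), P[key("dec", l, "sWk")]),
                 G.at(key("dec", l, "sWv"), P[key("dec", l, "sWv")]),
                 G.at(key("dec", l, "sWo"), P[key("dec", l, "sWo")]),
                 dYs, dYkv, h.n_heads);
    dY = dpre1 + dYs + dYkv;
  }
  mat dY0 = dr.back(dY, c.drop_in);
  double scale = std::sqrt((double)h.d_model);
  mat& dE = G.at("dec_emb", P["dec_emb"]);
  for (arma::uword t = 0; t < c.ids.n_elem; ++t) {
    dE.row(c.ids[t]) += dY0.row(t) * scale;
  }
  if (h.learned_pos) {
    G.at("dec_pos", P["dec_pos"]).rows(0, dY0.n_rows - 1) += dY0;
  }
  return dMem;
}

// ---- batched training path --------------------------------------------------
//
// For throughput, the training step stacks the whole batch into single
// (B*T) x d matrices so every projection and FFN runs as one BLAS call;
// only the attention softmax/context runs per (sample, head). Decoder
// sequences are right-padded to the batch maximum; pad positions are
// excluded from attention keys and from the loss, so they contribute
// nothing to either the loss or the gradients.

struct BAttCache {
  mat Xq, Xkv, Q, K, V, ctx;
  std::vector<mat> A;
};

mat bmha_forward(const mat& Xq, const mat& Xkv,
                 const mat& Wq, const mat& Wk, const mat& Wv, const mat& Wo,
                 int B, int Tq, int Tk, const std::vector<int>* klens,
                 bool causal, int n_heads, BAttCache& c) {
  int d = Wq.n_cols, dk = d / n_heads;
  double scl = 1.0 / std::sqrt((double)dk);
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * Wq; c.K = Xkv * Wk; c.V = Xkv * Wv;
  c.ctx.zeros(Xq.n_rows, d);
  c.A.assign((size_t)B * n_heads, mat());
  for (int b = 0; b < B; ++b) {
    int tk = klens ? (*klens)[b] : Tk;
    if (tk <= 0) continue;
    for (int h = 0; h < n_heads; ++h) {
      mat S = c.Q.submat(b * Tq, h * dk, b * Tq + Tq - 1,
                         h * dk + dk - 1) *
              c.K.submat(b * Tk, h * dk, b * Tk + tk - 1,
                         h * dk + dk - 1).t() * scl;
      if (causal) {
        for (int i = 0; i < Tq; ++i)
          for (int j = i + 1; j < tk; ++j) S(i, j) = -1e30;
      }
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      c.A[(size_t)b * n_heads + h] = S;
      c.ctx.submat(b * Tq, h * dk, b * Tq + Tq - 1, h * dk + dk - 1) =
          S * c.V.submat(b * Tk, h * dk, b * Tk + tk - 1, h * dk + dk - 1);
    }
  }
  return c.ctx * Wo;
}

void bmha_backward(const mat& dOut, const BAttCache& c,
                   const mat& Wq, const mat& Wk, const mat& Wv,
                   const mat& Wo,
                   mat& dWq, mat& dWk, mat& dWv, mat& dWo,
                   mat& dXq, mat& dXkv,
                   int B, int Tq, int Tk, const std::vector<int>* klens,
                   int n_heads) {
  int d = Wq.n_cols, dk = d / n_heads;
  double scl = 1.0 / std::sqrt((double)dk);
  dWo += c.ctx.t() * dOut;
  mat dctx = dOut * Wo.t();
  mat dQ(c.Q.n_rows, d, arma::fill::zeros);
  mat dK(c.K.n_rows, d, arma::fill::zeros);
  mat dV(c.V.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    int tk = klens ? (*klens)[b] : Tk;
    if (tk <= 0) continue;
    for (int h = 0; h < n_heads; ++h) {
      const mat& A = c.A[(size_t)b * n_heads + h];
      mat dctx_b = dctx.submat(b * Tq, h * dk, b * Tq + Tq - 1,
                               h * dk + dk - 1);
      mat dA = dctx_b * c.V.submat(b * Tk, h * dk, b * Tk + tk - 1,
                                   h * dk + dk - 1).t();
      dV.submat(b * Tk, h * dk, b * Tk + tk - 1, h * dk + dk - 1) =
          A.t() * dctx_b;
      mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
      dQ.submat(b * Tq, h * dk, b * Tq + Tq - 1, h * dk + dk - 1) =
          dS * c.K.submat(b * Tk, h * dk, b * Tk + tk - 1,
                          h * dk + dk - 1) * scl;
      dK.submat(b * Tk, h * dk, b * Tk + tk - 1, h * dk + dk - 1) =
          dS.t() * c.Q.submat(b * Tq, h * dk, b * Tq + Tq - 1,
                              h * dk + dk - 1) * scl;
    }
  }
  dWq += c.Xq.t() * dQ;
  dWk += c.Xkv.t() * dK;
  dWv += c.Xkv.t() * dV;
  dXq += dQ * Wq.t();
  dXkv += dK * Wk.t() + dV * Wv.t();
}

struct BEncCache {
  mat X0, drop_in;
  std::vector<BAttCache> att;
  std::vector<FFNCache> ffn;
  std::vector<LNCache> ln1, ln2;
  std::vector<mat> pre_ln1, pre_ln2, drop_att, drop_ffn;
};

mat bencoder_forward(const mat& fstack, const ParamStore& P, const Hyper& h,
                     int B, int Pn, Dropout& dr, bool train, BEncCache& c) {
  mat X = fstack * P["enc_proj_W"];
  X.each_row() += P["enc_proj_b"].row(0);
  mat pe = h.learned_pos ? mat(P["enc_pos"].rows(0, Pn - 1))
                         : sinusoidal_pe(Pn, h.d_model);
  for (int b = 0; b < B; ++b) X.rows(b * Pn, (b + 1) * Pn - 1) += pe;
  if (train) X = dr.apply(X, c.drop_in);
  c.X0 = X;
  c.att.resize(h.n_layers); c.ffn.resize(h.n_layers);
  c.ln1.resize(h.n_layers); c.ln2.resize(h.n_layers);
  c.pre_ln1.resize(h.n_layers); c.pre_ln2.resize(h.n_layers);
  c.drop_att.resize(h.n_layers); c.drop_ffn.resize(h.n_layers);
  for (int l = 0; l < h.n_layers; ++l) {
    mat A = bmha_forward(X, X, P[key("enc", l, "Wq")],
                         P[key("enc", l, "Wk")], P[key("enc", l, "Wv")],
                         P[key("enc", l, "Wo")], B, Pn, Pn, nullptr,
                         false, h.n_heads, c.att[l]);
    if (train) A = dr.apply(A, c.drop_att[l]);
    c.pre_ln1[l] = X + A;
    X = ln_forward(c.pre_ln1[l], P[key("enc", l, "ln1_g")],
                   P[key("enc", l, "ln1_b")], c.ln1[l]);
    mat F = ffn_forward(X, P[key("enc", l, "W1")], P[key("enc", l, "b1")],
                        P[key("enc", l, "W2")], P[key("enc", l, "b2")],
                        c.ffn[l]);
    if (train) F = dr.apply(F, c.drop_ffn[l]);
    c.pre_ln2[l] = X + F;
    X = ln_forward(c.pre_ln2[l], P[key("enc", l, "ln2_g")],
                   P[key("enc", l, "ln2_b")], c.ln2[l]);
  }
  return X;
}

mat bencoder_backward(mat dX, const BEncCache& c, const ParamStore& P,
                      const Hyper& h, int B, int Pn, Dropout& dr,
                      GradStore& G) {
  for (int l = h.n_layers - 1; l >= 0; --l) {
    mat dpre2 = ln_backward(dX, c.ln2[l], P[key("enc", l, "ln2_g")],
                            G.at(key("enc", l, "ln2_g"),
                                 P[key("enc", l, "ln2_g")]),
                            G.at(key("enc", l, "ln2_b"),
                                 P[key("enc", l, "ln2_b")]));
    mat dF = dr.back(dpre2, c.drop_ffn[l]);
    mat dXmid = dpre2 +
        ffn_backward(dF, c.ffn[l], P[key("enc", l, "W1")],
                     P[key("enc", l, "W2")],
                     G.at(key("enc", l, "W1"), P[key("enc", l, "W1")]),
                     G.at(key("enc", l, "b1"), P[key("enc", l, "b1")]),
                     G.at(key("enc", l, "W2"), P[key("enc", l, "W2")]),
                     G.at(key("enc", l, "b2"), P[key("enc", l, "b2")]));
    mat dpre1 = ln_backward(dXmid, c.ln1[l], P[key("enc", l, "ln1_g")],
                            G.at(key("enc", l, "ln1_g"),
                                 P[key("enc", l, "ln1_g")]),
                            G.at(key("enc", l, "ln1_b"),
                                 P[key("enc", l, "ln1_b")]));
    mat dA = dr.back(dpre1, c.drop_att[l]);
    mat dXq(dpre1.n_rows, dpre1.n_cols, arma::fill::zeros);
    mat dXkv(dpre1.n_rows, dpre1.n_cols, arma::fill::zeros);
    bmha_backward(dA, c.att[l], P[key("enc", l, "Wq")],
                  P[key("enc", l, "Wk")], P[key("enc", l, "Wv")],
                  P[key("enc", l, "Wo")],
                  G.at(key("enc", l, "Wq"), P[key("enc", l, "Wq")]),
                  G.at(key("enc", l, "Wk"), P[key("enc", l, "Wk")]),
                  G.at(key("enc", l, "Wv"), P[key("enc", l, "Wv")]),
                  G.at(key("enc", l, "Wo"), P[key("enc", l, "Wo")]),
                  dXq, dXkv, B, Pn, Pn, nullptr, h.n_heads);
    dX = dpre1 + dXq + dXkv;
  }
  return dr.back(dX, c.drop_in);
}

struct BDecCache {
  std::vector<int> ids;   // stacked, pad-filled
  mat drop_in;
  std::vector<BAttCache> satt, xatt;
  std::vector<FFNCache> ffn;
  std::vector<LNCache> ln1, ln2, ln3;
  std::vector<mat> pre1, pre2, pre3, drop1, drop2, drop3;
};

mat bdecoder_forward(const std::vector<int>& ids, const mat& memory,
                     const ParamStore& P, const Hyper& h,
                     int B, int T, int Pn, const std::vector<int>& lens,
                     Dropout& dr, bool train, BDecCache& c) {
  double scale = std::sqrt((double)h.d_model);
  const mat& E = P["dec_emb"];
  mat Y((size_t)B * T, h.d_model);
  for (int i = 0; i < B * T; ++i) Y.row(i) = E.row(ids[i]) * scale;
  mat pe = h.learned_pos ? mat(P["dec_pos"].rows(0, T - 1))
                         : sinusoidal_pe(T, h.d_model);
  for (int b = 0; b < B; ++b) Y.rows(b * T, (b + 1) * T - 1) += pe;
  if (train) Y = dr.apply(Y, c.drop_in);
  c.ids = ids;
  c.satt.resize(h.n_layers); c.xatt.resize(h.n_layers);
  c.ffn.resize(h.n_layers);
  c.ln1.resize(h.n_layers); c.ln2.resize(h.n_layers);
  c.ln3.resize(h.n_layers);
  c.pre1.resize(h.n_layers); c.pre2.resize(h.n_layers);
  c.pre3.resize(h.n_layers);
  c.drop1.resize(h.n_layers); c.drop2.resize(h.n_layers);
  c.drop3.resize(h.n_layers);
  for (int l = 0; l < h.n_layers; ++l) {
    mat S = bmha_forward(Y, Y, P[key("dec", l, "sWq")],
                         P[key("dec", l, "sWk")], P[key("dec", l, "sWv")],
                         P[key("dec", l, "sWo")], B, T, T, &lens, true,
                         h.n_heads, c.satt[l]);
    if (train) S = dr.apply(S, c.drop1[l]);
    c.pre1[l] = Y + S;
    Y = ln_forward(c.pre1[l], P[key("dec", l, "ln1_g")],
                   P[key("dec", l, "ln1_b")], c.ln1[l]);
    mat X = bmha_forward(Y, memory, P[key("dec", l, "cWq")],
                         P[key("dec", l, "cWk")], P[key("dec", l, "cWv")],
                         P[key("dec", l, "cWo")], B, T, Pn, nullptr, false,
                         h.n_heads, c.xatt[l]);
    if (train) X = dr.apply(X, c.drop2[l]);
    c.pre2[l] = Y + X;
    Y = ln_forward(c.pre2[l], P[key("dec", l, "ln2_g")],
                   P[key("dec", l, "ln2_b")], c.ln2[l]);
    mat F = ffn_forward(Y, P[key("dec", l, "W1")], P[key("dec", l, "b1")],
                        P[key("dec", l, "W2")], P[key("dec", l, "b2")],
                        c.ffn[l]);
    if (train) F = dr.apply(F, c.drop3[l]);
    c.pre3[l] = Y + F;
    Y = ln_forward(c.pre3[l], P[key("dec", l, "ln3_g")],
                   P[key("dec", l, "ln3_b")], c.ln3[l]);
  }
  return Y;
}

mat bdecoder_backward(mat dY, const BDecCache& c, const ParamStore& P,
                      const Hyper& h, int B, int T, int Pn,
                      const std::vector<int>& lens, Dropout& dr,
                      GradStore& G) {
  mat dMem((size_t)B * Pn, h.d_model, arma::fill::zeros);
  for (int l = h.n_layers - 1; l >= 0; --l) {
    mat dpre3 = ln_backward(dY, c.ln3[l], P[key("dec", l, "ln3_g")],
                            G.at(key("dec", l, "ln3_g"),
                                 P[key("dec", l, "ln3_g")]),
                            G.at(key("dec", l, "ln3_b"),
                                 P[key("dec", l, "ln3_b")]));
    mat dF = dr.back(dpre3, c.drop3[l]);
    mat dY2 = dpre3 +
        ffn_backward(dF, c.ffn[l], P[key("dec", l, "W1")],
                     P[key("dec", l, "W2")],
                     G.at(key("dec", l, "W1"), P[key("dec", l, "W1")]),
                     G.at(key("dec", l, "b1"), P[key("dec", l, "b1")]),
                     G.at(key("dec", l, "W2"), P[key("dec", l, "W2")]),
                     G.at(key("dec", l, "b2"), P[key("dec", l, "b2")]));
    mat dpre2 = ln_backward(dY2, c.ln2[l], P[key("dec", l, "ln2_g")],
                            G.at(key("dec", l, "ln2_g"),
                                 P[key("dec", l, "ln2_g")]),
                            G.at(key("dec", l, "ln2_b"),
                                 P[key("dec", l, "ln2_b")]));
    mat dXatt = dr.back(dpre2, c.drop2[l]);
    mat dYq(dpre2.n_rows, h.d_model, arma::fill::zeros);
    bmha_backward(dXatt, c.xatt[l], P[key("dec", l, "cWq")],
                  P[key("dec", l, "cWk")], P[key("dec", l, "cWv")],
                  P[key("dec", l, "cWo")],
                  G.at(key("dec", l, "cWq"), P[key("dec", l, "cWq")]),
                  G.at(key("dec", l, "cWk"), P[key("dec", l, "cWk")]),
                  G.at(key("dec", l, "cWv"), P[key("dec", l, "cWv")]),
                  G.at(key("dec", l, "cWo"), P[key("dec", l, "cWo")]),
                  dYq, dMem, B, T, Pn, nullptr, h.n_heads);
    mat dY3 = dpre2 + dYq;
    mat dpre1 = ln_backward(dY3, c.ln1[l], P[key("dec", l, "ln1_g")],
                            G.at(key("dec", l, "ln1_g"),
                                 P[key("dec", l, "ln1_g")]),
                            G.at(key("dec", l, "ln1_b"),
                                 P[key("dec", l, "ln1_b")]));
    mat dS = dr.back(dpre1, c.drop1[l]);
    mat dYs(dpre1.n_rows, h.d_model, arma::fill::zeros);
    mat dYkv(dpre1.n_rows, h.d_model, arma::fill::zeros);
    bmha_backward(dS, c.satt[l], P[key("dec", l, "sWq")],
                  P[key("dec", l, "sWk")], P[key("dec", l, "sWv")],
                  P[key("dec", l, "sWo")],
                  G.at(key("dec", l, "sWq"), P[key("dec", l, "sWq")]),
                  G.at(key("dec", l, "sWk"), P[key("dec", l, "sWk")]),
                  G.at(key("dec", l, "sWv"), P[key("dec", l, "sWv")]),
                  G.at(key("dec", l, "sWo"), P[key("dec", l, "sWo")]),
                  dYs, dYkv, B, T, T, &lens, h.n_heads);
    dY = dpre1 + dYs + dYkv;
  }
  mat dY0 = dr.back(dY, c.drop_in);
  double scale = std::sqrt((double)h.d_model);
  mat& dE = G.at("dec_emb", P["dec_emb"]);
  for (int i = 0; i < (int)c.ids.size(); ++i) {
    dE.row(c.ids[i]) += dY0.row(i) * scale;
  }
  if (h.learned_pos) {
    mat& dPos = G.at("dec_pos", P["dec_pos"]);
    int B2 = dY0.n_rows / T;
    for (int b = 0; b < B2; ++b) {
      dPos.rows(0, T - 1) += dY0.rows(b * T, (b + 1) * T - 1);
    }
  }
  return dMem;
}

}  // namespace

// Training step gradient: mean masked cross-entropy over the batch and
// parameter gradients. feats: list of (positions x channels) matrices;
// tokens: B x max_len integer matrix of padded id sequences.
// [[Rcpp::export]]
List tf_batch_grad(List params, List cfg, List feats, IntegerMatrix tokens,
                   double dropout_p, int seed, bool want_grads = true) {
  Hyper h = read_hyper(cfg);
  h.dropout = dropout_p;
  ParamStore P = read_params(params);
  GradStore G;
  std::mt19937_64 rng((unsigned long long)seed);
  Dropout dr{&rng, dropout_p};
  int B = feats.size();
  long n_tok = 0;
  std::vector<int> lens(B);
  for (int b = 0; b < B; ++b) {
    IntegerMatrix::Row row = tokens(b, _);
    int last = row.size() - 1;
    while (last > 0 && row[last] == h.pad_id) --last;
    lens[b] = last;            // inputs 0..last-1 predict targets 1..last
    n_tok += last;
  }
  if (n_tok == 0) stop("batch contains no target tokens");
  int T = *std::max_element(lens.begin(), lens.end());
  std::vector<int> ids((size_t)B * T, h.pad_id), tg((size_t)B * T,
                                                    h.pad_id);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < lens[b]; ++t) {
      ids[(size_t)b * T + t] = tokens(b, t);
      tg[(size_t)b * T + t] = tokens(b, t + 1);
    }
  }
  // stack features
  mat f0 = as<mat>(feats[0]);
  int Pn = f0.n_rows, Cn = f0.n_cols;
  mat fstack((size_t)B * Pn, Cn);
  fstack.rows(0, Pn - 1) = f0;
  for (int b = 1; b < B; ++b) {
    fstack.rows((size_t)b * Pn, (size_t)(b + 1) * Pn - 1) =
        as<mat>(feats[b]);
  }
  bool train = want_grads || dropout_p > 0;
  BEncCache ec;
  mat memory = bencoder_forward(fstack, P, h, B, Pn, dr, train, ec);
  BDecCache dc;
  mat Y = bdecoder_forward(ids, memory, P, h, B, T, Pn, lens, dr, train,
                           dc);
  mat logits = Y * P["out_W"];
  logits.each_row() += P["out_b"].row(0);
  mat sm = logits;
  sm.each_col() -= arma::max(sm, 1);
  sm = arma::exp(sm);
  sm.each_col() /= arma::sum(sm, 1);
  double loss_sum = 0.0;
  mat dlogits;
  if (want_grads) dlogits.zeros(sm.n_rows, sm.n_cols);
  for (size_t i = 0; i < tg.size(); ++i) {
    int y = tg[i];
    if (y == h.pad_id) continue;
    loss_sum += -std::log(std::max(sm(i, y), 1e-300));
    if (want_grads) {
      dlogits.row(i) = sm.row(i) / (double)n_tok;
      dlogits(i, y) -= 1.0 / (double)n_tok;
    }
  }
  if (want_grads) {
    G.at("out_W", P["out_W"]) += Y.t() * dlogits;
    G.at("out_b", P["out_b"]).row(0) += arma::sum(dlogits, 0);
    mat dY = dlogits * P["out_W"].t();
    mat dMem = bdecoder_backward(dY, dc, P, h, B, T, Pn, lens, dr, G);
    mat dX0 = bencoder_backward(dMem, ec, P, h, B, Pn, dr, G);
    G.at("enc_proj_W", P["enc_proj_W"]) += fstack.t() * dX0;
    G.at("enc_proj_b", P["enc_proj_b"]).row(0) += arma::sum(dX0, 0);
    if (h.learned_pos) {
      mat& dPos = G.at("enc_pos", P["enc_pos"]);
      for (int b = 0; b < B; ++b) {
        dPos.rows(0, Pn - 1) += dX0.rows((size_t)b * Pn,
                                         (size_t)(b + 1) * Pn - 1);
      }
    }
  }
  List out;
  out["loss"] = loss_sum / (double)n_tok;
  out["n_tokens"] = (double)n_tok;
  if (want_grads) {
    List gl;
    for (auto& kv : G.g) gl[kv.first] = wrap(kv.second);
    out["grads"] = gl;
  }
  return out;
}

// Greedy decoding: argmax token per step until <end> or max_len.
// Returns a B x (max_len) integer matrix padded with pad_id; sequences
// include neither the start nor the end marker.
// [[Rcpp::export]]
IntegerMatrix tf_greedy_decode(List params, List cfg, List feats,
                               int max_len) {
  Hyper h = read_hyper(cfg);
  ParamStore P = read_params(params);
  std::mt19937_64 rng(0);
  Dropout dr{&rng, 0.0};
  int B = feats.size();
  IntegerMatrix out(B, max_len);
  std::fill(out.begin(), out.end(), h.pad_id);
  for (int b = 0; b < B; ++b) {
    mat f = as<mat>(feats[b]);
    EncCache ec;
    mat memory = encoder_forward(f, P, h, dr, false, ec);
    std::vector<int> ids{h.start_id};
    for (int step = 0; step < max_len; ++step) {
      arma::ivec in(ids.size());
      for (size_t t = 0; t < ids.size(); ++t) in[t] = ids[t];
      DecCache dc;
      mat dummy;
      mat Y = decoder_forward(in, memory, P, h, dr, false, dc, dummy);
      rowvec logits = Y.row(Y.n_rows - 1) * P["out_W"];
      logits += P["out_b"].row(0);
      int nxt = logits.index_max();
      if (nxt == h.end_id) break;
      out(b, step) = nxt;
      ids.push_back(nxt);
      if ((int)ids.size() >= max_len) break;
    }
  }
  return out;
}

// Per-position logits for one sample (diagnostics: causality checks).
// [[Rcpp::export]]
NumericMatrix tf_logits(List params, List cfg, NumericMatrix feats,
                        IntegerVector ids_in) {
  Hyper h = read_hyper(cfg);
  ParamStore P = read_params(params);
  std::mt19937_64 rng(0);
  Dropout dr{&rng, 0.0};
  EncCache ec;
  mat memory = encoder_forward(as<mat>(feats), P, h, dr, false, ec);
  arma::ivec in(ids_in.size());
  for (int t = 0; t < ids_in.size(); ++t) in[t] = ids_in[t];
  DecCache dc;
  mat dummy;
  mat Y = decoder_forward(in, memory, P, h, dr, false, dc, dummy);
  mat logits = Y * P["out_W"];
  logits.each_row() += P["out_b"].row(0);
  return wrap(logits);
}
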