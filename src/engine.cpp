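// Training engine: cross-modal transformer feature extractor + adversarial
// learning-classifying heads, with hand-written backpropagation.
//
// Layout conventions: sequences are [time, feature] matrices. The training
// path stacks a whole minibatch as large row-block matrices so that
// projections, layer norms, feed-forward blocks and convolutions each run
// as one large GEMM; only the scaled dot-product attention cores loop over
// row blocks (one block per trial and, in the encoder, per modality). The
// training path computes in single precision (the attention score matrices
// are memory-bandwidth bound; fp32 rounding is far below the SGD noise
// floor), while the small exported reference kernels used as test oracles
// compute in double precision. All label vectors arriving here are 0-based.
//
// Parameters travel as a flat named R list ("proj.1.W", "cross.Wq",
// "enc.2.W1", "conv.1.K2", "emo_head.W2", ...); gradients are returned under
// identical names so the R-side optimizer can walk them generically.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>
#include <cstring>
#include <cstdint>
#ifdef __GLIBC__
#include <malloc.h>
// the training loop allocates and frees many large activation buffers per
// step; keeping them on the heap free-lists (instead of mmap/munmap round
// trips) avoids re-faulting the same pages thousands of times
struct MallocTuning {
  MallocTuning() {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
  }
};
static MallocTuning malloc_tuning_;
#endif

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float LN_EPS = 1e-5f;

// ---------------------------------------------------------------- config ---

struct Cfg {
  int D, H, U, Dff, C, emo_hidden, head_hidden;
  bool cross;
  float dropout;
};

static Cfg read_cfg(const List& config) {
  Cfg c;
  c.D = Rcpp::as<int>(config["model_dim"]);
  c.H = Rcpp::as<int>(config["n_heads"]);
  c.U = Rcpp::as<int>(config["n_layers"]);
  c.Dff = Rcpp::as<int>(config["ffn_mult"]) * c.D;
  c.C = Rcpp::as<int>(config["conv_channels"]);
  c.emo_hidden = Rcpp::as<int>(config["emo_hidden"]);
  c.head_hidden = Rcpp::as<int>(config["head_hidden"]);
  c.cross = Rcpp::as<bool>(config["cross_attention"]);
  c.dropout = (float)Rcpp::as<double>(config["dropout"]);
  return c;
}

// ------------------------------------------------------------- parameters ---

struct EncP {
  fvec ln1g, ln1b, ln2g, ln2b, b1, b2;
  fmat Wqkv, Wo, W1, W2;  // Wqkv = [Wq | Wk | Wv], D x 3D
};
struct ConvP { fmat K1, K2; fvec b1, b2, g1, be1, g2, be2; };

struct Params {
  std::vector<fmat> projW; std::vector<fvec> projb;
  fmat cWq, cWk, cWv, cWo; fvec clnqg, clnqb, clncg, clncb;
  std::vector<EncP> enc;
  std::vector<ConvP> conv;
  fmat mW1, mW2, sW1, sW2, eW1, eW2;
  fvec mb1, mb2, sb1, sb2, eb1, eb2;
  bool has_sub = false;
};

static fmat Pm_(const List& p, const std::string& k) {
  return conv_to<fmat>::from(Rcpp::as<mat>(p[k.c_str()]));
}
static fvec Pv_(const List& p, const std::string& k) {
  return conv_to<fvec>::from(Rcpp::as<vec>(p[k.c_str()]));
}
static bool has_(const List& p, const std::string& k) {
  return p.containsElementNamed(k.c_str());
}

static Params read_params(const List& p, const Cfg& cfg, int M) {
  Params P;
  for (int i = 0; i < M; ++i) {
    std::string b = "proj." + std::to_string(i + 1) + ".";
    P.projW.push_back(Pm_(p, b + "W"));
    P.projb.push_back(Pv_(p, b + "b"));
  }
  if (cfg.cross) {
    P.cWq = Pm_(p, "cross.Wq"); P.cWk = Pm_(p, "cross.Wk");
    P.cWv = Pm_(p, "cross.Wv"); P.cWo = Pm_(p, "cross.Wo");
    P.clnqg = Pv_(p, "cross.lnq_g"); P.clnqb = Pv_(p, "cross.lnq_b");
    P.clncg = Pv_(p, "cross.lnc_g"); P.clncb = Pv_(p, "cross.lnc_b");
  }
  for (int l = 0; l < cfg.U; ++l) {
    std::string b = "enc." + std::to_string(l + 1) + ".";
    EncP e;
    e.ln1g = Pv_(p, b + "ln1_g"); e.ln1b = Pv_(p, b + "ln1_b");
    e.ln2g = Pv_(p, b + "ln2_g"); e.ln2b = Pv_(p, b + "ln2_b");
    e.Wqkv = join_rows(Pm_(p, b + "Wq"), Pm_(p, b + "Wk"), Pm_(p, b + "Wv"));
    e.Wo = Pm_(p, b + "Wo");
    e.W1 = Pm_(p, b + "W1"); e.b1 = Pv_(p, b + "b1");
    e.W2 = Pm_(p, b + "W2"); e.b2 = Pv_(p, b + "b2");
    P.enc.push_back(e);
  }
  for (int i = 0; i < M; ++i) {
    std::string b = "conv." + std::to_string(i + 1) + ".";
    ConvP c;
    c.K1 = Pm_(p, b + "K1"); c.b1 = Pv_(p, b + "b1");
    c.g1 = Pv_(p, b + "g1"); c.be1 = Pv_(p, b + "be1");
    c.K2 = Pm_(p, b + "K2"); c.b2 = Pv_(p, b + "b2");
    c.g2 = Pv_(p, b + "g2"); c.be2 = Pv_(p, b + "be2");
    P.conv.push_back(c);
  }
  P.mW1 = Pm_(p, "mod_head.W1"); P.mb1 = Pv_(p, "mod_head.b1");
  P.mW2 = Pm_(p, "mod_head.W2"); P.mb2 = Pv_(p, "mod_head.b2");
  P.eW1 = Pm_(p, "emo_head.W1"); P.eb1 = Pv_(p, "emo_head.b1");
  P.eW2 = Pm_(p, "emo_head.W2"); P.eb2 = Pv_(p, "emo_head.b2");
  if (has_(p, "sub_head.W1")) {
    P.has_sub = true;
    P.sW1 = Pm_(p, "sub_head.W1"); P.sb1 = Pv_(p, "sub_head.b1");
    P.sW2 = Pm_(p, "sub_head.W2"); P.sb2 = Pv_(p, "sub_head.b2");
  }
  return P;
}

struct Grads {
  std::vector<fmat> projW; std::vector<fvec> projb;
  fmat cWq, cWk, cWv, cWo; fvec clnqg, clnqb, clncg, clncb;
  std::vector<EncP> enc;
  std::vector<ConvP> conv;
  fmat mW1, mW2, sW1, sW2, eW1, eW2;
  fvec mb1, mb2, sb1, sb2, eb1, eb2;

  static Grads like(const Params& P) {
    Grads g;
    for (size_t i = 0; i < P.projW.size(); ++i) {
      g.projW.push_back(zeros<fmat>(size(P.projW[i])));
      g.projb.push_back(zeros<fvec>(P.projb[i].n_elem));
    }
    if (P.cWq.n_elem) {
      g.cWq = zeros<fmat>(size(P.cWq)); g.cWk = zeros<fmat>(size(P.cWk));
      g.cWv = zeros<fmat>(size(P.cWv)); g.cWo = zeros<fmat>(size(P.cWo));
      g.clnqg = zeros<fvec>(P.clnqg.n_elem); g.clnqb = zeros<fvec>(P.clnqb.n_elem);
      g.clncg = zeros<fvec>(P.clncg.n_elem); g.clncb = zeros<fvec>(P.clncb.n_elem);
    }
    for (const EncP& e : P.enc) {
      EncP z;
      z.ln1g = zeros<fvec>(e.ln1g.n_elem); z.ln1b = zeros<fvec>(e.ln1b.n_elem);
      z.ln2g = zeros<fvec>(e.ln2g.n_elem); z.ln2b = zeros<fvec>(e.ln2b.n_elem);
      z.Wqkv = zeros<fmat>(size(e.Wqkv)); z.Wo = zeros<fmat>(size(e.Wo));
      z.W1 = zeros<fmat>(size(e.W1)); z.b1 = zeros<fvec>(e.b1.n_elem);
      z.W2 = zeros<fmat>(size(e.W2)); z.b2 = zeros<fvec>(e.b2.n_elem);
      g.enc.push_back(z);
    }
    for (const ConvP& c : P.conv) {
      ConvP z;
      z.K1 = zeros<fmat>(size(c.K1)); z.b1 = zeros<fvec>(c.b1.n_elem);
      z.g1 = zeros<fvec>(c.g1.n_elem); z.be1 = zeros<fvec>(c.be1.n_elem);
      z.K2 = zeros<fmat>(size(c.K2)); z.b2 = zeros<fvec>(c.b2.n_elem);
      z.g2 = zeros<fvec>(c.g2.n_elem); z.be2 = zeros<fvec>(c.be2.n_elem);
      g.conv.push_back(z);
    }
    g.mW1 = zeros<fmat>(size(P.mW1)); g.mb1 = zeros<fvec>(P.mb1.n_elem);
    g.mW2 = zeros<fmat>(size(P.mW2)); g.mb2 = zeros<fvec>(P.mb2.n_elem);
    g.eW1 = zeros<fmat>(size(P.eW1)); g.eb1 = zeros<fvec>(P.eb1.n_elem);
    g.eW2 = zeros<fmat>(size(P.eW2)); g.eb2 = zeros<fvec>(P.eb2.n_elem);
    if (P.has_sub) {
      g.sW1 = zeros<fmat>(size(P.sW1)); g.sb1 = zeros<fvec>(P.sb1.n_elem);
      g.sW2 = zeros<fmat>(size(P.sW2)); g.sb2 = zeros<fvec>(P.sb2.n_elem);
    }
    return g;
  }

  List to_list(const Cfg& cfg, int M, bool has_sub) const {
    List out;
    auto M_ = [](const fmat& x) { return conv_to<mat>::from(x); };
    auto V_ = [](const fvec& x) { return conv_to<vec>::from(x); };
    for (int i = 0; i < M; ++i) {
      std::string b = "proj." + std::to_string(i + 1) + ".";
      out[b + "W"] = M_(projW[i]); out[b + "b"] = V_(projb[i]);
    }
    if (cfg.cross) {
      out["cross.Wq"] = M_(cWq); out["cross.Wk"] = M_(cWk);
      out["cross.Wv"] = M_(cWv); out["cross.Wo"] = M_(cWo);
      out["cross.lnq_g"] = V_(clnqg); out["cross.lnq_b"] = V_(clnqb);
      out["cross.lnc_g"] = V_(clncg); out["cross.lnc_b"] = V_(clncb);
    }
    for (int l = 0; l < cfg.U; ++l) {
      std::string b = "enc." + std::to_string(l + 1) + ".";
      const EncP& e = enc[l];
      out[b + "ln1_g"] = V_(e.ln1g); out[b + "ln1_b"] = V_(e.ln1b);
      out[b + "ln2_g"] = V_(e.ln2g); out[b + "ln2_b"] = V_(e.ln2b);
      out[b + "Wq"] = M_(e.Wqkv.cols(0, cfg.D - 1));
      out[b + "Wk"] = M_(e.Wqkv.cols(cfg.D, 2 * cfg.D - 1));
      out[b + "Wv"] = M_(e.Wqkv.cols(2 * cfg.D, 3 * cfg.D - 1));
      out[b + "Wo"] = M_(e.Wo);
      out[b + "W1"] = M_(e.W1); out[b + "b1"] = V_(e.b1);
      out[b + "W2"] = M_(e.W2); out[b + "b2"] = V_(e.b2);
    }
    for (int i = 0; i < M; ++i) {
      std::string b = "conv." + std::to_string(i + 1) + ".";
      const ConvP& c = conv[i];
      out[b + "K1"] = M_(c.K1); out[b + "b1"] = V_(c.b1);
      out[b + "g1"] = V_(c.g1); out[b + "be1"] = V_(c.be1);
      out[b + "K2"] = M_(c.K2); out[b + "b2"] = V_(c.b2);
      out[b + "g2"] = V_(c.g2); out[b + "be2"] = V_(c.be2);
    }
    out["mod_head.W1"] = M_(mW1); out["mod_head.b1"] = V_(mb1);
    out["mod_head.W2"] = M_(mW2); out["mod_head.b2"] = V_(mb2);
    if (has_sub) {
      out["sub_head.W1"] = M_(sW1); out["sub_head.b1"] = V_(sb1);
      out["sub_head.W2"] = M_(sW2); out["sub_head.b2"] = V_(sb2);
    }
    out["emo_head.W1"] = M_(eW1); out["emo_head.b1"] = V_(eb1);
    out["emo_head.W2"] = M_(eW2); out["emo_head.b2"] = V_(eb2);
    return out;
  }
};

// ------------------------------------------------------------- primitives ---

// branchless single-precision exp for softmax/tanh inner loops; arguments
// are clamped to [-80, 80], plenty for post-max-subtraction scores
static inline float fexpf_(float x) {
  x = x < -80.0f ? -80.0f : (x > 80.0f ? 80.0f : x);
  // round-to-nearest via the float magic-number trick (vectorizable)
  const float t = x * 1.4426950408889634f + 12582912.0f;
  const float k = t - 12582912.0f;
  const float r = x - k * 0.6931471805599453f;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.16666667f + r *
            (0.041666667f + r * (0.0083333333f + r * 0.0013888889f)))));
  const int32_t bits = ((int32_t)k + 127) << 23;  // 2^k via exponent bits
  float two_k;
  std::memcpy(&two_k, &bits, sizeof(two_k));
  return p * two_k;
}
// Pade 7/6 approximant of tanh; relative error ~1e-7 on the unclamped range
static inline float ftanhf(float x) {
  if (x > 4.97f) return 1.0f;
  if (x < -4.97f) return -1.0f;
  const float x2 = x * x;
  const float p = x * (135135.0f + x2 * (17325.0f + x2 * (378.0f + x2)));
  const float q = 135135.0f + x2 * (62370.0f + x2 * (3150.0f + x2 * 28.0f));
  return p / q;
}

// small fast counter-free RNG for dropout masks (xorshift128+, seeded via
// splitmix64); quality is ample for Bernoulli masks and it is several times
// faster than the Mersenne twister at these volumes
struct Drop {
  uint64_t s0 = 1, s1 = 2;
  float p = 0.0f;
  bool active = false;
  bool on() const { return active && p > 0.0f; }
  void seed(uint64_t x) {
    auto sm = [&x]() {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
    if (!(s0 | s1)) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    s0 = b;
    a ^= a << 23;
    s1 = a ^ b ^ (a >> 17) ^ (b >> 26);
    return s1 + b;
  }
  fmat mask(uword r, uword c) {
    fmat m(r, c);
    const double keep = 1.0 - (double)p;
    const float inv = 1.0f / (float)keep;
    float* v = m.memptr();
    for (uword i = 0; i < r * c; ++i) {
      const double u = (next() >> 11) * (1.0 / 9007199254740992.0);
      v[i] = (u < keep) ? inv : 0.0f;
    }
    return m;
  }
};

struct LNCache { fmat xhat; fvec inv; };

static fmat ln_fwd(const fmat& X, const fvec& g, const fvec& b, LNCache& c) {
  const float Dd = (float)X.n_cols;
  fvec mu = sum(X, 1) / Dd;
  fmat Xc = X.each_col() - mu;
  fvec v = sum(square(Xc), 1) / Dd;
  c.inv = 1.0f / sqrt(v + LN_EPS);
  c.xhat = Xc.each_col() % c.inv;
  fmat Y = c.xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Y;
}

static fmat ln_bwd(const fmat& dY, const fvec& g, const LNCache& c,
                   fvec& dg, fvec& db) {
  dg += sum(dY % c.xhat, 0).t();
  db += sum(dY, 0).t();
  fmat dxh = dY.each_row() % g.t();
  const float Dd = (float)dY.n_cols;
  fvec m1 = sum(dxh, 1) / Dd;
  fvec m2 = sum(dxh % c.xhat, 1) / Dd;
  fmat dX = (dxh.each_col() - m1) - (c.xhat.each_col() % m2);
  dX.each_col() %= c.inv;
  return dX;
}

// in-place softmax over each column (contiguous memory)
static void softmax_cols_inplace(fmat& S) {
  const uword R = S.n_rows, C = S.n_cols;
  for (uword j = 0; j < C; ++j) {
    float* col = S.colptr(j);
    float mx = col[0];
    for (uword i = 1; i < R; ++i) if (col[i] > mx) mx = col[i];
    float sm = 0.0f;
    for (uword i = 0; i < R; ++i) { col[i] = fexpf_(col[i] - mx); sm += col[i]; }
    const float inv = 1.0f / sm;
    for (uword i = 0; i < R; ++i) col[i] *= inv;
  }
}

// Generic row-block attention. Block b uses query rows
// [q0[b], q0[b]+Lq[b]) of Q and key/value rows [k0[b], k0[b]+Lk[b]) of K/V.
// Score/probability matrices are held TRANSPOSED ([Lk, Lq], one column per
// query) so the softmax and its backward pass sweep contiguous memory; they
// are kept per (block, head) for the backward pass. The 1/sqrt(d_head)
// scale is expected to be folded into Q by the caller.
struct AttnBlocks {
  std::vector<int> q0, Lq, k0, Lk;
  void uniform(int n, int lq, int lk) {
    q0.resize(n); Lq.assign(n, lq); k0.resize(n); Lk.assign(n, lk);
    for (int t = 0; t < n; ++t) { q0[t] = t * lq; k0[t] = t * lk; }
  }
};

static void attn_blocks_fwd(const fmat& Q, const fmat& K, const fmat& V,
                            const AttnBlocks& B, int H, fmat& O,
                            std::vector<std::vector<fmat>>* Pkeep) {
  const int D = Q.n_cols, dh = D / H, nb = B.q0.size();
  O.set_size(Q.n_rows, D);
  if (Pkeep) Pkeep->assign(nb, std::vector<fmat>(H));
  for (int b = 0; b < nb; ++b) {
    span rq(B.q0[b], B.q0[b] + B.Lq[b] - 1);
    span rk(B.k0[b], B.k0[b] + B.Lk[b] - 1);
    for (int h = 0; h < H; ++h) {
      span cs(h * dh, (h + 1) * dh - 1);
      fmat St = K(rk, cs) * Q(rq, cs).t();       // [Lk, Lq]
      softmax_cols_inplace(St);
      O(rq, cs) = St.t() * V(rk, cs);
      if (Pkeep) (*Pkeep)[b][h] = std::move(St);
    }
  }
}

// backward; dQ comes out on the scaled-Q convention (the caller folds the
// scale back into the weight gradients)
static void attn_blocks_bwd(const fmat& dO, const fmat& Q, const fmat& K,
                            const fmat& V, const AttnBlocks& B, int H,
                            const std::vector<std::vector<fmat>>& P,
                            fmat& dQ, fmat& dK, fmat& dV) {
  const int D = Q.n_cols, dh = D / H, nb = B.q0.size();
  dQ.zeros(Q.n_rows, D); dK.zeros(K.n_rows, D); dV.zeros(V.n_rows, D);
  fmat dPt, dSt;
  for (int b = 0; b < nb; ++b) {
    span rq(B.q0[b], B.q0[b] + B.Lq[b] - 1);
    span rk(B.k0[b], B.k0[b] + B.Lk[b] - 1);
    const int lq = B.Lq[b], lk = B.Lk[b];
    dPt.set_size(lk, lq); dSt.set_size(lk, lq);
    for (int h = 0; h < H; ++h) {
      span cs(h * dh, (h + 1) * dh - 1);
      const fmat& Pt = P[b][h];                  // [Lk, Lq]
      fmat dOh = dO(rq, cs);
      dV(rk, cs) += Pt * dOh;
      dPt = V(rk, cs) * dOh.t();                 // [Lk, Lq]
      for (int j = 0; j < lq; ++j) {             // dS = P % (dP - colsum(dP%P))
        const float* p = Pt.colptr(j);
        const float* dp = dPt.colptr(j);
        float* ds = dSt.colptr(j);
        float rs = 0.0f;
        for (int i = 0; i < lk; ++i) rs += p[i] * dp[i];
        for (int i = 0; i < lk; ++i) ds[i] = p[i] * (dp[i] - rs);
      }
      dQ(rq, cs) = dSt.t() * K(rk, cs);
      dK(rk, cs) += dSt * Q(rq, cs);
    }
  }
}

// tanh-form GELU; the tanh values are cached so the backward pass reuses them
static fmat gelu_fwd(const fmat& X, fmat& Tn) {
  const float c1 = 0.7978845608028654f, a = 0.044715f;
  Tn.set_size(size(X));
  fmat Y(size(X));
  const float* x = X.memptr();
  float* t = Tn.memptr();
  float* y = Y.memptr();
  for (uword i = 0; i < X.n_elem; ++i) {
    const float u = c1 * (x[i] + a * x[i] * x[i] * x[i]);
    t[i] = ftanhf(u);
    y[i] = 0.5f * x[i] * (1.0f + t[i]);
  }
  return Y;
}
static fmat gelu_grad(const fmat& X, const fmat& Tn) {
  const float c1 = 0.7978845608028654f, a = 0.044715f;
  fmat Gd(size(X));
  const float* x = X.memptr();
  const float* t = Tn.memptr();
  float* g = Gd.memptr();
  for (uword i = 0; i < X.n_elem; ++i) {
    const float du = c1 * (1.0f + 3.0f * a * x[i] * x[i]);
    g[i] = 0.5f * (1.0f + t[i]) + 0.5f * x[i] * (1.0f - t[i] * t[i]) * du;
  }
  return Gd;
}

// sinusoidal positional encoding, 0-based positions (double: exported)
// [[Rcpp::export]]
arma::mat cpp_positional_encoding(int L, int D) {
  mat pe(L, D);
  for (int j = 0; j < D; ++j) {
    int k = j / 2;
    double denom = std::pow(10000.0, 2.0 * k / (double)D);
    for (int t = 0; t < L; ++t) {
      double a = t / denom;
      pe(t, j) = (j % 2 == 0) ? std::sin(a) : std::cos(a);
    }
  }
  return pe;
}

// ----------------------------------------------- stacked conv feature block ---

// width-3 same-pad im2col within per-trial blocks of length L
static fmat im2col_blocks(const fmat& X, int n, int L) {
  const int C = X.n_cols;
  fmat M(X.n_rows, 3 * C, fill::zeros);
  M.cols(C, 2 * C - 1) = X;
  for (int t = 0; t < n; ++t) {
    const int r0 = t * L;
    M.submat(r0 + 1, 0, r0 + L - 1, C - 1) = X.rows(r0, r0 + L - 2);
    M.submat(r0, 2 * C, r0 + L - 2, 3 * C - 1) = X.rows(r0 + 1, r0 + L - 1);
  }
  return M;
}

static fmat im2col_bwd(const fmat& dM, int n, int L) {
  const int C = dM.n_cols / 3;
  fmat dX = dM.cols(C, 2 * C - 1);
  for (int t = 0; t < n; ++t) {
    const int r0 = t * L;
    dX.rows(r0, r0 + L - 2) += dM.submat(r0 + 1, 0, r0 + L - 1, C - 1);
    dX.rows(r0 + 1, r0 + L - 1) += dM.submat(r0, 2 * C, r0 + L - 2, 3 * C - 1);
  }
  return dX;
}

struct ConvStageCache { fmat M, pre; LNCache ln; umat arg; };

static fmat conv_stage_fwd(const fmat& X, int n, int L, const fmat& K,
                           const fvec& b, const fvec& g, const fvec& be,
                           ConvStageCache& c) {
  c.M = im2col_blocks(X, n, L);
  fmat Cv = c.M * K;
  Cv.each_row() += b.t();
  fmat Nv = ln_fwd(Cv, g, be, c.ln);
  c.pre = Nv;
  fmat R = Nv;
  R.elem(find(Nv < 0)).zeros();
  const int L2 = L / 2, Co = R.n_cols;
  fmat Pp(n * L2, Co);
  c.arg.set_size(n * L2, Co);
  for (int t = 0; t < n; ++t)
    for (int u = 0; u < L2; ++u) {
      const int ro = t * L2 + u, ri = t * L + 2 * u;
      for (int j = 0; j < Co; ++j) {
        if (R(ri, j) >= R(ri + 1, j)) { Pp(ro, j) = R(ri, j); c.arg(ro, j) = ri; }
        else { Pp(ro, j) = R(ri + 1, j); c.arg(ro, j) = ri + 1; }
      }
    }
  return Pp;
}

static fmat conv_stage_bwd(const fmat& dP, int n, int L, const fmat& K,
                           const fvec& g, ConvStageCache& c,
                           fmat& dK, fvec& db, fvec& dg, fvec& dbe) {
  fmat dR(c.M.n_rows, dP.n_cols, fill::zeros);
  for (uword r = 0; r < dP.n_rows; ++r)
    for (uword j = 0; j < dP.n_cols; ++j)
      dR(c.arg(r, j), j) += dP(r, j);
  dR.elem(find(c.pre < 0)).zeros();
  fmat dCv = ln_bwd(dR, g, c.ln, dg, dbe);
  dK += c.M.t() * dCv;
  db += sum(dCv, 0).t();
  return im2col_bwd(dCv * K.t(), n, L);
}

// -------------------------------------------------------- stacked CT pass ---

struct ModCache {
  int L = 0;              // sequence length of this modality
  fmat X;                 // stacked raw input [(n L), D_i] (real trials)
  fmat H;                 // projected + positionally encoded
  fmat Y;                 // CT output, stacked over real trials
  fmat Yall;              // real + generated feature maps
  ConvStageCache cs1, cs2;
  fmat Z;                 // conv output stacked [(nt L/4), C]
};

// encoder layer cache over the modality-stacked layout
struct EncL {
  LNCache ln1, ln2;
  fmat N1, QKV, O, mask1, N2, H1pre, H1, Tn, mask2;
  std::vector<std::vector<fmat>> Ph;
};

struct CtCache {
  // cross-modal block, per-trial gathered layout
  LNCache lnq, lnc;
  fmat Nq, Nc, Q, K, V, O, maskX;
  std::vector<std::vector<fmat>> Pc;
  AttnBlocks cross_blocks;
  // encoder stack, modality-stacked layout
  fmat A0;                // encoder input
  std::vector<EncL> enc;
  AttnBlocks enc_blocks;
  std::vector<int> mod_row0;  // row offset of each modality in the stack
};

// forward through projection + positional encoding + cross-modal attention +
// encoder stack, over n stacked real trials (dropout active in training)
static void ct_fwd(std::vector<ModCache>& mc, CtCache& cc, const Params& P,
                   const Cfg& cfg, int n, Drop& drop, bool keep) {
  const int M = mc.size();
  const float qsc = 1.0f / std::sqrt((float)(cfg.D / cfg.H));
  for (int i = 0; i < M; ++i) {
    mc[i].H = mc[i].X * P.projW[i];
    mc[i].H.each_row() += P.projb[i].t();
    fmat pe = conv_to<fmat>::from(cpp_positional_encoding(mc[i].L, cfg.D));
    for (int t = 0; t < n; ++t)
      mc[i].H.rows(t * mc[i].L, (t + 1) * mc[i].L - 1) += pe;
  }
  int Lt = 0;
  for (int i = 0; i < M; ++i) Lt += mc[i].L;
  // modality-stacked layout: all of modality 0's trials, then modality 1's...
  cc.mod_row0.resize(M);
  int R = 0;
  for (int i = 0; i < M; ++i) { cc.mod_row0[i] = R; R += n * mc[i].L; }

  if (cfg.cross) {
    // the cross-modal block runs on the per-trial gathered layout: all
    // modality segments of one trial are contiguous rows, so every modality
    // attends over the full multimodal context in one attention call
    fmat Hg(n * Lt, cfg.D);
    for (int t = 0; t < n; ++t) {
      int r = t * Lt;
      for (int i = 0; i < M; ++i) {
        Hg.rows(r, r + mc[i].L - 1) =
          mc[i].H.rows(t * mc[i].L, (t + 1) * mc[i].L - 1);
        r += mc[i].L;
      }
    }
    fmat Ncg = ln_fwd(Hg, P.clncg, P.clncb, cc.lnc);
    fmat Kg = Ncg * P.cWk, Vg = Ncg * P.cWv;
    fmat Nqg = ln_fwd(Hg, P.clnqg, P.clnqb, cc.lnq);
    fmat Qg = (Nqg * P.cWq) * qsc;
    cc.cross_blocks.uniform(n, Lt, Lt);
    fmat Og;
    attn_blocks_fwd(Qg, Kg, Vg, cc.cross_blocks, cfg.H, Og,
                    keep ? &cc.Pc : nullptr);
    fmat OW = Og * P.cWo;
    if (drop.on()) {
      cc.maskX = drop.mask(OW.n_rows, OW.n_cols);
      OW %= cc.maskX;
    }
    fmat Ag = Hg + OW;
    // scatter into the modality-stacked encoder input
    cc.A0.set_size(R, cfg.D);
    for (int t = 0; t < n; ++t) {
      int r = t * Lt;
      for (int i = 0; i < M; ++i) {
        cc.A0.rows(cc.mod_row0[i] + t * mc[i].L,
                   cc.mod_row0[i] + (t + 1) * mc[i].L - 1) =
          Ag.rows(r, r + mc[i].L - 1);
        r += mc[i].L;
      }
    }
    if (keep) {
      cc.Nc = std::move(Ncg); cc.K = std::move(Kg); cc.V = std::move(Vg);
      cc.Nq = std::move(Nqg); cc.Q = std::move(Qg); cc.O = std::move(Og);
    }
  } else {
    cc.A0.set_size(R, cfg.D);
    for (int i = 0; i < M; ++i)
      cc.A0.rows(cc.mod_row0[i], cc.mod_row0[i] + n * mc[i].L - 1) = mc[i].H;
  }

  // encoder blocks: one per (modality, trial); self-attention within trial
  cc.enc_blocks.q0.clear(); cc.enc_blocks.Lq.clear();
  cc.enc_blocks.k0.clear(); cc.enc_blocks.Lk.clear();
  for (int i = 0; i < M; ++i)
    for (int t = 0; t < n; ++t) {
      const int r0 = cc.mod_row0[i] + t * mc[i].L;
      cc.enc_blocks.q0.push_back(r0); cc.enc_blocks.Lq.push_back(mc[i].L);
      cc.enc_blocks.k0.push_back(r0); cc.enc_blocks.Lk.push_back(mc[i].L);
    }
  cc.enc.resize(cfg.U);
  fmat A = cc.A0;
  for (int l = 0; l < cfg.U; ++l) {
    const EncP& e = P.enc[l];
    EncL& c = cc.enc[l];
    c.N1 = ln_fwd(A, e.ln1g, e.ln1b, c.ln1);
    c.QKV = c.N1 * e.Wqkv;
    c.QKV.cols(0, cfg.D - 1) *= qsc;
    const fmat Qv = c.QKV.cols(0, cfg.D - 1);
    const fmat Kv = c.QKV.cols(cfg.D, 2 * cfg.D - 1);
    const fmat Vv = c.QKV.cols(2 * cfg.D, 3 * cfg.D - 1);
    attn_blocks_fwd(Qv, Kv, Vv, cc.enc_blocks, cfg.H, c.O,
                    keep ? &c.Ph : nullptr);
    fmat OW = c.O * e.Wo;
    if (drop.on()) { c.mask1 = drop.mask(OW.n_rows, OW.n_cols); OW %= c.mask1; }
    fmat A2 = A + OW;
    c.N2 = ln_fwd(A2, e.ln2g, e.ln2b, c.ln2);
    c.H1pre = c.N2 * e.W1;
    c.H1pre.each_row() += e.b1.t();
    c.H1 = gelu_fwd(c.H1pre, c.Tn);
    fmat F = c.H1 * e.W2;
    F.each_row() += e.b2.t();
    if (drop.on()) { c.mask2 = drop.mask(F.n_rows, F.n_cols); F %= c.mask2; }
    A = A2 + F;
    if (!keep) {
      c.Ph.clear(); c.QKV.reset(); c.O.reset(); c.N1.reset(); c.N2.reset();
      c.H1pre.reset(); c.H1.reset(); c.Tn.reset();
    }
  }
  for (int i = 0; i < M; ++i)
    mc[i].Y = A.rows(cc.mod_row0[i], cc.mod_row0[i] + n * mc[i].L - 1);
}

// backward through the CT given d(Y) per modality (real trials)
static void ct_bwd(std::vector<ModCache>& mc, CtCache& cc,
                   std::vector<fmat>& dY, const Params& P, Grads& G,
                   const Cfg& cfg, int n, Drop& drop) {
  const int M = mc.size();
  const float qsc = 1.0f / std::sqrt((float)(cfg.D / cfg.H));
  const int R = cc.A0.n_rows;
  fmat d(R, cfg.D);
  for (int i = 0; i < M; ++i)
    d.rows(cc.mod_row0[i], cc.mod_row0[i] + n * mc[i].L - 1) = dY[i];
  for (int l = cfg.U - 1; l >= 0; --l) {
    const EncP& e = P.enc[l];
    EncP& g = G.enc[l];
    EncL& c = cc.enc[l];
    fmat dF = drop.on() ? fmat(d % c.mask2) : d;
    g.W2 += c.H1.t() * dF;
    g.b2 += sum(dF, 0).t();
    fmat dH1 = (dF * e.W2.t()) % gelu_grad(c.H1pre, c.Tn);
    g.W1 += c.N2.t() * dH1;
    g.b1 += sum(dH1, 0).t();
    fmat dA2 = d + ln_bwd(dH1 * e.W1.t(), e.ln2g, c.ln2, g.ln2g, g.ln2b);
    fmat dOW = drop.on() ? fmat(dA2 % c.mask1) : dA2;
    g.Wo += c.O.t() * dOW;
    fmat dO = dOW * e.Wo.t();
    const fmat Qv = c.QKV.cols(0, cfg.D - 1);
    const fmat Kv = c.QKV.cols(cfg.D, 2 * cfg.D - 1);
    const fmat Vv = c.QKV.cols(2 * cfg.D, 3 * cfg.D - 1);
    fmat dQ, dK, dV;
    attn_blocks_bwd(dO, Qv, Kv, Vv, cc.enc_blocks, cfg.H, c.Ph, dQ, dK, dV);
    dQ *= qsc;
    fmat dQKV = join_rows(dQ, dK, dV);
    g.Wqkv += c.N1.t() * dQKV;
    fmat dN1 = dQKV * e.Wqkv.t();
    d = dA2 + ln_bwd(dN1, e.ln1g, c.ln1, g.ln1g, g.ln1b);
  }

  std::vector<fmat> dH(M);
  if (cfg.cross) {
    int Lt = 0;
    for (int i = 0; i < M; ++i) Lt += mc[i].L;
    // regather the encoder-input gradient into the per-trial layout
    fmat dAg(n * Lt, cfg.D);
    for (int t = 0; t < n; ++t) {
      int r = t * Lt;
      for (int i = 0; i < M; ++i) {
        dAg.rows(r, r + mc[i].L - 1) =
          d.rows(cc.mod_row0[i] + t * mc[i].L,
                 cc.mod_row0[i] + (t + 1) * mc[i].L - 1);
        r += mc[i].L;
      }
    }
    fmat dHg = dAg;  // residual path
    fmat dOW = drop.on() ? fmat(dAg % cc.maskX) : dAg;
    G.cWo += cc.O.t() * dOW;
    fmat dO = dOW * P.cWo.t();
    fmat dQ, dK, dV;
    attn_blocks_bwd(dO, cc.Q, cc.K, cc.V, cc.cross_blocks, cfg.H, cc.Pc,
                    dQ, dK, dV);
    G.cWq += cc.Nq.t() * dQ * qsc;
    dHg += ln_bwd((dQ * qsc) * P.cWq.t(), P.clnqg, cc.lnq, G.clnqg, G.clnqb);
    G.cWk += cc.Nc.t() * dK;
    G.cWv += cc.Nc.t() * dV;
    dHg += ln_bwd(dK * P.cWk.t() + dV * P.cWv.t(), P.clncg, cc.lnc,
                  G.clncg, G.clncb);
    for (int t = 0; t < n; ++t) {
      int r = t * Lt;
      for (int i = 0; i < M; ++i) {
        if (t == 0) dH[i].set_size(n * mc[i].L, cfg.D);
        dH[i].rows(t * mc[i].L, (t + 1) * mc[i].L - 1) =
          dHg.rows(r, r + mc[i].L - 1);
        r += mc[i].L;
      }
    }
  } else {
    for (int i = 0; i < M; ++i)
      dH[i] = d.rows(cc.mod_row0[i], cc.mod_row0[i] + n * mc[i].L - 1);
  }
  for (int i = 0; i < M; ++i) {
    G.projW[i] += mc[i].X.t() * dH[i];
    G.projb[i] += sum(dH[i], 0).t();
  }
}

// classifier head: X -> relu(X W1 + b1) [dropout] -> logits -> softmax CE.
// Returns average CE; accumulates (weight-scaled) parameter grads and dX.
static double head_pass(const fmat& X, const std::vector<int>& lab, int K,
                        const fmat& W1, const fvec& b1,
                        const fmat& W2, const fvec& b2,
                        float w, Drop* drop,
                        fmat& gW1, fvec& gb1, fmat& gW2, fvec& gb2,
                        fmat& dX, bool want_grad) {
  const uword n = X.n_rows;
  fmat H1 = X * W1;
  H1.each_row() += b1.t();
  fmat relu_mask = conv_to<fmat>::from(H1 > 0);
  H1 %= relu_mask;
  fmat dmask;
  const bool use_drop = drop && drop->on();
  if (use_drop) {
    dmask = drop->mask(H1.n_rows, H1.n_cols);
    H1 %= dmask;
  }
  fmat Lg = H1 * W2;
  Lg.each_row() += b2.t();
  fmat Pp = Lg.t();              // [K, n], softmax per column
  softmax_cols_inplace(Pp);
  Pp = Pp.t();
  double ce = 0.0;
  for (uword i = 0; i < n; ++i)
    ce -= std::log(std::max((double)Pp(i, lab[i]), 1e-300));
  ce /= n;
  if (want_grad && w != 0.0f) {
    fmat dL = Pp;
    for (uword i = 0; i < n; ++i) dL(i, lab[i]) -= 1.0f;
    dL *= w / (float)n;
    gW2 += H1.t() * dL;
    gb2 += sum(dL, 0).t();
    fmat dH1 = dL * W2.t();
    if (use_drop) dH1 %= dmask;
    dH1 %= relu_mask;
    gW1 += X.t() * dH1;
    gb1 += sum(dH1, 0).t();
    dX = dH1 * W1.t();
  } else {
    dX.zeros(X.n_rows, X.n_cols);
  }
  return ce;
}

// build stacked per-modality inputs from a list of [L, D_i, n] cubes
static void stack_signals(const List& signals, std::vector<ModCache>& mc,
                          int& n) {
  const int M = signals.size();
  mc.resize(M);
  for (int i = 0; i < M; ++i) {
    cube s = Rcpp::as<cube>(signals[i]);
    n = s.n_slices;
    mc[i].L = s.n_rows;
    mc[i].X.set_size(n * s.n_rows, s.n_cols);
    for (int t = 0; t < n; ++t)
      mc[i].X.rows(t * s.n_rows, (t + 1) * s.n_rows - 1) =
        conv_to<fmat>::from(s.slice(t));
  }
}

// conv feature learner for all nt trials of one modality
static void conv_fwd_mod(ModCache& m, const ConvP& cp, int nt) {
  fmat P1 = conv_stage_fwd(m.Yall, nt, m.L, cp.K1, cp.b1, cp.g1, cp.be1, m.cs1);
  m.Z = conv_stage_fwd(P1, nt, m.L / 2, cp.K2, cp.b2, cp.g2, cp.be2, m.cs2);
}

// ------------------------------------------------------------ entry points ---

// Feature-extractor forward over a batch (evaluation mode unless a
// nonnegative dropout seed is given). Returns per-modality context-enriched
// sequences and the concatenated projected context.
// [[Rcpp::export]]
List cpp_ct_forward(List signals, List params, List config, int dropout_seed) {
  Cfg cfg = read_cfg(config);
  const int M = signals.size();
  Params P = read_params(params, cfg, M);
  std::vector<ModCache> mc;
  CtCache cc;
  int n = 0;
  stack_signals(signals, mc, n);
  Drop drop;
  drop.active = dropout_seed >= 0;
  drop.p = cfg.dropout;
  drop.seed((uint64_t)std::max(dropout_seed, 0));
  ct_fwd(mc, cc, P, cfg, n, drop, false);
  List Yl(M);
  int Lt = 0;
  for (int i = 0; i < M; ++i) Lt += mc[i].L;
  cube Ctx(Lt, cfg.D, n);
  for (int i = 0; i < M; ++i) {
    cube Y(mc[i].L, cfg.D, n);
    for (int t = 0; t < n; ++t)
      Y.slice(t) = conv_to<mat>::from(
        mc[i].Y.rows(t * mc[i].L, (t + 1) * mc[i].L - 1));
    Yl[i] = Y;
  }
  for (int t = 0; t < n; ++t) {
    int r = 0;
    for (int i = 0; i < M; ++i) {
      Ctx.slice(t).rows(r, r + mc[i].L - 1) = conv_to<mat>::from(
        mc[i].H.rows(t * mc[i].L, (t + 1) * mc[i].L - 1));
      r += mc[i].L;
    }
  }
  return List::create(Named("Y") = Yl, Named("context") = Ctx);
}

// Full joint loss and gradient for one minibatch.
// signals: real trials; gen_feats: generated feature-space samples (may be
// empty). Labels 0-based.
// [[Rcpp::export]]
List cpp_model_loss_grad(List signals, Rcpp::IntegerVector emo,
                         Rcpp::IntegerVector subj,
                         List gen_feats, Rcpp::IntegerVector gen_emo,
                         List params, List config,
                         double lambda, Rcpp::NumericVector weights,
                         int n_sub, int n_emo, int dropout_seed) {
  Cfg cfg = read_cfg(config);
  const int M = signals.size();
  Params P = read_params(params, cfg, M);
  Grads G = Grads::like(P);
  const float alpha = (float)weights[0], beta = (float)weights[1],
              gamma_w = (float)weights[2];

  std::vector<ModCache> mc;
  CtCache cc;
  int n = 0;
  stack_signals(signals, mc, n);
  const bool has_gen = gen_feats.size() > 0;
  int ng = 0;
  if (has_gen) {
    cube g0 = Rcpp::as<cube>(gen_feats[0]);
    ng = g0.n_slices;
  }
  const int nt = n + ng;

  Drop drop;
  drop.active = dropout_seed >= 0;
  drop.p = cfg.dropout;
  drop.seed((uint64_t)std::max(dropout_seed, 0));

  ct_fwd(mc, cc, P, cfg, n, drop, true);

  // append generated feature maps and run the conv feature learner
  for (int i = 0; i < M; ++i) {
    if (has_gen) {
      cube gi = Rcpp::as<cube>(gen_feats[i]);
      mc[i].Yall.set_size(nt * mc[i].L, cfg.D);
      mc[i].Yall.rows(0, n * mc[i].L - 1) = mc[i].Y;
      for (int t = 0; t < ng; ++t)
        mc[i].Yall.rows((n + t) * mc[i].L, (n + t + 1) * mc[i].L - 1) =
          conv_to<fmat>::from(gi.slice(t));
    } else {
      mc[i].Yall = mc[i].Y;
    }
    conv_fwd_mod(mc[i], P.conv[i], nt);
  }

  // pooled fused features (length-weighted mean over the concatenated
  // sequence) feed the emotion head; the adversarial modality and subject
  // classifiers act per position of the fused sequence, so the invariance
  // pressure is applied pointwise rather than to a pooled summary
  std::vector<float> Lw(M);
  float Lf = 0.0f;
  for (int i = 0; i < M; ++i) { Lw[i] = (float)((mc[i].L / 2) / 2); Lf += Lw[i]; }
  for (int i = 0; i < M; ++i) Lw[i] /= Lf;
  fmat Zf(nt, cfg.C, fill::zeros);
  int rows_total = 0;
  for (int i = 0; i < M; ++i) rows_total += nt * ((mc[i].L / 2) / 2);
  fmat Zrows(rows_total, cfg.C);
  std::vector<int> mod_lab(rows_total), sub_row_lab;
  std::vector<int> row_of;  // start row of (modality i) block in Zrows
  {
    int r = 0;
    for (int i = 0; i < M; ++i) {
      const int L4 = (mc[i].L / 2) / 2;
      row_of.push_back(r);
      Zrows.rows(r, r + nt * L4 - 1) = mc[i].Z;
      for (int t = 0; t < nt; ++t) {
        for (int u = 0; u < L4; ++u) mod_lab[r + t * L4 + u] = i;
        frowvec z = sum(mc[i].Z.rows(t * L4, (t + 1) * L4 - 1), 0) / (float)L4;
        Zf.row(t) += Lw[i] * z;
      }
      r += nt * L4;
    }
  }

  std::vector<int> emo_lab(nt);
  for (int t = 0; t < n; ++t) emo_lab[t] = emo[t];
  for (int t = 0; t < ng; ++t) emo_lab[n + t] = gen_emo[t];

  fmat dZf_e, dZrows_m, dZrows_s;
  double l_emo = head_pass(Zf, emo_lab, n_emo, P.eW1, P.eb1, P.eW2, P.eb2,
                           gamma_w, &drop, G.eW1, G.eb1, G.eW2, G.eb2,
                           dZf_e, true);
  double l_mod = head_pass(Zrows, mod_lab, M, P.mW1, P.mb1, P.mW2, P.mb2,
                           alpha, nullptr, G.mW1, G.mb1, G.mW2, G.mb2,
                           dZrows_m, true);
  double l_sub = 0.0;
  bool use_sub = P.has_sub && n > 0;
  if (use_sub) {
    // real trials' rows only (generated samples carry no subject identity)
    int nreal_rows = 0;
    for (int i = 0; i < M; ++i) nreal_rows += n * ((mc[i].L / 2) / 2);
    fmat Zsub(nreal_rows, cfg.C);
    std::vector<int> sub_lab(nreal_rows);
    int r = 0;
    for (int i = 0; i < M; ++i) {
      const int L4 = (mc[i].L / 2) / 2;
      Zsub.rows(r, r + n * L4 - 1) = Zrows.rows(row_of[i], row_of[i] + n * L4 - 1);
      for (int t = 0; t < n; ++t)
        for (int u = 0; u < L4; ++u) sub_lab[r + t * L4 + u] = subj[t];
      r += n * L4;
    }
    fmat dZsub;
    l_sub = head_pass(Zsub, sub_lab, n_sub, P.sW1, P.sb1, P.sW2, P.sb2,
                      beta, nullptr, G.sW1, G.sb1, G.sW2, G.sb2,
                      dZsub, true);
    // scatter back into the Zrows layout (zeros for generated rows)
    dZrows_s.zeros(rows_total, cfg.C);
    r = 0;
    for (int i = 0; i < M; ++i) {
      const int L4 = (mc[i].L / 2) / 2;
      dZrows_s.rows(row_of[i], row_of[i] + n * L4 - 1) =
        dZsub.rows(r, r + n * L4 - 1);
      r += n * L4;
    }
  }

  // backward into the feature learner; adversarial paths reversed by -lambda
  const float lam = (float)lambda;
  dZrows_m *= -lam;
  if (use_sub) dZrows_s *= -lam;
  std::vector<fmat> dY(M);
  for (int i = 0; i < M; ++i) {
    const int L4 = (mc[i].L / 2) / 2;
    fmat dZ(nt * L4, cfg.C);
    dZ = dZrows_m.rows(row_of[i], row_of[i] + nt * L4 - 1);
    if (use_sub) dZ += dZrows_s.rows(row_of[i], row_of[i] + nt * L4 - 1);
    for (int t = 0; t < nt; ++t) {
      frowvec dzi = Lw[i] * dZf_e.row(t);
      dZ.rows(t * L4, (t + 1) * L4 - 1).each_row() += dzi / (float)L4;
    }
    fmat dP1 = conv_stage_bwd(dZ, nt, mc[i].L / 2, P.conv[i].K2, P.conv[i].g2,
                              mc[i].cs2, G.conv[i].K2, G.conv[i].b2,
                              G.conv[i].g2, G.conv[i].be2);
    fmat dYall = conv_stage_bwd(dP1, nt, mc[i].L, P.conv[i].K1, P.conv[i].g1,
                                mc[i].cs1, G.conv[i].K1, G.conv[i].b1,
                                G.conv[i].g1, G.conv[i].be1);
    dY[i] = dYall.rows(0, n * mc[i].L - 1);
  }
  ct_bwd(mc, cc, dY, P, G, cfg, n, drop);

  return List::create(
    Named("l_mod") = l_mod, Named("l_sub") = l_sub, Named("l_emo") = l_emo,
    Named("grads") = G.to_list(cfg, M, P.has_sub));
}

// Evaluation-mode forward: emotion probabilities and fused pooled features.
// [[Rcpp::export]]
List cpp_model_predict(List signals, List params, List config) {
  Cfg cfg = read_cfg(config);
  const int M = signals.size();
  Params P = read_params(params, cfg, M);
  std::vector<ModCache> mc;
  CtCache cc;
  int n = 0;
  stack_signals(signals, mc, n);
  Drop drop;  // inactive
  ct_fwd(mc, cc, P, cfg, n, drop, false);
  std::vector<float> Lw(M);
  float Lf = 0.0f;
  for (int i = 0; i < M; ++i) { Lw[i] = (float)((mc[i].L / 2) / 2); Lf += Lw[i]; }
  for (int i = 0; i < M; ++i) Lw[i] /= Lf;
  fmat Zf(n, cfg.C, fill::zeros);
  for (int i = 0; i < M; ++i) {
    mc[i].Yall = std::move(mc[i].Y);
    conv_fwd_mod(mc[i], P.conv[i], n);
    const int L4 = (mc[i].L / 2) / 2;
    for (int t = 0; t < n; ++t)
      Zf.row(t) += Lw[i] *
        (sum(mc[i].Z.rows(t * L4, (t + 1) * L4 - 1), 0) / (float)L4);
  }
  fmat H1 = Zf * P.eW1;
  H1.each_row() += P.eb1.t();
  H1.elem(find(H1 < 0)).zeros();
  fmat Lg = H1 * P.eW2;
  Lg.each_row() += P.eb2.t();
  fmat Pt = Lg.t();
  softmax_cols_inplace(Pt);
  // renormalize in double on export so each probability row is a clean
  // distribution at double precision
  mat probs = conv_to<mat>::from(Pt.t());
  for (uword i = 0; i < probs.n_rows; ++i) probs.row(i) /= accu(probs.row(i));
  return List::create(Named("probs") = probs,
                      Named("fused") = conv_to<mat>::from(Zf));
}

// One modality's convolutional feature-learner block: two stages of
// width-3 convolution + layer normalization + ReLU + max-pool(2).
// [[Rcpp::export]]
arma::mat cpp_conv_block(arma::mat y, List cp) {
  ConvStageCache c1, c2;
  fmat yf = conv_to<fmat>::from(y);
  fmat P1 = conv_stage_fwd(yf, 1, yf.n_rows,
                           conv_to<fmat>::from(Rcpp::as<mat>(cp["K1"])),
                           conv_to<fvec>::from(Rcpp::as<vec>(cp["b1"])),
                           conv_to<fvec>::from(Rcpp::as<vec>(cp["g1"])),
                           conv_to<fvec>::from(Rcpp::as<vec>(cp["be1"])), c1);
  fmat Z = conv_stage_fwd(P1, 1, P1.n_rows,
                          conv_to<fmat>::from(Rcpp::as<mat>(cp["K2"])),
                          conv_to<fvec>::from(Rcpp::as<vec>(cp["b2"])),
                          conv_to<fvec>::from(Rcpp::as<vec>(cp["g2"])),
                          conv_to<fvec>::from(Rcpp::as<vec>(cp["be2"])), c2);
  return conv_to<mat>::from(Z);
}

// Double-precision multi-head attention reference: probabilities and
// (pre-output-projection) values for one sequence/context pair; this is the
// oracle-facing kernel of the test suite.
// [[Rcpp::export]]
List cpp_multihead_attention(arma::mat query, arma::mat context,
                             arma::mat Wq, arma::mat Wk, arma::mat Wv,
                             int n_heads) {
  mat Q = query * Wq, K = context * Wk, V = context * Wv;
  const int D = Q.n_cols, dh = D / n_heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  mat O(Q.n_rows, D);
  List pl(n_heads);
  for (int h = 0; h < n_heads; ++h) {
    span cs(h * dh, (h + 1) * dh - 1);
    mat S = Q.cols(cs) * K.cols(cs).t() * sc;
    vec mx = max(S, 1);
    S.each_col() -= mx;
    S = exp(S);
    vec sm = sum(S, 1);
    S.each_col() /= sm;
    O.cols(cs) = S * V.cols(cs);
    pl[h] = S;
  }
  return List::create(Named("output") = O, Named("probs") = pl);
}
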