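// Compiled hot path of the encoder-decoder transformer: teacher-forced
// forward/backward over a ragged minibatch, inference-mode encoding, and
// batched autoregressive decoding. Mirrors the base R reference
// implementation exactly (the test suite asserts equality); all
// randomness (dropout masks, multinomial draws) flows through the R RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

static NumericVector rv(const rowvec &x) {
  return NumericVector(x.begin(), x.end());
}

static const double LN_EPS = 1e-5;

static mat posenc(const arma::uvec &pos, int d) {
  mat pe(pos.n_elem, d, arma::fill::zeros);
  for (int i2 = 0; i2 < d; i2 += 2) {
    double freq = std::pow(10000.0, -double(i2) / d);
    for (uword r = 0; r < pos.n_elem; ++r) {
      double a = double(pos[r]) * freq;
      pe(r, i2) = std::sin(a);
      if (i2 + 1 < d) pe(r, i2 + 1) = std::cos(a);
    }
  }
  return pe;
}

struct LNCache { mat xhat; vec inv; mat Y; };

static LNCache ln_fwd(const mat &X, const rowvec &g, const rowvec &b) {
  LNCache c;
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  c.inv = 1.0 / arma::sqrt(v + LN_EPS);
  c.xhat = xc.each_col() % c.inv;
  c.Y = c.xhat.each_row() % g;
  c.Y.each_row() += b;
  return c;
}

static mat ln_bwd(const mat &dY, const LNCache &c, const rowvec &g,
                  rowvec &dg, rowvec &db) {
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv;
  dg = arma::sum(dY % c.xhat, 0);
  db = arma::sum(dY, 0);
  return dX;
}

static void softmax_rows(mat &S) {
  vec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

struct AttnP { mat Wq, Wk, Wv, Wo; };

static AttnP attn_p(const List &p) {
  return {as<mat>(p["Wq"]), as<mat>(p["Wk"]), as<mat>(p["Wv"]), as<mat>(p["Wo"])};
}

struct AttnCache {
  mat Q, K, V, C, Out;
  std::vector<std::vector<mat>> P;  // per sample, per head
};

static AttnCache mha_fwd(const AttnP &p, int H, const mat &Xq, const mat &Xkv,
                         const arma::uvec &qoff, const arma::uvec &qlen,
                         const arma::uvec &koff, const arma::uvec &klen,
                         bool causal) {
  int d = Xq.n_cols, dh = d / H;
  double scale = 1.0 / std::sqrt(double(dh));
  AttnCache c;
  c.Q = Xq * p.Wq; c.K = Xkv * p.Wk; c.V = Xkv * p.Wv;
  c.C.zeros(Xq.n_rows, d);
  c.P.resize(qlen.n_elem);
  for (uword i = 0; i < qlen.n_elem; ++i) {
    uword q0 = qoff[i], q1 = qoff[i] + qlen[i] - 1;
    uword k0 = koff[i], k1 = koff[i] + klen[i] - 1;
    c.P[i].resize(H);
    for (int h = 0; h < H; ++h) {
      uword c0 = uword(h) * dh, c1 = uword(h + 1) * dh - 1;
      mat S = c.Q.submat(q0, c0, q1, c1) * c.K.submat(k0, c0, k1, c1).t() * scale;
      if (causal)
        for (uword r = 0; r < S.n_rows; ++r)
          for (uword cc = r + 1; cc < S.n_cols; ++cc)
            S(r, cc) = -arma::datum::inf;
      softmax_rows(S);
      c.P[i][h] = S;
      c.C.submat(q0, c0, q1, c1) = S * c.V.submat(k0, c0, k1, c1);
    }
  }
  c.Out = c.C * p.Wo;
  return c;
}

// dXkv is accumulated into; returns dXq. Gradients land in gq..go.
static mat mha_bwd(const mat &dOut, const AttnP &p, int H, const AttnCache &c,
                   const mat &Xq, const mat &Xkv,
                   const arma::uvec &qoff, const arma::uvec &qlen,
                   const arma::uvec &koff, const arma::uvec &klen,
                   mat &gWq, mat &gWk, mat &gWv, mat &gWo, mat &dXkv_acc) {
  int d = Xq.n_cols, dh = d / H;
  double scale = 1.0 / std::sqrt(double(dh));
  mat dC = dOut * p.Wo.t();
  mat dQ(Xq.n_rows, d, arma::fill::zeros);
  mat dK(Xkv.n_rows, d, arma::fill::zeros);
  mat dV(Xkv.n_rows, d, arma::fill::zeros);
  for (uword i = 0; i < qlen.n_elem; ++i) {
    uword q0 = qoff[i], q1 = qoff[i] + qlen[i] - 1;
    uword k0 = koff[i], k1 = koff[i] + klen[i] - 1;
    for (int h = 0; h < H; ++h) {
      uword c0 = uword(h) * dh, c1 = uword(h + 1) * dh - 1;
      const mat &P = c.P[i][h];
      mat dCh = dC.submat(q0, c0, q1, c1);
      mat dP = dCh * c.V.submat(k0, c0, k1, c1).t();
      dV.submat(k0, c0, k1, c1) += P.t() * dCh;
      vec rs = arma::sum(dP % P, 1);
      mat dS = P % (dP.each_col() - rs);
      dQ.submat(q0, c0, q1, c1) += dS * c.K.submat(k0, c0, k1, c1) * scale;
      dK.submat(k0, c0, k1, c1) += dS.t() * c.Q.submat(q0, c0, q1, c1) * scale;
    }
  }
  gWq = Xq.t() * dQ; gWk = Xkv.t() * dK; gWv = Xkv.t() * dV;
  gWo = c.C.t() * dOut;
  dXkv_acc += dK * p.Wk.t() + dV * p.Wv.t();
  return dQ * p.Wq.t();
}

struct FFP { mat W1, W2; rowvec b1, b2; };
static FFP ff_p(const List &p) {
  return {as<mat>(p["W1"]), as<mat>(p["W2"]), as<rowvec>(p["b1"]), as<rowvec>(p["b2"])};
}
struct FFCache { mat Hpre, Hact, Y; };

static FFCache ff_fwd(const FFP &p, const mat &X) {
  FFCache c;
  c.Hpre = X * p.W1;
  c.Hpre.each_row() += p.b1;
  c.Hact = c.Hpre % (c.Hpre > 0);
  c.Y = c.Hact * p.W2;
  c.Y.each_row() += p.b2;
  return c;
}

static mat ff_bwd(const mat &dY, const FFP &p, const FFCache &c, const mat &X,
                  mat &gW1, rowvec &gb1, mat &gW2, rowvec &gb2) {
  mat dH = (dY * p.W2.t()) % (c.Hpre > 0);
  gW1 = X.t() * dH; gb1 = arma::sum(dH, 0);
  gW2 = c.Hact.t() * dY; gb2 = arma::sum(dY, 0);
  return dH * p.W1.t();
}

// dropout mask drawn from the R RNG (column-major, matching matrix(runif(n*d)))
static mat drop_mask(uword n, uword d, double rate) {
  mat m(n, d);
  double keep = 1.0 - rate;
  for (uword j = 0; j < d; ++j)
    for (uword i = 0; i < n; ++i)
      m(i, j) = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
  return m;
}

static arma::uvec uvec_from(const IntegerVector &x, int shift = 0) {
  arma::uvec out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = uword(x[i] + shift);
  return out;
}

static mat embed(const mat &emb, const arma::uvec &ids, const arma::uvec &len, int d) {
  mat X = emb.rows(ids) * std::sqrt(double(d));
  arma::uvec pos(ids.n_elem);
  uword k = 0;
  for (uword i = 0; i < len.n_elem; ++i)
    for (uword t = 0; t < len[i]; ++t) pos[k++] = t;
  return X + posenc(pos, d);
}

struct EncCache {
  mat X_in; AttnCache attn; mat drop1; LNCache ln1;
  FFCache ff; mat drop2; LNCache ln2;
};
struct DecCache {
  mat Y_in; AttnCache self; mat drop1; LNCache ln1;
  AttnCache cross; mat drop2; LNCache ln2;
  FFCache ff; mat drop3; LNCache ln3;
};

// [[Rcpp::export]]
List cpp_train_batch(List params, List cfg,
                     IntegerVector src_ids, IntegerVector src_off, IntegerVector src_len,
                     IntegerVector tin_ids, IntegerVector tin_off, IntegerVector tin_len,
                     IntegerVector tout_ids,
                     double dropout, bool want_grads) {
  int d = as<int>(cfg["d_model"]), H = as<int>(cfg["n_heads"]);
  List enc_par = params["enc"], dec_par = params["dec"], out_par = params["out"];
  int NE = enc_par.size(), ND = dec_par.size();
  mat src_emb = as<mat>(params["src_emb"]), tgt_emb = as<mat>(params["tgt_emb"]);
  mat Wout = as<mat>(out_par["W"]);
  rowvec bout = as<rowvec>(out_par["b"]);

  arma::uvec sids = uvec_from(src_ids, -1), soff = uvec_from(src_off),
             slen = uvec_from(src_len);
  arma::uvec tids = uvec_from(tin_ids, -1), toff = uvec_from(tin_off),
             tlen = uvec_from(tin_len);
  arma::uvec oids = uvec_from(tout_ids, -1);

  bool use_drop = dropout > 0;
  mat X = embed(src_emb, sids, slen, d);
  mat drop_src;
  if (use_drop) { drop_src = drop_mask(X.n_rows, d, dropout); X %= drop_src; }

  std::vector<EncCache> ec(NE);
  std::vector<AttnP> enc_attn(NE); std::vector<FFP> enc_ff(NE);
  std::vector<rowvec> enc_g1(NE), enc_b1(NE), enc_g2(NE), enc_b2(NE);
  for (int l = 0; l < NE; ++l) {
    List lp = enc_par[l];
    enc_attn[l] = attn_p(lp["attn"]); enc_ff[l] = ff_p(lp["ff"]);
    List ln1 = lp["ln1"], ln2 = lp["ln2"];
    enc_g1[l] = as<rowvec>(ln1["g"]); enc_b1[l] = as<rowvec>(ln1["b"]);
    enc_g2[l] = as<rowvec>(ln2["g"]); enc_b2[l] = as<rowvec>(ln2["b"]);
    ec[l].X_in = X;
    ec[l].attn = mha_fwd(enc_attn[l], H, X, X, soff, slen, soff, slen, false);
    mat A = ec[l].attn.Out;
    if (use_drop) { ec[l].drop1 = drop_mask(A.n_rows, d, dropout); A %= ec[l].drop1; }
    ec[l].ln1 = ln_fwd(X + A, enc_g1[l], enc_b1[l]);
    ec[l].ff = ff_fwd(enc_ff[l], ec[l].ln1.Y);
    mat F = ec[l].ff.Y;
    if (use_drop) { ec[l].drop2 = drop_mask(F.n_rows, d, dropout); F %= ec[l].drop2; }
    ec[l].ln2 = ln_fwd(ec[l].ln1.Y + F, enc_g2[l], enc_b2[l]);
    X = ec[l].ln2.Y;
  }
  mat memory = X;

  mat Y = embed(tgt_emb, tids, tlen, d);
  mat drop_tgt;
  if (use_drop) { drop_tgt = drop_mask(Y.n_rows, d, dropout); Y %= drop_tgt; }

  std::vector<DecCache> dc(ND);
  std::vector<AttnP> dec_self(ND), dec_cross(ND); std::vector<FFP> dec_ff(ND);
  std::vector<rowvec> dg1(ND), db1(ND), dg2(ND), db2(ND), dg3(ND), db3(ND);
  for (int l = 0; l < ND; ++l) {
    List lp = dec_par[l];
    dec_self[l] = attn_p(lp["self_attn"]); dec_cross[l] = attn_p(lp["cross_attn"]);
    dec_ff[l] = ff_p(lp["ff"]);
    List ln1 = lp["ln1"], ln2 = lp["ln2"], ln3 = lp["ln3"];
    dg1[l] = as<rowvec>(ln1["g"]); db1[l] = as<rowvec>(ln1["b"]);
    dg2[l] = as<rowvec>(ln2["g"]); db2[l] = as<rowvec>(ln2["b"]);
    dg3[l] = as<rowvec>(ln3["g"]); db3[l] = as<rowvec>(ln3["b"]);
    dc[l].Y_in = Y;
    dc[l].self = mha_fwd(dec_self[l], H, Y, Y, toff, tlen, toff, tlen, true);
    mat A1 = dc[l].self.Out;
    if (use_drop) { dc[l].drop1 = drop_mask(A1.n_rows, d, dropout); A1 %= dc[l].drop1; }
    dc[l].ln1 = ln_fwd(Y + A1, dg1[l], db1[l]);
    dc[l].cross = mha_fwd(dec_cross[l], H, dc[l].ln1.Y, memory, toff, tlen, soff, slen, false);
    mat A2 = dc[l].cross.Out;
    if (use_drop) { dc[l].drop2 = drop_mask(A2.n_rows, d, dropout); A2 %= dc[l].drop2; }
    dc[l].ln2 = ln_fwd(dc[l].ln1.Y + A2, dg2[l], db2[l]);
    dc[l].ff = ff_fwd(dec_ff[l], dc[l].ln2.Y);
    mat F = dc[l].ff.Y;
    if (use_drop) { dc[l].drop3 = drop_mask(F.n_rows, d, dropout); F %= dc[l].drop3; }
    dc[l].ln3 = ln_fwd(dc[l].ln2.Y + F, dg3[l], db3[l]);
    Y = dc[l].ln3.Y;
  }

  mat logits = Y * Wout;
  logits.each_row() += bout;
  vec mx = arma::max(logits, 1);
  vec lse = mx + arma::log(arma::sum(arma::exp(logits.each_col() - mx), 1));
  double n_tok = double(oids.n_elem);
  double loss = 0;
  for (uword i = 0; i < oids.n_elem; ++i) loss += lse[i] - logits(i, oids[i]);
  loss /= n_tok;

  if (!want_grads) return List::create(_["loss"] = loss, _["n_tokens"] = n_tok);

  // ---- backward
  mat P = arma::exp(logits.each_col() - lse);
  for (uword i = 0; i < oids.n_elem; ++i) P(i, oids[i]) -= 1.0;
  P /= n_tok;
  mat gWout = Y.t() * P;
  rowvec gbout = arma::sum(P, 0);
  mat dY = P * Wout.t();
  mat dMem(memory.n_rows, d, arma::fill::zeros);

  List g_dec(ND);
  for (int l = ND - 1; l >= 0; --l) {
    DecCache &c = dc[l];
    rowvec g3g, g3b, g2g, g2b, g1g, g1b;
    mat dR3 = ln_bwd(dY, c.ln3, dg3[l], g3g, g3b);
    mat dF = use_drop ? mat(dR3 % c.drop3) : dR3;
    mat gW1, gW2; rowvec gb1, gb2;
    mat dN2 = dR3 + ff_bwd(dF, dec_ff[l], c.ff, c.ln2.Y, gW1, gb1, gW2, gb2);
    mat dR2 = ln_bwd(dN2, c.ln2, dg2[l], g2g, g2b);
    mat dA2 = use_drop ? mat(dR2 % c.drop2) : dR2;
    mat cWq, cWk, cWv, cWo;
    mat dN1 = dR2 + mha_bwd(dA2, dec_cross[l], H, c.cross, c.ln1.Y, memory,
                            toff, tlen, soff, slen, cWq, cWk, cWv, cWo, dMem);
    mat dR1 = ln_bwd(dN1, c.ln1, dg1[l], g1g, g1b);
    mat dA1 = use_drop ? mat(dR1 % c.drop1) : dR1;
    mat sWq, sWk, sWv, sWo;
    mat dSelfKV(c.Y_in.n_rows, d, arma::fill::zeros);
    mat dQ = mha_bwd(dA1, dec_self[l], H, c.self, c.Y_in, c.Y_in,
                     toff, tlen, toff, tlen, sWq, sWk, sWv, sWo, dSelfKV);
    dY = dR1 + dQ + dSelfKV;
    g_dec[l] = List::create(
      _["self_attn"] = List::create(_["Wq"] = sWq, _["Wk"] = sWk, _["Wv"] = sWv, _["Wo"] = sWo),
      _["ln1"] = List::create(_["g"] = rv(g1g), _["b"] = rv(g1b)),
      _["cross_attn"] = List::create(_["Wq"] = cWq, _["Wk"] = cWk, _["Wv"] = cWv, _["Wo"] = cWo),
      _["ln2"] = List::create(_["g"] = rv(g2g), _["b"] = rv(g2b)),
      _["ff"] = List::create(_["W1"] = gW1, _["b1"] = rv(gb1), _["W2"] = gW2, _["b2"] = rv(gb2)),
      _["ln3"] = List::create(_["g"] = rv(g3g), _["b"] = rv(g3b)));
  }
  if (use_drop) dY %= drop_tgt;
  mat g_tgt_emb(tgt_emb.n_rows, d, arma::fill::zeros);
  {
    mat contrib = dY * std::sqrt(double(d));
    for (uword i = 0; i < tids.n_elem; ++i) g_tgt_emb.row(tids[i]) += contrib.row(i);
  }

  mat dX = dMem;
  List g_enc(NE);
  for (int l = NE - 1; l >= 0; --l) {
    EncCache &c = ec[l];
    rowvec g2g, g2b, g1g, g1b;
    mat dR2 = ln_bwd(dX, c.ln2, enc_g2[l], g2g, g2b);
    mat dF = use_drop ? mat(dR2 % c.drop2) : dR2;
    mat gW1, gW2; rowvec gb1, gb2;
    mat dN1 = dR2 + ff_bwd(dF, enc_ff[l], c.ff, c.ln1.Y, gW1, gb1, gW2, gb2);
    mat dR1 = ln_bwd(dN1, c.ln1, enc_g1[l], g1g, g1b);
    mat dA = use_drop ? mat(dR1 % c.drop1) : dR1;
    mat aWq, aWk, aWv, aWo;
    mat dKV(c.X_in.n_rows, d, arma::fill::zeros);
    mat dQ = mha_bwd(dA, enc_attn[l], H, c.attn, c.X_in, c.X_in,
                     soff, slen, soff, slen, aWq, aWk, aWv, aWo, dKV);
    dX = dR1 + dQ + dKV;
    g_enc[l] = List::create(
      _["attn"] = List::create(_["Wq"] = aWq, _["Wk"] = aWk, _["Wv"] = aWv, _["Wo"] = aWo),
      _["ln1"] = List::create(_["g"] = rv(g1g), _["b"] = rv(g1b)),
      _["ff"] = List::create(_["W1"] = gW1, _["b1"] = rv(gb1), _["W2"] = gW2, _["b2"] = rv(gb2)),
      _["ln2"] = List::create(_["g"] = rv(g2g), _["b"] = rv(g2b)));
  }
  if (use_drop) dX %= drop_src;
  mat g_src_emb(src_emb.n_rows, d, arma::fill::zeros);
  {
    mat contrib = dX * std::sqrt(double(d));
    for (uword i = 0; i < sids.n_elem; ++i) g_src_emb.row(sids[i]) += contrib.row(i);
  }

  List grads = List::create(
    _["src_emb"] = g_src_emb, _["tgt_emb"] = g_tgt_emb,
    _["enc"] = g_enc, _["dec"] = g_dec,
    _["out"] = List::create(_["W"] = gWout, _["b"] = rv(gbout)));
  return List::create(_["loss"] = loss, _["n_tokens"] = n_tok, _["grads"] = grads);
}

// [[Rcpp::export]]
arma::mat cpp_encode_memory(List params, List cfg, IntegerVector src_ids) {
  int d = as<int>(cfg["d_model"]), H = as<int>(cfg["n_heads"]);
  List enc_par = params["enc"];
  mat src_emb = as<mat>(params["src_emb"]);
  arma::uvec ids = uvec_from(src_ids, -1);
  arma::uvec off(1); off[0] = 0;
  arma::uvec len(1); len[0] = ids.n_elem;
  mat X = embed(src_emb, ids, len, d);
  for (int l = 0; l < enc_par.size(); ++l) {
    List lp = enc_par[l];
    AttnP ap = attn_p(lp["attn"]); FFP fp = ff_p(lp["ff"]);
    List ln1 = lp["ln1"], ln2 = lp["ln2"];
    AttnCache a = mha_fwd(ap, H, X, X, off, len, off, len, false);
    LNCache n1 = ln_fwd(X + a.Out, as<rowvec>(ln1["g"]), as<rowvec>(ln1["b"]));
    FFCache f = ff_fwd(fp, n1.Y);
    X = ln_fwd(n1.Y + f.Y, as<rowvec>(ln2["g"]), as<rowvec>(ln2["b"])).Y;
  }
  return X;
}

// [[Rcpp::export]]
IntegerMatrix cpp_decode(List params, List cfg, arma::mat memory, int n,
                         double temperature, int max_steps,
                         int start_id, int end_id, bool greedy) {
  int d = as<int>(cfg["d_model"]), H = as<int>(cfg["n_heads"]);
  int dh = d / H;
  double scale = 1.0 / std::sqrt(double(dh));
  List dec_par = params["dec"], out_par = params["out"];
  int ND = dec_par.size();
  mat tgt_emb = as<mat>(params["tgt_emb"]);
  mat Wout = as<mat>(out_par["W"]);
  rowvec bout = as<rowvec>(out_par["b"]);
  int V = Wout.n_cols;

  std::vector<AttnP> self_p(ND), cross_p(ND);
  std::vector<FFP> ff(ND);
  std::vector<rowvec> g1(ND), b1(ND), g2(ND), b2(ND), g3(ND), b3(ND);
  std::vector<mat> crossK(ND), crossV(ND);
  for (int l = 0; l < ND; ++l) {
    List lp = dec_par[l];
    self_p[l] = attn_p(lp["self_attn"]); cross_p[l] = attn_p(lp["cross_attn"]);
    ff[l] = ff_p(lp["ff"]);
    List ln1 = lp["ln1"], ln2 = lp["ln2"], ln3 = lp["ln3"];
    g1[l] = as<rowvec>(ln1["g"]); b1[l] = as<rowvec>(ln1["b"]);
    g2[l] = as<rowvec>(ln2["g"]); b2[l] = as<rowvec>(ln2["b"]);
    g3[l] = as<rowvec>(ln3["g"]); b3[l] = as<rowvec>(ln3["b"]);
    crossK[l] = memory * cross_p[l].Wk;
    crossV[l] = memory * cross_p[l].Wv;
  }

  std::vector<arma::cube> Kc(ND), Vc(ND);
  for (int l = 0; l < ND; ++l) {
    Kc[l].set_size(n, d, max_steps);
    Vc[l].set_size(n, d, max_steps);
  }

  IntegerMatrix tokens(n, max_steps);
  arma::uvec cur(n); cur.fill(uword(start_id - 1));
  std::vector<bool> alive(n, true);
  int used_steps = max_steps;

  for (int t = 0; t < max_steps; ++t) {
    mat X = tgt_emb.rows(cur) * std::sqrt(double(d));
    arma::uvec pos(1); pos[0] = uword(t);
    rowvec pe = posenc(pos, d).row(0);
    X.each_row() += pe;

    for (int l = 0; l < ND; ++l) {
      mat Q = X * self_p[l].Wq;
      Kc[l].slice(t) = X * self_p[l].Wk;
      Vc[l].slice(t) = X * self_p[l].Wv;
      mat C(n, d, arma::fill::zeros);
      for (int h = 0; h < H; ++h) {
        uword c0 = uword(h) * dh, c1 = uword(h + 1) * dh - 1;
        mat S(n, t + 1);
        for (int j = 0; j <= t; ++j)
          S.col(j) = arma::sum(Q.cols(c0, c1) % Kc[l].slice(j).cols(c0, c1), 1) * scale;
        softmax_rows(S);
        mat Ch(n, dh, arma::fill::zeros);
        for (int j = 0; j <= t; ++j)
          Ch += Vc[l].slice(j).cols(c0, c1).each_col() % S.col(j);
        C.cols(c0, c1) = Ch;
      }
      mat A1 = C * self_p[l].Wo;
      LNCache n1 = ln_fwd(X + A1, g1[l], b1[l]);
      mat Qc = n1.Y * cross_p[l].Wq;
      mat C2(n, d, arma::fill::zeros);
      for (int h = 0; h < H; ++h) {
        uword c0 = uword(h) * dh, c1 = uword(h + 1) * dh - 1;
        mat S = Qc.cols(c0, c1) * crossK[l].cols(c0, c1).t() * scale;
        softmax_rows(S);
        C2.cols(c0, c1) = S * crossV[l].cols(c0, c1);
      }
      mat A2 = C2 * cross_p[l].Wo;
      LNCache n2 = ln_fwd(n1.Y + A2, g2[l], b2[l]);
      FFCache f = ff_fwd(ff[l], n2.Y);
      X = ln_fwd(n2.Y + f.Y, g3[l], b3[l]).Y;
    }

    mat logits = X * Wout;
    logits.each_row() += bout;
    if (greedy) {
      for (int i = 0; i < n; ++i) {
        if (!alive[i]) { tokens(i, t) = end_id; cur[i] = uword(end_id - 1); continue; }
        uword best = logits.row(i).index_max();
        tokens(i, t) = int(best) + 1;
        cur[i] = best;
        if (int(best) + 1 == end_id) alive[i] = false;
      }
    } else {
      logits /= temperature;
      vec mx = arma::max(logits, 1);
      mat Pr = arma::exp(logits.each_col() - mx);
      vec rs = arma::sum(Pr, 1);
      Pr.each_col() /= rs;
      for (int i = 0; i < n; ++i) {
        if (!alive[i]) { tokens(i, t) = end_id; cur[i] = uword(end_id - 1); continue; }
        double u = unif_rand(), acc = 0;
        int pick = V - 1;
        for (int j = 0; j < V; ++j) {
          acc += Pr(i, j);
          if (u <= acc) { pick = j; break; }
        }
        tokens(i, t) = pick + 1;
        cur[i] = uword(pick);
        if (pick + 1 == end_id) alive[i] = false;
      }
    }
    bool any_alive = false;
    for (int i = 0; i < n; ++i) if (alive[i]) { any_alive = true; break; }
    if (!any_alive) { used_steps = t + 1; break; }
  }
  if (used_steps < max_steps)
    return tokens(Range(0, n - 1), Range(0, used_steps - 1));
  return tokens;
}
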