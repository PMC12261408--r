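// Compiled engine for the convolution-transformer encoder: batch forward
// pass and analytic backward pass. Mirrors the base-R reference
// implementation in R/nn.R; the test suite asserts numerical agreement
// between the two engines.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat softmax_rows(arma::mat S) {
  S.each_col() -= arma::max(S, 1);
  arma::mat E = arma::exp(S);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

// rowwise layer norm; writes xhat and inv (1/sd per row)
static arma::mat ln_fwd(const arma::mat& x, const arma::rowvec& g,
                        const arma::rowvec& b, arma::mat& xhat,
                        arma::vec& inv) {
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  inv = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + 1e-5);
  xhat = xc.each_col() % inv;
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static arma::mat ln_bwd(const arma::mat& dy, const arma::mat& xhat,
                        const arma::vec& inv, const arma::rowvec& g,
                        arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dy % xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxh = dy.each_row() % g;
  arma::vec m1 = arma::mean(dxh, 1);
  arma::vec m2 = arma::mean(dxh % xhat, 1);
  arma::mat dx = dxh;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return dx;
}

// inverted dropout mask drawn from R's RNG (honours set.seed upstream)
static NumericVector rv(const arma::rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

static arma::mat drop_mask(arma::uword nr, arma::uword nc, double p) {
  NumericVector u = runif(nr * nc);
  arma::mat m(u.begin(), nr, nc, true);
  m.transform([p](double v) { return v >= p ? 1.0 / (1.0 - p) : 0.0; });
  return m;
}

// [[Rcpp::export(name = ".arma_encoder_forward")]]
List arma_encoder_forward(List ep, List Xlist, List cfg, bool training,
                          const arma::mat& pe) {
  const int w = as<int>(cfg["conv_kernel"]), s = as<int>(cfg["conv_stride"]);
  const int D = as<int>(cfg["model_width"]), h = as<int>(cfg["n_heads"]);
  const int nb = as<int>(cfg["n_blocks"]);
  const double pdrop = training ? as<double>(cfg["dropout"]) : 0.0;
  const int dk = D / h;
  const double scale = 1.0 / std::sqrt((double)dk);

  const int B = Xlist.size();
  arma::mat X0 = as<arma::mat>(Xlist[0]);
  const int S = X0.n_cols;
  if (S < w) stop("sequence length shorter than the convolution kernel");
  const int L = (S - w) / s + 1;

  List conv = ep["conv"];
  arma::mat Wc = as<arma::mat>(conv["W"]);      // (2w) x D
  arma::rowvec bc = as<arma::rowvec>(conv["b"]);

  arma::mat P(B * L, 2 * w);
  for (int i = 0; i < B; ++i) {
    arma::mat X = as<arma::mat>(Xlist[i]);      // 2 x S
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < w; ++c) {
        P(i * L + t, 2 * c) = X(0, t * s + c);
        P(i * L + t, 2 * c + 1) = X(1, t * s + c);
      }
    }
  }
  arma::mat T = P * Wc;
  T.each_row() += bc;
  if (pe.n_rows > 0)
    for (int i = 0; i < B; ++i)
      T.rows(i * L, i * L + L - 1) += pe.rows(0, L - 1);

  List blocks = ep["blocks"];
  List caches(nb);
  for (int bi = 0; bi < nb; ++bi) {
    List blk = blocks[bi];
    List at = blk["attn"], ln1 = blk["ln1"], ffn = blk["ffn"], ln2 = blk["ln2"];
    arma::mat Wq = as<arma::mat>(at["Wq"]), Wk = as<arma::mat>(at["Wk"]);
    arma::mat Wv = as<arma::mat>(at["Wv"]), Wo = as<arma::mat>(at["Wo"]);
    arma::rowvec bq = as<arma::rowvec>(at["bq"]), bk = as<arma::rowvec>(at["bk"]);
    arma::rowvec bv = as<arma::rowvec>(at["bv"]), bo = as<arma::rowvec>(at["bo"]);

    arma::mat Tin = T;
    arma::mat Q = Tin * Wq; Q.each_row() += bq;
    arma::mat K = Tin * Wk; K.each_row() += bk;
    arma::mat V = Tin * Wv; V.each_row() += bv;
    arma::mat O(B * L, D);
    arma::cube A(L, L, B * h);
    for (int i = 0; i < B; ++i) {
      const arma::uword r0 = i * L, r1 = i * L + L - 1;
      for (int hd = 0; hd < h; ++hd) {
        const arma::uword c0 = hd * dk, c1 = hd * dk + dk - 1;
        arma::mat Ah = softmax_rows(Q.submat(r0, c0, r1, c1) *
                                    K.submat(r0, c0, r1, c1).t() * scale);
        O.submat(r0, c0, r1, c1) = Ah * V.submat(r0, c0, r1, c1);
        A.slice(i * h + hd) = Ah;
      }
    }
    arma::mat O2 = O * Wo;
    O2.each_row() += bo;
    arma::mat m1;
    if (pdrop > 0) { m1 = drop_mask(O2.n_rows, O2.n_cols, pdrop); O2 %= m1; }
    arma::mat U1 = Tin + O2;
    arma::mat xh1; arma::vec inv1;
    arma::mat T1 = ln_fwd(U1, as<arma::rowvec>(ln1["g"]),
                          as<arma::rowvec>(ln1["b"]), xh1, inv1);
    arma::mat W1 = as<arma::mat>(ffn["W1"]), W2 = as<arma::mat>(ffn["W2"]);
    arma::rowvec b1 = as<arma::rowvec>(ffn["b1"]), b2 = as<arma::rowvec>(ffn["b2"]);
    arma::mat Hpre = T1 * W1;
    Hpre.each_row() += b1;
    arma::mat Hact = arma::clamp(Hpre, 0.0, arma::datum::inf);
    arma::mat F2 = Hact * W2;
    F2.each_row() += b2;
    arma::mat m2;
    if (pdrop > 0) { m2 = drop_mask(F2.n_rows, F2.n_cols, pdrop); F2 %= m2; }
    arma::mat U2 = T1 + F2;
    arma::mat xh2; arma::vec inv2;
    T = ln_fwd(U2, as<arma::rowvec>(ln2["g"]), as<arma::rowvec>(ln2["b"]),
               xh2, inv2);
    caches[bi] = List::create(
      _["Tin"] = Tin, _["Q"] = Q, _["K"] = K, _["V"] = V, _["A"] = A,
      _["O"] = O, _["m1"] = m1, _["xh1"] = xh1, _["inv1"] = inv1,
      _["T1"] = T1, _["relu"] = arma::mat(arma::conv_to<arma::mat>::from(Hpre > 0)),
      _["Hact"] = Hact, _["m2"] = m2, _["xh2"] = xh2, _["inv2"] = inv2);
  }
  arma::mat emb(B, D);
  for (int i = 0; i < B; ++i)
    emb.row(i) = arma::mean(T.rows(i * L, i * L + L - 1), 0);
  return List::create(_["emb"] = emb,
                      _["cache"] = List::create(_["P"] = P, _["blocks"] = caches,
                                                _["B"] = B, _["L"] = L));
}

// [[Rcpp::export(name = ".arma_encoder_backward")]]
List arma_encoder_backward(List ep, List cfg, List cache,
                           const arma::mat& dEmb, bool has_pos) {
  const int D = as<int>(cfg["model_width"]), h = as<int>(cfg["n_heads"]);
  const int nb = as<int>(cfg["n_blocks"]);
  const int dk = D / h;
  const double scale = 1.0 / std::sqrt((double)dk);
  const int B = as<int>(cache["B"]), L = as<int>(cache["L"]);
  List blocks = ep["blocks"], bcaches = cache["blocks"];

  arma::mat dT(B * L, D);
  for (int i = 0; i < B; ++i)
    dT.rows(i * L, i * L + L - 1) = arma::repmat(dEmb.row(i) / L, L, 1);

  List gblocks(nb);
  for (int bi = nb - 1; bi >= 0; --bi) {
    List blk = blocks[bi], ca = bcaches[bi];
    List at = blk["attn"], ln1 = blk["ln1"], ffn = blk["ffn"], ln2 = blk["ln2"];
    arma::rowvec dg2, db2v;
    arma::mat dU2 = ln_bwd(dT, as<arma::mat>(ca["xh2"]), as<arma::vec>(ca["inv2"]),
                           as<arma::rowvec>(ln2["g"]), dg2, db2v);
    arma::mat dF2 = dU2;
    if (!Rf_isNull(ca["m2"]) && as<arma::mat>(ca["m2"]).n_elem > 0)
      dF2 %= as<arma::mat>(ca["m2"]);
    arma::mat Hact = as<arma::mat>(ca["Hact"]);
    arma::mat W2 = as<arma::mat>(ffn["W2"]), W1 = as<arma::mat>(ffn["W1"]);
    arma::mat dW2 = Hact.t() * dF2;
    arma::rowvec db2 = arma::sum(dF2, 0);
    arma::mat dHpre = (dF2 * W2.t()) % as<arma::mat>(ca["relu"]);
    arma::mat T1 = as<arma::mat>(ca["T1"]);
    arma::mat dW1 = T1.t() * dHpre;
    arma::rowvec db1 = arma::sum(dHpre, 0);
    arma::mat dT1 = dU2 + dHpre * W1.t();
    arma::rowvec dg1, db1v;
    arma::mat dU1 = ln_bwd(dT1, as<arma::mat>(ca["xh1"]), as<arma::vec>(ca["inv1"]),
                           as<arma::rowvec>(ln1["g"]), dg1, db1v);
    arma::mat dO2 = dU1;
    if (!Rf_isNull(ca["m1"]) && as<arma::mat>(ca["m1"]).n_elem > 0)
      dO2 %= as<arma::mat>(ca["m1"]);
    arma::mat O = as<arma::mat>(ca["O"]);
    arma::mat Wo = as<arma::mat>(at["Wo"]);
    arma::mat dWo = O.t() * dO2;
    arma::rowvec dbo = arma::sum(dO2, 0);
    arma::mat dO = dO2 * Wo.t();

    arma::mat Q = as<arma::mat>(ca["Q"]), K = as<arma::mat>(ca["K"]);
    arma::mat V = as<arma::mat>(ca["V"]);
    arma::cube A = as<arma::cube>(ca["A"]);
    arma::mat dQ(B * L, D, arma::fill::zeros), dK = dQ, dV = dQ;
    for (int i = 0; i < B; ++i) {
      const arma::uword r0 = i * L, r1 = i * L + L - 1;
      for (int hd = 0; hd < h; ++hd) {
        const arma::uword c0 = hd * dk, c1 = hd * dk + dk - 1;
        const arma::mat& Ah = A.slice(i * h + hd);
        arma::mat dOh = dO.submat(r0, c0, r1, c1);
        arma::mat dAh = dOh * V.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = Ah.t() * dOh;
        arma::mat dS = dAh;
        dS.each_col() -= arma::sum(dAh % Ah, 1);
        dS %= Ah;
        dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    arma::mat Tin = as<arma::mat>(ca["Tin"]);
    List gat = List::create(
      _["Wq"] = Tin.t() * dQ, _["bq"] = rv(arma::sum(dQ, 0)),
      _["Wk"] = Tin.t() * dK, _["bk"] = rv(arma::sum(dK, 0)),
      _["Wv"] = Tin.t() * dV, _["bv"] = rv(arma::sum(dV, 0)),
      _["Wo"] = dWo, _["bo"] = rv(dbo));
    gblocks[bi] = List::create(
      _["attn"] = gat,
      _["ln1"] = List::create(_["g"] = rv(dg1),
                              _["b"] = rv(db1v)),
      _["ffn"] = List::create(_["W1"] = dW1, _["b1"] = rv(db1),
                              _["W2"] = dW2, _["b2"] = rv(db2)),
      _["ln2"] = List::create(_["g"] = rv(dg2),
                              _["b"] = rv(db2v)));
    dT = dU1 + dQ * as<arma::mat>(at["Wq"]).t() +
         dK * as<arma::mat>(at["Wk"]).t() + dV * as<arma::mat>(at["Wv"]).t();
  }
  arma::mat P = as<arma::mat>(cache["P"]);
  List g = List::create(
    _["conv"] = List::create(_["W"] = P.t() * dT,
                             _["b"] = rv(arma::sum(dT, 0))),
    _["blocks"] = gblocks);
  if (has_pos) {
    arma::mat ppos = as<arma::mat>(ep["pos"]);
    arma::mat dpe(ppos.n_rows, ppos.n_cols, arma::fill::zeros);
    for (int i = 0; i < B; ++i)
      dpe.rows(0, L - 1) += dT.rows(i * L, i * L + L - 1);
    g["pos"] = dpe;
  }
  return g;
}
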