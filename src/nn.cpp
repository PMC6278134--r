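// Neural predictor core: masked GRU branch, time-distributed dense branch,
// and the dual-input fusion, with analytic gradients for a weighted
// softmax cross-entropy head. Layout contracts with the R side:
//   - sequence input arrives as a cube (n, D, T): slice t is the n x D
//     matrix of timestep t (R permutes its n x T x D array once);
//   - masks are n x T with 1 on real rows, 0 on (leading) padding;
//   - per-example loss weights implement the imbalance objective's
//     weighted-cross-entropy form.
// All randomness (init, shuffling) lives in R; these routines are pure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PROB_CLIP = 1e-7;

struct GruParams {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  rowvec bz, br, bh;
};

static GruParams gru_from_list(const Rcpp::List& p) {
  GruParams g;
  g.Wz = Rcpp::as<mat>(p["Wz"]); g.Wr = Rcpp::as<mat>(p["Wr"]);
  g.Wh = Rcpp::as<mat>(p["Wh"]); g.Uz = Rcpp::as<mat>(p["Uz"]);
  g.Ur = Rcpp::as<mat>(p["Ur"]); g.Uh = Rcpp::as<mat>(p["Uh"]);
  g.bz = Rcpp::as<rowvec>(p["bz"]); g.br = Rcpp::as<rowvec>(p["br"]);
  g.bh = Rcpp::as<rowvec>(p["bh"]);
  return g;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruCache {
  std::vector<mat> z, r, c, h; // h has T+1 entries, h[0] = 0
};

// forward pass; returns final hidden state (n x H)
static mat gru_forward(const cube& X, const mat& mask, const GruParams& P,
                       GruCache& cache) {
  const uword n = X.n_rows, T = X.n_slices, H = P.Uz.n_rows;
  mat h(n, H, fill::zeros);
  cache.h.push_back(h);
  for (uword t = 0; t < T; ++t) {
    const mat& Xt = X.slice(t);
    vec m = mask.col(t);
    mat z = sigmoid(Xt * P.Wz + h * P.Uz + repmat(P.bz, n, 1));
    mat r = sigmoid(Xt * P.Wr + h * P.Ur + repmat(P.br, n, 1));
    mat c = tanh(Xt * P.Wh + (r % h) * P.Uh + repmat(P.bh, n, 1));
    mat hcand = (1.0 - z) % h + z % c;
    mat hnew = hcand.each_col() % m + h.each_col() % (1.0 - m);
    cache.z.push_back(z); cache.r.push_back(r); cache.c.push_back(c);
    cache.h.push_back(hnew);
    h = hnew;
  }
  return h;
}

// backward through time from d(final hidden); accumulates parameter grads
static void gru_backward(const cube& X, const mat& mask, const GruParams& P,
                         const GruCache& cache, mat dh,
                         Rcpp::List& grads) {
  const uword T = X.n_slices;
  mat dWz(size(P.Wz), fill::zeros), dWr(size(P.Wr), fill::zeros),
      dWh(size(P.Wh), fill::zeros), dUz(size(P.Uz), fill::zeros),
      dUr(size(P.Ur), fill::zeros), dUh(size(P.Uh), fill::zeros);
  rowvec dbz(P.bz.n_elem, fill::zeros), dbr(P.br.n_elem, fill::zeros),
         dbh(P.bh.n_elem, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& Xt = X.slice(t);
    const mat& z = cache.z[t];
    const mat& r = cache.r[t];
    const mat& c = cache.c[t];
    const mat& hprev = cache.h[t];
    vec m = mask.col(t);
    mat dhc = dh.each_col() % m;
    mat dh_prev = dh.each_col() % (1.0 - m);
    mat dz = dhc % (c - hprev) % z % (1.0 - z);
    mat dc = dhc % z % (1.0 - c % c);
    dh_prev += dhc % (1.0 - z);
    // candidate path
    dWh += Xt.t() * dc;
    dbh += sum(dc, 0);
    mat drh = dc * P.Uh.t();
    dUh += (r % hprev).t() * dc;
    mat dr = drh % hprev % r % (1.0 - r);
    dh_prev += drh % r;
    // update gate
    dWz += Xt.t() * dz;
    dUz += hprev.t() * dz;
    dbz += sum(dz, 0);
    dh_prev += dz * P.Uz.t();
    // reset gate
    dWr += Xt.t() * dr;
    dUr += hprev.t() * dr;
    dbr += sum(dr, 0);
    dh_prev += dr * P.Ur.t();
    dh = dh_prev;
  }
  grads["Wz"] = dWz; grads["Wr"] = dWr; grads["Wh"] = dWh;
  grads["Uz"] = dUz; grads["Ur"] = dUr; grads["Uh"] = dUh;
  grads["bz"] = dbz; grads["br"] = dbr; grads["bh"] = dbh;
}

struct MlpParams {
  mat Wt, W1, W2;
  rowvec bt, b1, b2;
};

static MlpParams mlp_from_list(const Rcpp::List& p) {
  MlpParams m;
  m.Wt = Rcpp::as<mat>(p["Wt"]); m.W1 = Rcpp::as<mat>(p["W1"]);
  m.W2 = Rcpp::as<mat>(p["W2"]);
  m.bt = Rcpp::as<rowvec>(p["bt"]); m.b1 = Rcpp::as<rowvec>(p["b1"]);
  m.b2 = Rcpp::as<rowvec>(p["b2"]);
  return m;
}

struct MlpCache {
  std::vector<mat> A; // per-timestep activations
  mat F, H1, H2;
};

// shared per-timestep dense (relu) -> flatten -> dense stack (relu)
static mat mlp_forward(const cube& X, const MlpParams& P, MlpCache& cache) {
  const uword n = X.n_rows, T = X.n_slices, K = P.Wt.n_cols;
  cache.F.set_size(n, T * K);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * P.Wt + repmat(P.bt, n, 1);
    A.transform([](double v) { return v > 0 ? v : 0.0; });
    cache.A.push_back(A);
    cache.F.cols(t * K, (t + 1) * K - 1) = A;
  }
  cache.H1 = cache.F * P.W1 + repmat(P.b1, n, 1);
  cache.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  cache.H2 = cache.H1 * P.W2 + repmat(P.b2, n, 1);
  cache.H2.transform([](double v) { return v > 0 ? v : 0.0; });
  return cache.H2;
}

static void mlp_backward(const cube& X, const MlpParams& P,
                         const MlpCache& cache, const mat& dH2,
                         Rcpp::List& grads) {
  const uword T = X.n_slices, K = P.Wt.n_cols;
  mat d2 = dH2 % conv_to<mat>::from(cache.H2 > 0);
  grads["W2"] = cache.H1.t() * d2;
  grads["b2"] = rowvec(sum(d2, 0));
  mat d1 = (d2 * P.W2.t()) % conv_to<mat>::from(cache.H1 > 0);
  grads["W1"] = cache.F.t() * d1;
  grads["b1"] = rowvec(sum(d1, 0));
  mat dF = d1 * P.W1.t();
  mat dWt(size(P.Wt), fill::zeros);
  rowvec dbt(P.bt.n_elem, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat dA = dF.cols(t * K, (t + 1) * K - 1) % conv_to<mat>::from(cache.A[t] > 0);
    dWt += X.slice(t).t() * dA;
    dbt += sum(dA, 0);
  }
  grads["Wt"] = dWt;
  grads["bt"] = dbt;
}

// softmax over 2 logit columns; returns probs, fills loss and dlogits
static mat head_loss(const mat& logits, const vec& y, const vec& w,
                     double& loss, mat& dlogits, bool want_grad) {
  const uword n = logits.n_rows;
  mat shifted = logits.each_col() - max(logits, 1);
  mat e = exp(shifted);
  mat probs = e.each_col() / sum(e, 1);
  loss = 0.0;
  for (uword i = 0; i < n; ++i) {
    double pt = y(i) > 0.5 ? probs(i, 1) : probs(i, 0);
    loss += -w(i) * std::log(std::max(pt, PROB_CLIP));
  }
  if (want_grad) {
    dlogits = probs;
    for (uword i = 0; i < n; ++i) {
      dlogits(i, y(i) > 0.5 ? 1 : 0) -= 1.0;
      dlogits.row(i) *= w(i);
    }
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List nn_m1(const arma::cube& X, const arma::mat& mask,
                 const Rcpp::List& params, const arma::vec& y,
                 const arma::vec& w, bool grad, bool hidden) {
  GruParams P = gru_from_list(params);
  mat Wo = Rcpp::as<mat>(params["Wo"]);
  rowvec bo = Rcpp::as<rowvec>(params["bo"]);
  GruCache cache;
  mat h = gru_forward(X, mask, P, cache);
  mat logits = h * Wo + repmat(bo, h.n_rows, 1);
  double loss; mat dlogits;
  mat probs = head_loss(logits, y, w, loss, dlogits, grad);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs,
                                      Rcpp::Named("loss") = loss);
  if (grad) {
    Rcpp::List g;
    g["Wo"] = mat(h.t() * dlogits);
    g["bo"] = rowvec(sum(dlogits, 0));
    mat dh = dlogits * Wo.t();
    gru_backward(X, mask, P, cache, dh, g);
    out["grads"] = g;
  }
  if (hidden) out["hidden"] = h;
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_m2(const arma::cube& X, const Rcpp::List& params,
                 const arma::vec& y, const arma::vec& w, bool grad,
                 bool hidden) {
  MlpParams P = mlp_from_list(params);
  mat Wo = Rcpp::as<mat>(params["Wo"]);
  rowvec bo = Rcpp::as<rowvec>(params["bo"]);
  MlpCache cache;
  mat H2 = mlp_forward(X, P, cache);
  mat logits = H2 * Wo + repmat(bo, H2.n_rows, 1);
  double loss; mat dlogits;
  mat probs = head_loss(logits, y, w, loss, dlogits, grad);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs,
                                      Rcpp::Named("loss") = loss);
  if (grad) {
    Rcpp::List g;
    g["Wo"] = mat(H2.t() * dlogits);
    g["bo"] = rowvec(sum(dlogits, 0));
    mat dH2 = dlogits * Wo.t();
    mlp_backward(X, P, cache, dH2, g);
    out["grads"] = g;
  }
  if (hidden) out["hidden"] = H2;
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_m3(const arma::cube& Xd, const arma::mat& mask,
                 const arma::cube& Xe, const Rcpp::List& params,
                 const arma::vec& y, const arma::vec& w, bool grad,
                 bool hidden) {
  GruParams Pg = gru_from_list(params);
  MlpParams Pm = mlp_from_list(params);
  mat Wf = Rcpp::as<mat>(params["Wf"]);
  rowvec bf = Rcpp::as<rowvec>(params["bf"]);
  mat Wo = Rcpp::as<mat>(params["Wo"]);
  rowvec bo = Rcpp::as<rowvec>(params["bo"]);
  GruCache gc;
  MlpCache mc;
  mat hD = gru_forward(Xd, mask, Pg, gc);
  mat hE = mlp_forward(Xe, Pm, mc);
  mat C = join_rows(hD, hE);
  mat Fz = C * Wf + repmat(bf, C.n_rows, 1);
  Fz.transform([](double v) { return v > 0 ? v : 0.0; });
  mat logits = Fz * Wo + repmat(bo, Fz.n_rows, 1);
  double loss; mat dlogits;
  mat probs = head_loss(logits, y, w, loss, dlogits, grad);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs,
                                      Rcpp::Named("loss") = loss);
  if (grad) {
    Rcpp::List g;
    g["Wo"] = mat(Fz.t() * dlogits);
    g["bo"] = rowvec(sum(dlogits, 0));
    mat dFz = (dlogits * Wo.t()) % conv_to<mat>::from(Fz > 0);
    g["Wf"] = mat(C.t() * dFz);
    g["bf"] = rowvec(sum(dFz, 0));
    mat dC = dFz * Wf.t();
    mat dhD = dC.cols(0, hD.n_cols - 1);
    mat dhE = dC.cols(hD.n_cols, dC.n_cols - 1);
    gru_backward(Xd, mask, Pg, gc, dhD, g);
    mlp_backward(Xe, Pm, mc, dhE, g);
    out["grads"] = g;
  }
  if (hidden) {
    out["hidden_d"] = hD;
    out["hidden_e"] = hE;
  }
  return out;
}
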