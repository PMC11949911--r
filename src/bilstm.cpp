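// Bidirectional-LSTM multi-output regressor with a dense head
// (batch-norm -> SiLU -> dropout per layer) and a sigmoid output layer,
// trained with minibatch Adam on mean squared error. The sequence input is
// shared across trials of the same stimulus, so the embedding tensor is
// passed once (T x D x S cube) with a per-trial stimulus index.
//
// Weight layout (flat list, in order):
//   Wx_f (D x 4H), Wh_f (H x 4H), b_f (1 x 4H),
//   Wx_b, Wh_b, b_b,
//   per dense layer: W (in x w), b (1 x w), gamma, beta, rmean, rvar (1 x w),
//   W_out (last x K), b_out (1 x K)
// Gate order within 4H blocks: input, forget, cell, output.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::rowvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

static mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Dims {
  int D, H, P, K, T;
  std::vector<int> widths;
};

static Dims dimsFromWeights(const std::vector<mat>& W, int T) {
  Dims d;
  d.T = T;
  d.D = W[0].n_rows;
  d.H = W[1].n_rows;
  int nDense = (W.size() - 8) / 6;
  d.widths.resize(nDense);
  int idx = 6;
  for (int l = 0; l < nDense; ++l) {
    d.widths[l] = W[idx].n_cols;
    idx += 6;
  }
  d.P = W[6].n_rows - 2 * d.H;  // first dense input = 2H + covariates
  d.K = W[W.size() - 2].n_cols;
  return d;
}

static std::vector<mat> listToWeights(List w) {
  std::vector<mat> out;
  for (int i = 0; i < w.size(); ++i)
    out.push_back(as<mat>(w[i]));
  return out;
}

static List weightsToList(const std::vector<mat>& w, CharacterVector nm) {
  List out(w.size());
  for (size_t i = 0; i < w.size(); ++i) out[i] = wrap(w[i]);
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export(name = ".lstmInit")]]
List lstm_init(int D, int H, int P, IntegerVector denseWidths, int K,
               int seed) {
  std::mt19937_64 rng(seed);
  auto glorot = [&](int nin, int nout) {
    double lim = std::sqrt(6.0 / (nin + nout));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat m(nin, nout);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i) m(i, j) = U(rng);
    return m;
  };
  std::vector<mat> w;
  std::vector<std::string> nm;
  for (int dir = 0; dir < 2; ++dir) {
    std::string sfx = dir == 0 ? "_f" : "_b";
    w.push_back(glorot(D, 4 * H)); nm.push_back("Wx" + sfx);
    w.push_back(glorot(H, 4 * H)); nm.push_back("Wh" + sfx);
    mat b(1, 4 * H, arma::fill::zeros);
    b.cols(H, 2 * H - 1).fill(1.0);  // forget-gate bias
    w.push_back(b); nm.push_back("b" + sfx);
  }
  int in = 2 * H + P;
  for (int l = 0; l < denseWidths.size(); ++l) {
    int out = denseWidths[l];
    std::string s = std::to_string(l + 1);
    w.push_back(glorot(in, out)); nm.push_back("W" + s);
    w.push_back(mat(1, out, arma::fill::zeros)); nm.push_back("b" + s);
    w.push_back(mat(1, out, arma::fill::ones)); nm.push_back("gamma" + s);
    w.push_back(mat(1, out, arma::fill::zeros)); nm.push_back("beta" + s);
    w.push_back(mat(1, out, arma::fill::zeros)); nm.push_back("rmean" + s);
    w.push_back(mat(1, out, arma::fill::ones)); nm.push_back("rvar" + s);
    in = out;
  }
  w.push_back(glorot(in, K)); nm.push_back("W_out");
  w.push_back(mat(1, K, arma::fill::zeros)); nm.push_back("b_out");
  return weightsToList(w, wrap(nm));
}

// Forward pass state kept for backprop.
struct LstmTrace {
  cube G;       // B x 4H x T, post-activation gates
  cube C;       // B x H x T, cell states
  cube Hs;      // B x H x T, hidden states
};

// One-direction LSTM over the (already direction-ordered) timestep list.
static mat lstmForward(const std::vector<mat>& X, const mat& Wx,
                       const mat& Wh, const mat& b, LstmTrace* tr) {
  int T = X.size(), B = X[0].n_rows, H = Wh.n_rows;
  if (tr) {
    tr->G.set_size(B, 4 * H, T);
    tr->C.set_size(B, H, T);
    tr->Hs.set_size(B, H, T);
  }
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat A = X[t] * Wx + h * Wh + arma::repmat(b, B, 1);
    mat gi = sigm(A.cols(0, H - 1));
    mat gf = sigm(A.cols(H, 2 * H - 1));
    mat gg = arma::tanh(A.cols(2 * H, 3 * H - 1));
    mat go = sigm(A.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    if (tr) {
      tr->G.slice(t) = arma::join_rows(arma::join_rows(gi, gf),
                                       arma::join_rows(gg, go));
      tr->C.slice(t) = c;
      tr->Hs.slice(t) = h;
    }
  }
  return h;  // final hidden state
}

// BPTT for one direction; accumulates dWx, dWh, db. dhT is the gradient at
// the final hidden state.
static void lstmBackward(const std::vector<mat>& X, const mat& Wx,
                         const mat& Wh, const LstmTrace& tr, const mat& dhT,
                         mat& dWx, mat& dWh, mat& db) {
  int T = X.size(), B = X[0].n_rows, H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(1, 4 * H);
  mat dh = dhT;
  mat dc(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat gi = tr.G.slice(t).cols(0, H - 1);
    mat gf = tr.G.slice(t).cols(H, 2 * H - 1);
    mat gg = tr.G.slice(t).cols(2 * H, 3 * H - 1);
    mat go = tr.G.slice(t).cols(3 * H, 4 * H - 1);
    mat ct = tr.C.slice(t);
    mat tc = arma::tanh(ct);
    mat cPrev = t > 0 ? mat(tr.C.slice(t - 1))
                      : mat(B, H, arma::fill::zeros);
    mat hPrev = t > 0 ? mat(tr.Hs.slice(t - 1))
                      : mat(B, H, arma::fill::zeros);
    mat do_ = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat di = dc % gg;
    mat dg = dc % gi;
    mat df = dc % cPrev;
    mat dcPrev = dc % gf;
    mat dG = arma::join_rows(
        arma::join_rows(di % gi % (1.0 - gi), df % gf % (1.0 - gf)),
        arma::join_rows(dg % (1.0 - gg % gg), do_ % go % (1.0 - go)));
    dWx += X[t].t() * dG;
    dWh += hPrev.t() * dG;
    db += arma::sum(dG, 0);
    dh = dG * Wh.t();
    dc = dcPrev;
  }
}

// Gather per-timestep input matrices for a batch of trials.
static std::vector<mat> gatherSeq(const cube& E, const arma::uvec& stim,
                                  bool reverse) {
  int T = E.n_rows, B = stim.n_elem, D = E.n_cols;
  std::vector<mat> X(T, mat(B, D));
  for (int t = 0; t < T; ++t) {
    int tt = reverse ? (T - 1 - t) : t;
    for (int i = 0; i < B; ++i)
      X[t].row(i) = E.slice(stim[i]).row(tt);
  }
  return X;
}

struct DenseTrace {
  std::vector<mat> in, xhat, bnOut, act, mask;
  std::vector<rowvec> mu, invstd;
};

// Dense head forward. In training mode uses batch statistics (updating the
// running ones) and applies inverted dropout with the supplied RNG.
static mat denseForward(const mat& z0, std::vector<mat>& W, const Dims& d,
                        bool train, double dropout, std::mt19937_64* rng,
                        DenseTrace* tr) {
  mat z = z0;
  int idx = 6;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (size_t l = 0; l < d.widths.size(); ++l) {
    mat& Wl = W[idx]; mat& bl = W[idx + 1];
    mat& gam = W[idx + 2]; mat& bet = W[idx + 3];
    mat& rmean = W[idx + 4]; mat& rvar = W[idx + 5];
    mat a = z * Wl + arma::repmat(bl, z.n_rows, 1);
    rowvec mu, var;
    if (train) {
      mu = arma::mean(a, 0);
      var = arma::var(a, 1, 0);  // population variance
      int B = a.n_rows;
      rmean = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu;
      rvar = (1 - BN_MOMENTUM) * rvar +
             BN_MOMENTUM * var * ((double)B / std::max(1, B - 1));
    } else {
      mu = rmean.row(0);
      var = rvar.row(0);
    }
    rowvec invstd = 1.0 / arma::sqrt(var + BN_EPS);
    mat xhat = (a - arma::repmat(mu, a.n_rows, 1)) %
               arma::repmat(invstd, a.n_rows, 1);
    mat y = xhat % arma::repmat(gam, a.n_rows, 1) +
            arma::repmat(bet, a.n_rows, 1);
    mat s = sigm(y);
    mat act = y % s;  // SiLU
    mat msk;
    if (train && dropout > 0) {
      msk.set_size(act.n_rows, act.n_cols);
      for (arma::uword j = 0; j < msk.n_cols; ++j)
        for (arma::uword i = 0; i < msk.n_rows; ++i)
          msk(i, j) = (U(*rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      act = act % msk;
    }
    if (tr) {
      tr->in.push_back(z); tr->xhat.push_back(xhat);
      tr->bnOut.push_back(y); tr->act.push_back(act);
      tr->mask.push_back(msk); tr->mu.push_back(mu);
      tr->invstd.push_back(invstd);
    }
    z = act;
    idx += 6;
  }
  return z;
}

// [[Rcpp::export(name = ".lstmPredict")]]
NumericMatrix lstm_predict(List weights, arma::cube E,
                           IntegerVector stimIdx, arma::mat C) {
  std::vector<mat> W = listToWeights(weights);
  Dims d = dimsFromWeights(W, E.n_rows);
  arma::uvec stim(stimIdx.size());
  for (int i = 0; i < stimIdx.size(); ++i) stim[i] = stimIdx[i];
  std::vector<mat> Xf = gatherSeq(E, stim, false);
  std::vector<mat> Xb = gatherSeq(E, stim, true);
  mat hf = lstmForward(Xf, W[0], W[1], W[2], nullptr);
  mat hb = lstmForward(Xb, W[3], W[4], W[5], nullptr);
  mat z0 = arma::join_rows(arma::join_rows(hf, hb), C);
  mat z = denseForward(z0, W, d, false, 0.0, nullptr, nullptr);
  int oi = 6 + 6 * d.widths.size();
  mat yhat = sigm(z * W[oi] + arma::repmat(W[oi + 1], z.n_rows, 1));
  return wrap(yhat);
}

struct Adam {
  std::vector<mat> m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat>& W, double lr_) {
    lr = lr_;
    for (auto& w : W) {
      m.push_back(mat(w.n_rows, w.n_cols, arma::fill::zeros));
      v.push_back(mat(w.n_rows, w.n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<mat>& W, const std::vector<mat>& G,
            const std::vector<bool>& update) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < W.size(); ++i) {
      if (!update[i]) continue;
      m[i] = b1 * m[i] + (1 - b1) * G[i];
      v[i] = b2 * v[i] + (1 - b2) * (G[i] % G[i]);
      W[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export(name = ".lstmTrain")]]
List lstm_train(List weights, arma::cube E, IntegerVector stimIdx,
                arma::mat C, arma::mat Y, int epochs, int batchSize,
                double lr, double dropout, int seed,
                bool gradCheck = false) {
  std::vector<mat> W = listToWeights(weights);
  CharacterVector nm = weights.attr("names");
  Dims d = dimsFromWeights(W, E.n_rows);
  int n = stimIdx.size();
  int nDense = d.widths.size();
  int oi = 6 + 6 * nDense;
  std::mt19937_64 rng(seed);
  // running-stat slots (rmean/rvar) are not Adam-updated
  std::vector<bool> upd(W.size(), true);
  for (int l = 0; l < nDense; ++l) {
    upd[6 + 6 * l + 4] = false;
    upd[6 + 6 * l + 5] = false;
  }
  Adam adam;
  adam.init(W, lr);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector lossTrace(epochs);
  List gradOut;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epLoss = 0.0;
    long epCount = 0;
    for (int start = 0; start < n; start += batchSize) {
      int B = std::min(batchSize, n - start);
      if (B < 2) continue;  // batch norm needs >= 2 samples
      arma::uvec stim(B);
      mat Cb(B, C.n_cols), Yb(B, Y.n_cols);
      for (int i = 0; i < B; ++i) {
        int r = order[start + i];
        stim[i] = stimIdx[r];
        Cb.row(i) = C.row(r);
        Yb.row(i) = Y.row(r);
      }
      std::vector<mat> Xf = gatherSeq(E, stim, false);
      std::vector<mat> Xb = gatherSeq(E, stim, true);
      LstmTrace trF, trB;
      mat hf = lstmForward(Xf, W[0], W[1], W[2], &trF);
      mat hb = lstmForward(Xb, W[3], W[4], W[5], &trB);
      mat z0 = arma::join_rows(arma::join_rows(hf, hb), Cb);
      DenseTrace dtr;
      mat z = denseForward(z0, W, d, true, dropout, &rng, &dtr);
      mat logits = z * W[oi] + arma::repmat(W[oi + 1], B, 1);
      mat yhat = sigm(logits);
      mat err = yhat - Yb;
      double loss = arma::accu(err % err) / (B * d.K);
      epLoss += loss * B;
      epCount += B;
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      // ---- backward ----
      std::vector<mat> G(W.size());
      for (size_t i = 0; i < W.size(); ++i)
        G[i] = mat(W[i].n_rows, W[i].n_cols, arma::fill::zeros);
      mat dyhat = 2.0 * err / (B * d.K);
      mat dlogits = dyhat % yhat % (1.0 - yhat);
      G[oi] = z.t() * dlogits;
      G[oi + 1] = arma::sum(dlogits, 0);
      mat dz = dlogits * W[oi].t();
      for (int l = nDense - 1; l >= 0; --l) {
        int base = 6 + 6 * l;
        if (dropout > 0 && dtr.mask[l].n_elem > 0)
          dz = dz % dtr.mask[l];
        // SiLU backward
        mat y = dtr.bnOut[l];
        mat s = sigm(y);
        mat dy = dz % (s % (1.0 + y % (1.0 - s)));
        // batch-norm backward (batch statistics)
        mat xhat = dtr.xhat[l];
        G[base + 2] = arma::sum(dy % xhat, 0);  // gamma
        G[base + 3] = arma::sum(dy, 0);         // beta
        mat dxhat = dy % arma::repmat(W[base + 2], B, 1);
        rowvec sumDx = arma::sum(dxhat, 0);
        rowvec sumDxX = arma::sum(dxhat % xhat, 0);
        mat da = (dxhat - arma::repmat(sumDx / B, B, 1) -
                  xhat % arma::repmat(sumDxX / B, B, 1)) %
                 arma::repmat(dtr.invstd[l], B, 1);
        G[base] = dtr.in[l].t() * da;
        G[base + 1] = arma::sum(da, 0);
        dz = da * W[base].t();
      }
      mat dhf = dz.cols(0, d.H - 1);
      mat dhb = dz.cols(d.H, 2 * d.H - 1);
      mat dWx, dWh, db;
      lstmBackward(Xf, W[0], W[1], trF, dhf, dWx, dWh, db);
      G[0] = dWx; G[1] = dWh; G[2] = db;
      lstmBackward(Xb, W[3], W[4], trB, dhb, dWx, dWh, db);
      G[3] = dWx; G[4] = dWh; G[5] = db;
      if (gradCheck) {  // expose first-batch gradients, skip the update
        gradOut = weightsToList(G, nm);
        return List::create(_["weights"] = weightsToList(W, nm),
                            _["loss"] = loss, _["grads"] = gradOut);
      }
      adam.step(W, G, upd);
    }
    lossTrace[ep] = epCount > 0 ? epLoss / epCount : NA_REAL;
  }
  return List::create(_["weights"] = weightsToList(W, nm),
                      _["lossTrace"] = lossTrace);
}
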