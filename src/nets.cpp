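// Minibatch trainers for the victim classifiers: a feed-forward net (zero
// hidden layers = logistic regression), and single-layer LSTM / GRU
// sequence classifiers with a last-step sigmoid readout. Binary
// cross-entropy loss, Adam updates, deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat*> params;
  std::vector<mat> m, v;
  explicit Adam(double lr_) : lr(lr_) {}
  void track(mat& p) {
    params.push_back(&p);
    m.push_back(zeros(p.n_rows, p.n_cols));
    v.push_back(zeros(p.n_rows, p.n_cols));
  }
  void step(const std::vector<mat>& g) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * square(g[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

mat glorot(int nin, int nout, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (nin + nout));
  std::uniform_real_distribution<double> U(-lim, lim);
  mat W(nin, nout);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = U(rng);
  return W;
}

inline mat sig(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

inline double bce_from_logits(const mat& logits, const vec& y) {
  vec l = logits.col(0);
  vec zl = zeros(l.n_elem);
  return mean(arma::max(l, zl) - l % y + log(1.0 + exp(-abs(l))));
}

std::vector<uvec> make_batches(uword n, uword batch, std::mt19937_64& rng) {
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  std::vector<uvec> out;
  for (uword s = 0; s < n; s += batch) {
    uword e = std::min(s + batch, n);
    uvec b(e - s);
    for (uword i = s; i < e; ++i) b[i - s] = idx[i];
    out.push_back(b);
  }
  return out;
}

void clip_grads(std::vector<mat>& g, double max_norm) {
  double ss = 0;
  for (auto& gi : g) ss += accu(square(gi));
  double nrm = std::sqrt(ss);
  if (nrm > max_norm)
    for (auto& gi : g) gi *= max_norm / nrm;
}


fmat fglorot(int nin, int nout, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (nin + nout));
  std::uniform_real_distribution<double> U(-lim, lim);
  fmat W(nin, nout);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = (float)U(rng);
  return W;
}

inline fmat fsig(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

inline double fbce_from_logits(const fmat& logits, const fvec& y) {
  fvec l = logits.col(0);
  fvec zl = zeros<fvec>(l.n_elem);
  return mean(arma::max(l, zl) - l % y + log(1.0f + exp(-abs(l))));
}

struct FAdam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<fmat*> params;
  std::vector<fmat> m, v;
  explicit FAdam(double lr_) : lr(lr_) {}
  void track(fmat& p) {
    params.push_back(&p);
    m.push_back(zeros<fmat>(p.n_rows, p.n_cols));
    v.push_back(zeros<fmat>(p.n_rows, p.n_cols));
  }
  void step(const std::vector<fmat>& g) {
    ++t;
    float c1 = 1.0f - (float)std::pow(b1, (double)t);
    float c2 = 1.0f - (float)std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = (float)b1 * m[i] + (1.0f - (float)b1) * g[i];
      v[i] = (float)b2 * v[i] + (1.0f - (float)b2) * square(g[i]);
      *params[i] -= (float)lr * (m[i] / c1) / (sqrt(v[i] / c2) + (float)eps);
    }
  }
};

void fclip_grads(std::vector<fmat>& g, float max_norm) {
  double ss = 0;
  for (auto& gi : g) ss += accu(square(gi));
  float nrm = (float)std::sqrt(ss);
  if (nrm > max_norm)
    for (auto& gi : g) gi *= max_norm / nrm;
}

}  // namespace

// ---------------------------------------------------------------- MLP / LR

// [[Rcpp::export]]
Rcpp::List mlp_train(const arma::mat& X, const arma::vec& y,
                     const arma::ivec& hidden, int epochs, int batch,
                     double lr, double wd, int seed) {
  std::mt19937_64 rng(seed);
  std::vector<int> sizes;
  sizes.push_back(X.n_cols);
  for (uword i = 0; i < hidden.n_elem; ++i) sizes.push_back(hidden[i]);
  sizes.push_back(1);
  int L = sizes.size() - 1;

  std::vector<mat> W(L), b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = glorot(sizes[l], sizes[l + 1], rng);
    b[l] = zeros(1, sizes[l + 1]);
  }
  Adam opt(lr);
  for (int l = 0; l < L; ++l) { opt.track(W[l]); opt.track(b[l]); }

  std::vector<double> epoch_loss;
  for (int ep = 0; ep < epochs; ++ep) {
    auto batches = make_batches(X.n_rows, batch, rng);
    double tot = 0; uword cnt = 0;
    for (auto& rows : batches) {
      mat Xb = X.rows(rows);
      vec yb = y.elem(rows);
      uword B = Xb.n_rows;
      std::vector<mat> A(L), H(L + 1);
      H[0] = Xb;
      for (int l = 0; l < L; ++l) {
        A[l] = H[l] * W[l];
        A[l].each_row() += b[l];
        H[l + 1] = (l == L - 1) ? A[l] : arma::max(A[l], zeros(A[l].n_rows, A[l].n_cols));
      }
      mat P = sig(A[L - 1]);
      double loss = bce_from_logits(A[L - 1], yb);
      if (!std::isfinite(loss)) Rcpp::stop("training diverged");
      tot += loss * B; cnt += B;

      mat delta = (P - repmat(yb, 1, 1)) / (double)B;
      std::vector<mat> g(2 * L);
      for (int l = L - 1; l >= 0; --l) {
        g[2 * l] = H[l].t() * delta + wd * W[l];
        g[2 * l + 1] = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(A[l - 1] > 0);
        }
      }
      opt.step(g);
    }
    epoch_loss.push_back(tot / cnt);
  }
  Rcpp::List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) { Wl[l] = W[l]; bl[l] = b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl,
                            Rcpp::Named("log") = epoch_loss);
}

// [[Rcpp::export]]
arma::vec mlp_predict(const Rcpp::List& params, const arma::mat& X) {
  Rcpp::List Wl = params["W"], bl = params["b"];
  int L = Wl.size();
  mat H = X;
  for (int l = 0; l < L; ++l) {
    mat W = Wl[l], b = bl[l];
    mat A = H * W;
    A.each_row() += b.row(0);
    H = (l == L - 1) ? A : arma::max(A, zeros(A.n_rows, A.n_cols));
  }
  return sig(H).col(0);
}

// ---------------------------------------------------------------- LSTM/GRU
// X is n x (T*F), step t occupying columns [t*F, (t+1)*F).

// [[Rcpp::export]]
Rcpp::List rnn_train(const arma::mat& X_, const arma::vec& y_, int T, int F,
                     int H, const std::string& kind, int epochs, int batch,
                     double lr, double wd, int seed) {
  // single precision throughout: the victims are standard deep-learning
  // models and fp32 doubles the throughput of the matrix kernels
  fmat X = conv_to<fmat>::from(X_);
  fvec y = conv_to<fvec>::from(y_);
  bool lstm = (kind == "lstm");
  int G = lstm ? 4 : 2;  // gate blocks in the fused matrices
  std::mt19937_64 rng(seed);

  fmat Wx = fglorot(F, G * H, rng);
  fmat Wh = fglorot(H, G * H, rng);
  fmat bg = zeros<fmat>(1, G * H);
  if (lstm) bg.cols(H, 2 * H - 1).fill(1.0f);  // forget-gate bias
  // GRU candidate weights (unused for LSTM)
  fmat Wxn = lstm ? fmat() : fglorot(F, H, rng);
  fmat Whn = lstm ? fmat() : fglorot(H, H, rng);
  fmat bn = zeros<fmat>(1, H);
  fmat wout = fglorot(H, 1, rng);
  fmat bout = zeros<fmat>(1, 1);

  FAdam opt(lr);
  opt.track(Wx); opt.track(Wh); opt.track(bg);
  if (!lstm) { opt.track(Wxn); opt.track(Whn); opt.track(bn); }
  opt.track(wout); opt.track(bout);

  std::vector<double> epoch_loss;
  for (int ep = 0; ep < epochs; ++ep) {
    auto batches = make_batches(X.n_rows, batch, rng);
    double tot = 0; uword cnt = 0;
    for (auto& rows : batches) {
      fmat Xb = X.rows(rows);
      fvec yb = y.elem(rows);
      uword B = Xb.n_rows;

      std::vector<fmat> hs(T + 1), cs(T + 1), I(T), Fg(T), Gg(T), O(T),
          TC(T), Z(T), R(T), N(T);
      hs[0] = zeros<fmat>(B, H); cs[0] = zeros<fmat>(B, H);
      for (int t = 0; t < T; ++t) {
        fmat Xt = Xb.cols(t * F, (t + 1) * F - 1);
        fmat A = Xt * Wx + hs[t] * Wh;
        A.each_row() += bg;
        if (lstm) {
          I[t] = fsig(A.cols(0, H - 1));
          Fg[t] = fsig(A.cols(H, 2 * H - 1));
          Gg[t] = tanh(A.cols(2 * H, 3 * H - 1));
          O[t] = fsig(A.cols(3 * H, 4 * H - 1));
          cs[t + 1] = Fg[t] % cs[t] + I[t] % Gg[t];
          TC[t] = tanh(cs[t + 1]);
          hs[t + 1] = O[t] % TC[t];
        } else {
          Z[t] = fsig(A.cols(0, H - 1));
          R[t] = fsig(A.cols(H, 2 * H - 1));
          fmat An = Xt * Wxn + (R[t] % hs[t]) * Whn;
          An.each_row() += bn;
          N[t] = tanh(An);
          hs[t + 1] = (1.0f - Z[t]) % N[t] + Z[t] % hs[t];
        }
      }
      fmat logit = hs[T] * wout;
      logit.each_row() += bout;
      fmat P = fsig(logit);
      double loss = fbce_from_logits(logit, yb);
      if (!std::isfinite(loss)) Rcpp::stop("training diverged");
      tot += loss * B; cnt += B;

      fmat dlogit = (P - repmat(yb, 1, 1)) / (float)B;
      fmat gwout = hs[T].t() * dlogit + (float)wd * wout;
      fmat gbout = sum(dlogit, 0);
      fmat dh = dlogit * wout.t();
      fmat dc = zeros<fmat>(B, H);
      fmat gWx = (float)wd * Wx, gWh = (float)wd * Wh;
      fmat gbg = zeros<fmat>(1, G * H);
      fmat gWxn, gWhn, gbn;
      if (!lstm) {
        gWxn = (float)wd * Wxn; gWhn = (float)wd * Whn;
        gbn = zeros<fmat>(1, H);
      }

      for (int t = T - 1; t >= 0; --t) {
        fmat Xt = Xb.cols(t * F, (t + 1) * F - 1);
        if (lstm) {
          fmat do_ = dh % TC[t];
          dc += dh % O[t] % (1.0f - square(TC[t]));
          fmat di = dc % Gg[t];
          fmat dg = dc % I[t];
          fmat df = dc % cs[t];
          fmat dcprev = dc % Fg[t];
          fmat dA(B, 4 * H);
          dA.cols(0, H - 1) = di % I[t] % (1.0f - I[t]);
          dA.cols(H, 2 * H - 1) = df % Fg[t] % (1.0f - Fg[t]);
          dA.cols(2 * H, 3 * H - 1) = dg % (1.0f - square(Gg[t]));
          dA.cols(3 * H, 4 * H - 1) = do_ % O[t] % (1.0f - O[t]);
          gWx += Xt.t() * dA;
          gWh += hs[t].t() * dA;
          gbg += sum(dA, 0);
          dh = dA * Wh.t();
          dc = dcprev;
        } else {
          fmat dz = dh % (hs[t] - N[t]);
          fmat dn = dh % (1.0f - Z[t]);
          fmat dhprev = dh % Z[t];
          fmat dAn = dn % (1.0f - square(N[t]));
          gWxn += Xt.t() * dAn;
          gWhn += (R[t] % hs[t]).t() * dAn;
          gbn += sum(dAn, 0);
          fmat drh = dAn * Whn.t();
          fmat dr = drh % hs[t];
          dhprev += drh % R[t];
          fmat dA(B, 2 * H);
          dA.cols(0, H - 1) = dz % Z[t] % (1.0f - Z[t]);
          dA.cols(H, 2 * H - 1) = dr % R[t] % (1.0f - R[t]);
          gWx += Xt.t() * dA;
          gWh += hs[t].t() * dA;
          gbg += sum(dA, 0);
          dh = dhprev + dA * Wh.t();
        }
      }
      std::vector<fmat> g;
      g.push_back(gWx); g.push_back(gWh); g.push_back(gbg);
      if (!lstm) { g.push_back(gWxn); g.push_back(gWhn); g.push_back(gbn); }
      g.push_back(gwout); g.push_back(gbout);
      fclip_grads(g, 5.0f);
      opt.step(g);
    }
    epoch_loss.push_back(tot / cnt);
  }
  return Rcpp::List::create(
      Rcpp::Named("Wx") = conv_to<mat>::from(Wx),
      Rcpp::Named("Wh") = conv_to<mat>::from(Wh),
      Rcpp::Named("bg") = conv_to<mat>::from(bg),
      Rcpp::Named("Wxn") = lstm ? mat() : conv_to<mat>::from(Wxn),
      Rcpp::Named("Whn") = lstm ? mat() : conv_to<mat>::from(Whn),
      Rcpp::Named("bn") = conv_to<mat>::from(bn),
      Rcpp::Named("wout") = conv_to<mat>::from(wout),
      Rcpp::Named("bout") = conv_to<mat>::from(bout),
      Rcpp::Named("kind") = kind,
      Rcpp::Named("H") = H, Rcpp::Named("log") = epoch_loss);
}

// [[Rcpp::export]]
arma::vec rnn_predict(const Rcpp::List& params, const arma::mat& X_, int T,
                      int F) {
  std::string kind = Rcpp::as<std::string>(params["kind"]);
  bool lstm = (kind == "lstm");
  int H = Rcpp::as<int>(params["H"]);
  fmat X = conv_to<fmat>::from(X_);
  fmat Wx = conv_to<fmat>::from(Rcpp::as<mat>(params["Wx"]));
  fmat Wh = conv_to<fmat>::from(Rcpp::as<mat>(params["Wh"]));
  fmat bg = conv_to<fmat>::from(Rcpp::as<mat>(params["bg"]));
  fmat wout = conv_to<fmat>::from(Rcpp::as<mat>(params["wout"]));
  fmat bout = conv_to<fmat>::from(Rcpp::as<mat>(params["bout"]));
  fmat Wxn, Whn, bn;
  if (!lstm) {
    Wxn = conv_to<fmat>::from(Rcpp::as<mat>(params["Wxn"]));
    Whn = conv_to<fmat>::from(Rcpp::as<mat>(params["Whn"]));
    bn = conv_to<fmat>::from(Rcpp::as<mat>(params["bn"]));
  }
  uword B = X.n_rows;
  fmat h = zeros<fmat>(B, H), c = zeros<fmat>(B, H);
  for (int t = 0; t < T; ++t) {
    fmat Xt = X.cols(t * F, (t + 1) * F - 1);
    fmat A = Xt * Wx + h * Wh;
    A.each_row() += bg;
    if (lstm) {
      fmat I = fsig(A.cols(0, H - 1));
      fmat Fg = fsig(A.cols(H, 2 * H - 1));
      fmat G = tanh(A.cols(2 * H, 3 * H - 1));
      fmat O = fsig(A.cols(3 * H, 4 * H - 1));
      c = Fg % c + I % G;
      h = O % tanh(c);
    } else {
      fmat Z = fsig(A.cols(0, H - 1));
      fmat R = fsig(A.cols(H, 2 * H - 1));
      fmat An = Xt * Wxn + (R % h) * Whn;
      An.each_row() += bn;
      h = (1.0f - Z) % tanh(An) + Z % h;
    }
  }
  fmat logit = h * wout;
  logit.each_row() += bout;
  return conv_to<vec>::from(fsig(logit).col(0));
}
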