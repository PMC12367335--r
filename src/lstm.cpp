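// Sequence-to-one LSTM regressor: forward pass, backpropagation through
// time, and the Adam training loop with early stopping / best-checkpoint
// selection. Parameters travel as one flat vector so the R side can
// serialize and seed them; gate blocks are ordered f (forget), c
// (candidate), i (input), o (output) to match the cell equations
//   f = sigma(xU_f + hW_f + b_f),  c~ = tanh(xU_c + hW_c + b_c),
//   i = sigma(xU_i + hW_i + b_i),  o = sigma(xU_o + hW_o + b_o),
//   C = f.C_prev + i.c~,           H = o.tanh(C).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline rowvec sigmoid(const rowvec& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirParams {       // one direction's gate parameters (views into theta)
  mat U;                 // D x 4H
  mat W;                 // H x 4H
  rowvec b;              // 4H
};

static int gate_len(int D, int H) { return 4 * D * H + 4 * H * H + 4 * H; }

static DirParams unpack_dir(const vec& theta, int off, int D, int H) {
  DirParams p;
  p.U = mat(theta.memptr() + off, D, 4 * H);
  p.W = mat(theta.memptr() + off + 4 * D * H, H, 4 * H);
  p.b = rowvec(theta.memptr() + off + 4 * D * H + 4 * H * H, 4 * H);
  return p;
}

struct Cache {           // per-sequence forward trajectories
  mat F, G, I, O, C, TC, Hs;   // each T x H
};

// Forward one direction over X (T x D); fills cache, returns final hidden.
static rowvec forward_dir(const mat& X, const DirParams& p, int H, Cache& K) {
  const int T = X.n_rows;
  K.F.set_size(T, H); K.G.set_size(T, H); K.I.set_size(T, H);
  K.O.set_size(T, H); K.C.set_size(T, H); K.TC.set_size(T, H); K.Hs.set_size(T, H);
  rowvec h(H, fill::zeros), c(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    rowvec a = X.row(t) * p.U + h * p.W + p.b;
    rowvec f = sigmoid(a.cols(0, H - 1));
    rowvec g = tanh(a.cols(H, 2 * H - 1));
    rowvec i = sigmoid(a.cols(2 * H, 3 * H - 1));
    rowvec o = sigmoid(a.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    rowvec tc = tanh(c);
    h = o % tc;
    K.F.row(t) = f; K.G.row(t) = g; K.I.row(t) = i; K.O.row(t) = o;
    K.C.row(t) = c; K.TC.row(t) = tc; K.Hs.row(t) = h;
  }
  return h;
}

// BPTT one direction; dh_T is dLoss/dH_final. Accumulates into grad at off.
static void backward_dir(const mat& X, const DirParams& p, const Cache& K,
                         rowvec dh, vec& grad, int off, int D, int H) {
  const int T = X.n_rows;
  mat gU(grad.memptr() + off, D, 4 * H, false, true);
  mat gW(grad.memptr() + off + 4 * D * H, H, 4 * H, false, true);
  rowvec gb(grad.memptr() + off + 4 * D * H + 4 * H * H, 4 * H, false, true);
  rowvec dc(H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    rowvec f = K.F.row(t), g = K.G.row(t), i = K.I.row(t), o = K.O.row(t);
    rowvec tc = K.TC.row(t);
    dc += dh % o % (1.0 - tc % tc);
    rowvec do_ = dh % tc;
    rowvec cprev = (t > 0) ? rowvec(K.C.row(t - 1)) : rowvec(H, fill::zeros);
    rowvec df = dc % cprev;
    rowvec dg = dc % i;
    rowvec di = dc % g;
    rowvec da(4 * H);
    da.cols(0, H - 1)         = df % f % (1.0 - f);
    da.cols(H, 2 * H - 1)     = dg % (1.0 - g % g);
    da.cols(2 * H, 3 * H - 1) = di % i % (1.0 - i);
    da.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    rowvec hprev = (t > 0) ? rowvec(K.Hs.row(t - 1)) : rowvec(H, fill::zeros);
    gU += X.row(t).t() * da;
    gW += hprev.t() * da;
    gb += da;
    dh = da * p.W.t();
    dc = dc % f;
  }
}

struct Model {           // fully unpacked parameter set
  DirParams fwd, bwd;
  rowvec wout;
  double bout;
  bool bidir;
  int D, H;
};

static Model unpack_model(const vec& theta, int D, int H, bool bidir) {
  Model mdl;
  mdl.D = D; mdl.H = H; mdl.bidir = bidir;
  const int GL = gate_len(D, H);
  const int hd = bidir ? 2 * H : H;
  const int off_head = bidir ? 2 * GL : GL;
  mdl.fwd = unpack_dir(theta, 0, D, H);
  if (bidir) mdl.bwd = unpack_dir(theta, GL, D, H);
  mdl.wout = rowvec(theta.memptr() + off_head, hd);
  mdl.bout = theta(off_head + hd);
  return mdl;
}

// Prediction for one sequence under an unpacked model.
static double predict_one(const mat& X, const Model& mdl,
                          Cache& Kf, Cache& Kb, mat& Xrev) {
  const int H = mdl.H;
  const int hd = mdl.bidir ? 2 * H : H;
  rowvec hfin(hd);
  hfin.cols(0, H - 1) = forward_dir(X, mdl.fwd, H, Kf);
  if (mdl.bidir) {
    Xrev = flipud(X);
    hfin.cols(H, 2 * H - 1) = forward_dir(Xrev, mdl.bwd, H, Kb);
  }
  return dot(mdl.wout, hfin) + mdl.bout;
}

// [[Rcpp::export]]
arma::vec cpp_predict(Rcpp::List X, const arma::vec& theta, int D, int H, bool bidir) {
  const int n = X.size();
  vec out(n);
  Cache Kf, Kb; mat Xrev;
  Model mdl = unpack_model(theta, D, H, bidir);
  for (int s = 0; s < n; ++s) {
    mat Xs = Rcpp::as<mat>(X[s]);
    out(s) = predict_one(Xs, mdl, Kf, Kb, Xrev);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_forward_states(const arma::mat& X, const arma::vec& theta_dir,
                              int D, int H) {
  DirParams p = unpack_dir(theta_dir, 0, D, H);
  Cache K;
  forward_dir(X, p, H, K);
  return Rcpp::List::create(Rcpp::Named("hidden") = K.Hs,
                            Rcpp::Named("cell") = K.C);
}

static double mse_loss(const std::vector<mat>& X, const vec& y, const vec& theta,
                       int D, int H, bool bidir) {
  Cache Kf, Kb; mat Xrev;
  Model mdl = unpack_model(theta, D, H, bidir);
  double s = 0.0;
  for (size_t i = 0; i < X.size(); ++i) {
    double r = predict_one(X[i], mdl, Kf, Kb, Xrev) - y(i);
    s += r * r;
  }
  return s / X.size();
}

// Mean-squared-error loss over a set of sequences and its gradient in the
// flat parameter vector (used by the training loop and by gradient tests).
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List X_, const arma::vec& y, const arma::vec& theta,
                         int D, int H, bool bidir) {
  const int n = X_.size();
  const int GL = gate_len(D, H);
  const int off_head = bidir ? 2 * GL : GL;
  const int hd = bidir ? 2 * H : H;
  vec grad(theta.n_elem, fill::zeros);
  Cache Kf, Kb; mat Xrev;
  Model mdl = unpack_model(theta, D, H, bidir);
  double loss = 0.0;
  for (int s = 0; s < n; ++s) {
    mat Xs = Rcpp::as<mat>(X_[s]);
    double r = predict_one(Xs, mdl, Kf, Kb, Xrev) - y(s);
    loss += r * r;
    const double scale = 2.0 * r / n;
    rowvec hfin(hd);
    hfin.cols(0, H - 1) = Kf.Hs.row(Kf.Hs.n_rows - 1);
    if (bidir) hfin.cols(H, 2 * H - 1) = Kb.Hs.row(Kb.Hs.n_rows - 1);
    for (int j = 0; j < hd; ++j) grad(off_head + j) += scale * hfin(j);
    grad(off_head + hd) += scale;
    backward_dir(Xs, mdl.fwd, Kf, scale * mdl.wout.cols(0, H - 1), grad, 0, D, H);
    if (bidir) {
      backward_dir(Xrev, mdl.bwd, Kb, scale * mdl.wout.cols(H, 2 * H - 1),
                   grad, GL, D, H);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List Xtr_, const arma::vec& ytr,
                     Rcpp::List Xval_, const arma::vec& yval,
                     const arma::vec& theta0, int D, int H, bool bidir,
                     double lr, int batch_size, int max_epochs, int patience,
                     int shuffle_seed) {
  const int n = Xtr_.size();
  std::vector<mat> Xtr(n), Xval(Xval_.size());
  for (int i = 0; i < n; ++i) Xtr[i] = Rcpp::as<mat>(Xtr_[i]);
  for (int i = 0; i < (int)Xval_.size(); ++i) Xval[i] = Rcpp::as<mat>(Xval_[i]);

  const int GL = gate_len(D, H);
  const int off_head = bidir ? 2 * GL : GL;
  vec theta = theta0, m(theta.n_elem, fill::zeros), v(theta.n_elem, fill::zeros);
  vec grad(theta.n_elem);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::mt19937 rng(static_cast<unsigned>(shuffle_seed));

  vec theta_best = theta;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> hist_tr, hist_val;
  bool diverged = false;

  Cache Kf, Kb; mat Xrev;

  for (int epoch = 0; epoch < max_epochs && !diverged; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0; int n_seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int bs = stop - start;
      grad.zeros();
      double bloss = 0.0;
      Model mdl = unpack_model(theta, D, H, bidir);
      const int hd = bidir ? 2 * H : H;
      for (int k = start; k < stop; ++k) {
        const mat& Xs = Xtr[idx[k]];
        double pred = predict_one(Xs, mdl, Kf, Kb, Xrev);
        double r = pred - ytr(idx[k]);
        bloss += r * r;
        const double scale = 2.0 * r / bs;
        rowvec hfin(hd);
        hfin.cols(0, H - 1) = Kf.Hs.row(Kf.Hs.n_rows - 1);
        if (bidir) hfin.cols(H, 2 * H - 1) = Kb.Hs.row(Kb.Hs.n_rows - 1);
        for (int j = 0; j < hd; ++j) grad(off_head + j) += scale * hfin(j);
        grad(off_head + hd) += scale;
        backward_dir(Xs, mdl.fwd, Kf, scale * mdl.wout.cols(0, H - 1), grad, 0, D, H);
        if (bidir) {
          backward_dir(Xrev, mdl.bwd, Kb, scale * mdl.wout.cols(H, 2 * H - 1),
                       grad, GL, D, H);
        }
      }
      bloss /= bs;
      if (!std::isfinite(bloss)) { diverged = true; break; }
      epoch_loss += bloss * bs; n_seen += bs;
      ++step;
      const double a_t = lr * std::sqrt(1.0 - std::pow(b2, step)) /
                         (1.0 - std::pow(b1, step));
      m = b1 * m + (1.0 - b1) * grad;
      v = b2 * v + (1.0 - b2) * square(grad);
      theta -= a_t * m / (sqrt(v) + eps);
    }
    if (diverged) break;
    epochs_run = epoch + 1;
    double tr_loss = epoch_loss / n_seen;
    double val_loss = mse_loss(Xval, yval, theta, D, H, bidir);
    if (!std::isfinite(val_loss)) { diverged = true; break; }
    hist_tr.push_back(tr_loss);
    hist_val.push_back(val_loss);
    if (val_loss < best_val - 1e-12) {
      best_val = val_loss;
      theta_best = theta;
      best_epoch = epoch + 1;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta_best,
    Rcpp::Named("best_val") = best_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("train_loss") = hist_tr,
    Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("diverged") = diverged);
}
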