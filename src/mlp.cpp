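// Feedforward neural network for coordinate regression: ReLU hidden layers
// with inverted dropout, L1/L2 penalties, Adam, mini-batches, and early
// stopping on a validation RMSE. Fully deterministic given the seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
};

static mat forward_eval(const Net &net, const mat &X) {
  mat A = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    A = A * net.W[l];
    A.each_row() += net.b[l].t();
    if (l + 1 < L) A = clamp(A, 0.0, datum::inf);   // ReLU
  }
  return A;
}

static double rmse_of(const Net &net, const mat &X, const mat &Y) {
  mat E = forward_eval(net, X) - Y;
  return std::sqrt(accu(square(E)) / E.n_elem);
}

static const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-8;

// in-place Adam step with L1/L2 penalty folded into the gradient
static void adam_update(mat &W, const mat &g, mat &m, mat &v, double l1,
                        double l2, double lr, long t) {
  const double c1 = 1.0 - std::pow(ADAM_B1, double(t));
  const double c2 = 1.0 - std::pow(ADAM_B2, double(t));
  for (uword i = 0; i < W.n_elem; ++i) {
    double gi = g(i) + l2 * W(i) + l1 * ((W(i) > 0) - (W(i) < 0));
    m(i) = ADAM_B1 * m(i) + (1 - ADAM_B1) * gi;
    v(i) = ADAM_B2 * v(i) + (1 - ADAM_B2) * gi * gi;
    W(i) -= lr * (m(i) / c1) / (std::sqrt(v(i) / c2) + ADAM_EPS);
  }
}

static void adam_update_vec(vec &b, const vec &g, vec &m, vec &v, double lr,
                            long t) {
  const double c1 = 1.0 - std::pow(ADAM_B1, double(t));
  const double c2 = 1.0 - std::pow(ADAM_B2, double(t));
  for (uword i = 0; i < b.n_elem; ++i) {
    m(i) = ADAM_B1 * m(i) + (1 - ADAM_B1) * g(i);
    v(i) = ADAM_B2 * v(i) + (1 - ADAM_B2) * g(i) * g(i);
    b(i) -= lr * (m(i) / c1) / (std::sqrt(v(i) / c2) + ADAM_EPS);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(const arma::mat &X, const arma::mat &Y,
                         const arma::ivec &hidden, double input_dropout,
                         const arma::vec &hidden_dropouts, double l1,
                         double l2, double lr, int batch_size, int max_epochs,
                         double tol, int patience, double val_frac,
                         int seed) {
  const uword n = X.n_rows, p = X.n_cols, nout = Y.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<uword> sizes;
  sizes.push_back(p);
  for (uword i = 0; i < hidden.n_elem; ++i)
    sizes.push_back(static_cast<uword>(hidden(i)));
  sizes.push_back(nout);
  const size_t L = sizes.size() - 1;

  Net net;
  for (size_t l = 0; l < L; ++l) {
    double sdev = std::sqrt(2.0 / double(sizes[l]));   // He init
    mat W(sizes[l], sizes[l + 1]);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sdev * gauss(rng);
    net.W.push_back(W);
    net.b.push_back(vec(sizes[l + 1], fill::zeros));
  }

  // validation split
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  uword nval = static_cast<uword>(std::round(val_frac * double(n)));
  if (val_frac > 0 && nval == 0) nval = 1;
  if (nval >= n) nval = n - 1;
  uvec vidx(nval), tidx(n - nval);
  for (uword i = 0; i < nval; ++i) vidx(i) = idx[i];
  for (uword i = nval; i < n; ++i) tidx(i - nval) = idx[i];
  mat Xtr = X.rows(tidx), Ytr = Y.rows(tidx);
  mat Xval = nval ? X.rows(vidx) : Xtr;
  mat Yval = nval ? Y.rows(vidx) : Ytr;

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = zeros<mat>(size(net.W[l])); vW[l] = mW[l];
    mb[l] = zeros<vec>(net.b[l].n_elem); vb[l] = mb[l];
  }
  long tstep = 0;

  Net best = net;
  double best_rmse = rmse_of(net, Xval, Yval);
  int stall = 0, epochs_run = 0;
  std::vector<double> val_trace;
  val_trace.push_back(best_rmse);
  bool diverged = false;

  const uword ntr = Xtr.n_rows;
  std::vector<uword> order(ntr);
  for (uword i = 0; i < ntr; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs && !diverged; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < ntr; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, ntr);
      uvec bi(stop - start);
      for (uword i = start; i < stop; ++i) bi(i - start) = order[i];
      mat A = Xtr.rows(bi);
      mat Yb = Ytr.rows(bi);
      const double nb = double(A.n_rows);

      // input dropout (inverted)
      std::vector<mat> acts;   // post-dropout activations per layer input
      if (input_dropout > 0) {
        double keep = 1.0 - input_dropout;
        for (uword i = 0; i < A.n_elem; ++i)
          A(i) = (unif(rng) < keep) ? A(i) / keep : 0.0;
      }
      acts.push_back(A);
      std::vector<mat> zs;
      std::vector<mat> masks;   // inverted-dropout masks (1/keep or 0)
      for (size_t l = 0; l < L; ++l) {
        mat Z = acts.back() * net.W[l];
        Z.each_row() += net.b[l].t();
        if (l + 1 < L) {
          mat H = clamp(Z, 0.0, datum::inf);
          double dr = hidden_dropouts(l);
          mat Mask(size(H), fill::ones);
          if (dr > 0) {
            double keep = 1.0 - dr;
            for (uword i = 0; i < Mask.n_elem; ++i)
              Mask(i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
            H %= Mask;
          }
          zs.push_back(Z);
          masks.push_back(Mask);
          acts.push_back(H);
        } else {
          zs.push_back(Z);
          acts.push_back(Z);
        }
      }

      mat delta = (2.0 / (nb * double(nout))) * (acts.back() - Yb); // d MSE
      ++tstep;
      for (size_t l = L; l-- > 0;) {
        mat gW = acts[l].t() * delta;
        vec gb = sum(delta, 0).t();
        if (l > 0) {
          mat nd = delta * net.W[l].t();
          const mat &Mk = masks[l - 1];
          const mat &Z = zs[l - 1];
          for (uword i = 0; i < nd.n_elem; ++i)
            nd(i) = (Z(i) > 0) ? nd(i) * Mk(i) : 0.0;
          // fused Adam update for this layer, single pass, no temporaries
          adam_update(net.W[l], gW, mW[l], vW[l], l1, l2, lr, tstep);
          adam_update_vec(net.b[l], gb, mb[l], vb[l], lr, tstep);
          delta = std::move(nd);
        } else {
          adam_update(net.W[l], gW, mW[l], vW[l], l1, l2, lr, tstep);
          adam_update_vec(net.b[l], gb, mb[l], vb[l], lr, tstep);
        }
      }
      if (!net.W[0].is_finite()) { diverged = true; break; }
    }
    epochs_run = epoch + 1;
    double r = rmse_of(net, Xval, Yval);
    if (!std::isfinite(r)) { diverged = true; break; }
    val_trace.push_back(r);
    if (r < best_rmse) { best = net; }
    if (r < best_rmse - tol) {
      best_rmse = r;
      stall = 0;
    } else {
      best_rmse = std::min(best_rmse, r);
      ++stall;
      if (stall >= patience) break;
    }
  }

  Rcpp::List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = best.W[l];
    bl[l] = best.b[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl,
      Rcpp::Named("epochs") = epochs_run,
      Rcpp::Named("val_rmse") = val_trace,
      Rcpp::Named("best_rmse") = best_rmse,
      Rcpp::Named("diverged") = diverged);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(const Rcpp::List &Wl, const Rcpp::List &bl,
                          const arma::mat &X) {
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(Wl[l]));
    net.b.push_back(Rcpp::as<vec>(bl[l]));
  }
  return forward_eval(net, X);
}
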