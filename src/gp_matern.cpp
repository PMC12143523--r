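// Batched exact Gaussian-process fitting of per-SNP allele-frequency
// surfaces on grid-cell centers: Matern 5/2 kernel, learned constant mean,
// marginal-likelihood ascent with Adam for a fixed number of epochs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

struct AdamState {
  vec m, v;
  int t;
  AdamState(int k) : m(k, fill::zeros), v(k, fill::zeros), t(0) {}
  void step(vec &theta, const vec &grad, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    ++t;
    m = b1 * m + (1 - b1) * grad;
    v = b2 * v + (1 - b2) * square(grad);
    vec mh = m / (1 - std::pow(b1, t));
    vec vh = v / (1 - std::pow(b2, t));
    theta += lr * mh / (sqrt(vh) + eps);
  }
};

// Marginal log-likelihood and gradient wrt (log s2, log l, log noise, mean).
// S5 = sqrt(5) * R precomputed by the caller. On success fills Kinv and
// alpha (reusable for prediction) and returns the log-likelihood.
static double mll_grad(const mat &S5, const vec &f, const vec &theta,
                       double jitter, vec &grad, mat &Kinv, vec &alpha) {
  const double s2 = std::exp(theta(0));
  const double l = std::exp(theta(1));
  const double noise = std::exp(theta(2));
  const double mu = theta(3);
  const uword m = S5.n_rows;
  mat S = S5 / l;
  mat E = exp(-S);                          // shared exponential term
  mat Ksig = s2 * ((1.0 + S + square(S) / 3.0) % E);
  mat K = Ksig;
  K.diag() += noise + jitter;
  mat U;
  if (!chol(U, K)) {
    K.diag() += 1e-4;
    if (!chol(U, K)) {
      grad.zeros(4);
      return -datum::inf;
    }
  }
  double ldet = 2.0 * accu(log(U.diag()));
  mat Uinv = inv(trimatu(U));
  Kinv = Uinv * Uinv.t();
  vec r = f - mu;
  alpha = Kinv * r;
  double ll = -0.5 * dot(r, alpha) - 0.5 * ldet -
              0.5 * double(m) * std::log(2.0 * datum::pi);
  mat A = alpha * alpha.t() - Kinv;         // dL/dK = A/2
  grad(0) = 0.5 * accu(A % Ksig);
  grad(1) = 0.5 * s2 * accu(A % ((square(S) % (1.0 + S)) / 3.0 % E));
  grad(2) = 0.5 * noise * trace(A);
  grad(3) = accu(alpha);
  return ll;
}

// Fit one GP per SNP column of F (observed cell frequencies) and predict the
// posterior mean at every target cell. Rtr: occupied-cell distance matrix;
// Rcross: target-cells x occupied-cells distances. Returns fitted
// hyperparameters, predictions and the per-epoch log-likelihood trace.
// [[Rcpp::export]]
Rcpp::List cpp_fit_predict_surfaces(const arma::mat &Rtr, const arma::mat &F,
                                    const arma::mat &Rcross, int epochs,
                                    double lr, double jitter) {
  const uword q = F.n_cols;
  const uword M = Rcross.n_rows;
  const double sqrt5 = std::sqrt(5.0);
  mat S5tr = sqrt5 * Rtr;
  mat S5cr = sqrt5 * Rcross;
  mat params(q, 4);
  mat pred(M, q);
  mat trace_ll(epochs + 1, q);

  // deterministic initial lengthscale: median positive pairwise distance
  vec rv = vectorise(trimatu(Rtr, 1));
  vec rpos = rv(find(rv > 0));
  double l0 = rpos.n_elem ? median(rpos) : 1.0;
  if (l0 <= 0) l0 = 1.0;

  for (uword j = 0; j < q; ++j) {
    vec f = F.col(j);
    double mu0 = mean(f);
    double v0 = var(f);
    if (!std::isfinite(v0) || v0 < 1e-4) v0 = 1e-4;
    vec theta = {std::log(v0), std::log(l0), std::log(0.01), mu0};
    AdamState adam(4);
    vec grad(4, fill::zeros), alpha;
    mat Kinv;
    double ll = mll_grad(S5tr, f, theta, jitter, grad, Kinv, alpha);
    trace_ll(0, j) = ll;
    for (int e = 0; e < epochs; ++e) {
      adam.step(theta, grad, lr);
      ll = mll_grad(S5tr, f, theta, jitter, grad, Kinv, alpha);
      trace_ll(e + 1, j) = ll;
    }
    params.row(j) = theta.t();
    // posterior mean at the target cells, reusing the final-state alpha
    const double s2 = std::exp(theta(0));
    const double l = std::exp(theta(1));
    mat Sc = S5cr / l;
    mat Kcr = s2 * ((1.0 + Sc + square(Sc) / 3.0) % exp(-Sc));
    pred.col(j) = theta(3) + Kcr * alpha;
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("pred") = pred,
                            Rcpp::Named("ll_trace") = trace_ll);
}
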