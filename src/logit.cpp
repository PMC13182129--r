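// Fast logistic-regression primitives for the simulation engine.
// Newton/IRLS maximum likelihood, a two-parameter calibration-slope fit, and
// the bootstrap uniform-shrinkage loop. These are the hot paths: a single
// study run performs hundreds of thousands of refits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct IrlsFit {
  arma::vec coef;
  double loglik;
  bool converged;
  int iter;
  double grad_max;
};

// Binomial log-likelihood for (possibly fractional) responses y at linear
// predictor eta. Fractional y gives the y-marginalised ("population")
// likelihood used when validating against true event probabilities.
static double binom_loglik(const arma::vec& y, const arma::vec& eta) {
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    ll += y[i] * eta[i] - softplus(eta[i]);
  return ll;
}

// IRLS / Newton with step halving. X is the full design (intercept included).
// Convergence: mean score (inf-norm of gradient divided by n) below tol.
// Separation flag: any coefficient exceeding 50 on the standardised scale.
static IrlsFit irls(const arma::mat& X, const arma::vec& y,
                    double tol, int maxit,
                    const arma::vec* start = nullptr) {
  const arma::uword n = X.n_rows, k = X.n_cols;
  IrlsFit out;
  out.coef = (start && start->n_elem == k) ? *start
                                           : arma::zeros<arma::vec>(k);
  out.converged = false;
  out.iter = 0;

  arma::vec eta = X * out.coef;
  double ll = binom_loglik(y, eta);
  arma::vec p(n), w(n), grad(k);
  arma::mat H(k, k);

  double gmax = arma::datum::inf;
  for (int it = 1; it <= maxit; ++it) {
    out.iter = it;
    for (arma::uword i = 0; i < n; ++i) {
      double e = eta[i];
      double pi = 1.0 / (1.0 + std::exp(-e));
      p[i] = pi;
      double wi = pi * (1.0 - pi);
      w[i] = (wi < 1e-10) ? 1e-10 : wi;
    }
    grad = X.t() * (y - p);
    gmax = arma::abs(grad).max();
    if (gmax / (double)n <= tol) {
      out.converged = true;
      break;
    }
    H = X.t() * (X.each_col() % w);
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd +
                                         arma::solve_opts::no_approx);
    if (!ok) {
      ok = arma::solve(step, H + 1e-8 * arma::eye(k, k), grad);
      if (!ok) break;
    }
    // step halving to guarantee likelihood ascent
    double llnew = -arma::datum::inf;
    arma::vec coef_new, eta_new;
    for (int h = 0; h < 30; ++h) {
      coef_new = out.coef + step;
      eta_new = X * coef_new;
      llnew = binom_loglik(y, eta_new);
      if (llnew >= ll - 1e-12) break;
      step *= 0.5;
    }
    if (llnew < ll - 1e-12) break;  // no ascent direction left
    if (std::abs(llnew - ll) < 1e-13 * (std::abs(ll) + 0.1) &&
        gmax / (double)n <= tol * 1e2) {
      // likelihood flat; accept if gradient nearly met
      out.coef = coef_new;
      eta = eta_new;
      ll = llnew;
      out.converged = true;
      break;
    }
    out.coef = coef_new;
    eta = eta_new;
    ll = llnew;
  }
  // re-check gradient at final coefficients
  for (arma::uword i = 0; i < n; ++i)
    p[i] = 1.0 / (1.0 + std::exp(-eta[i]));
  grad = X.t() * (y - p);
  gmax = arma::abs(grad).max();
  if (gmax / (double)n <= tol) out.converged = true;
  out.grad_max = gmax;
  // separation check on the standardised scale
  for (arma::uword j = 0; j < k; ++j) {
    double sd = arma::stddev(X.col(j));
    double scale = (sd > 0) ? sd : 1.0;
    if (std::abs(out.coef[j] * scale) > 50.0) {
      out.converged = false;
      break;
    }
  }
  out.loglik = ll;
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_logit_fit(const arma::mat& X, const arma::vec& y,
                   double tol = 1e-8, int maxit = 100) {
  IrlsFit f = irls(X, y, tol, maxit);
  return List::create(_["coef"] = f.coef,
                      _["loglik"] = f.loglik,
                      _["converged"] = f.converged,
                      _["iter"] = f.iter,
                      _["grad_max"] = f.grad_max);
}

// [[Rcpp::export]]
List cpp_calib_slope(const arma::vec& lp, const arma::vec& y,
                     double tol = 1e-8, int maxit = 100) {
  arma::mat X(lp.n_elem, 2);
  X.col(0).ones();
  X.col(1) = lp;
  // predictions are usually roughly calibrated: start near the identity
  arma::vec start = {0.0, 1.0};
  IrlsFit f = irls(X, y, tol, maxit, &start);
  return List::create(_["intercept"] = f.coef[0],
                      _["slope"] = f.coef[1],
                      _["converged"] = f.converged);
}

// Bootstrap uniform shrinkage: resample rows with replacement (size n), refit
// the model on the replicate, compute the calibration slope of the replicate
// model's predictions in the ORIGINAL data; average over replicates that
// converged. Uses R's RNG stream so results are reproducible via set.seed.
// [[Rcpp::export]]
List cpp_boot_shrinkage(const arma::mat& X, const arma::vec& y, int B,
                        double tol = 1e-8, int maxit = 100) {
  const arma::uword n = X.n_rows;
  arma::vec slopes(B);
  slopes.fill(arma::datum::nan);
  int failures = 0;
  // warm starts: the refit starts from the original-data MLE, the slope fit
  // from the identity — both cut Newton iterations without changing the
  // maximiser
  IrlsFit orig = irls(X, y, tol, maxit);
  const arma::vec* warm = orig.converged ? &orig.coef : nullptr;
  arma::vec cs_start = {0.0, 1.0};
  arma::uvec idx(n);
  arma::mat Xc(n, 2);
  Xc.col(0).ones();
  for (int b = 0; b < B; ++b) {
    for (arma::uword i = 0; i < n; ++i) {
      arma::uword j = (arma::uword)(unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    arma::vec yb = y(idx);
    double ssum = arma::accu(yb);
    if (ssum <= 0.0 || ssum >= (double)n) { ++failures; continue; }
    arma::mat Xb = X.rows(idx);
    IrlsFit f = irls(Xb, yb, tol, maxit, warm);
    if (!f.converged) { ++failures; continue; }
    Xc.col(1) = X * f.coef;
    IrlsFit cs = irls(Xc, y, tol, maxit, &cs_start);
    if (!cs.converged) { ++failures; continue; }
    slopes[b] = cs.coef[1];
  }
  arma::vec ok = slopes.elem(arma::find_finite(slopes));
  double mean_slope = ok.n_elem > 0 ? arma::mean(ok) : NA_REAL;
  return List::create(_["s_boot"] = mean_slope,
                      _["failures"] = failures,
                      _["slopes"] = slopes);
}
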