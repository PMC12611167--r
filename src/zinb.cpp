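// Fused ZINB negative log-likelihood and gradient kernel.
// Mixture: P(0) = pi + (1-pi) NB(0 | mu, theta), P(x>0) = (1-pi) NB(x).
// Computed entrywise in log space with epsilon guards; one pass yields
// the mean NLL and its gradients w.r.t. pi, mu, theta.
//
// For small integer counts the gamma-function ratios collapse to short
// recurrence sums — lgamma(x+t)-lgamma(t) = sum log(t+k) and
// digamma(x+t)-digamma(t) = sum 1/(t+k) — which are far cheaper than
// lgamma/digamma calls; large or non-integer counts fall back to Rmath.

#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

static const double EPS = 1e-10;
static const int SMALL_X = 64;

static inline bool is_small_int(double x) {
  return x == std::floor(x) && x >= 0.0 && x <= (double) SMALL_X;
}

// lgamma(x+1) for integer 0..SMALL_X, filled on first use
static double lgfact[SMALL_X + 1];
static bool lgfact_ready = false;

// [[Rcpp::export(name = ".zinb_nll_grad_cpp")]]
List zinb_nll_grad_cpp(NumericMatrix X, NumericMatrix pi_,
                       NumericMatrix mu_, NumericMatrix theta_,
                       bool want_grad) {
  if (!lgfact_ready) {
    for (int k = 0; k <= SMALL_X; ++k) lgfact[k] = R::lgammafn(k + 1.0);
    lgfact_ready = true;
  }
  const R_xlen_t n = X.size();
  NumericMatrix d_pi, d_mu, d_th;
  if (want_grad) {
    d_pi = NumericMatrix(X.nrow(), X.ncol());
    d_mu = NumericMatrix(X.nrow(), X.ncol());
    d_th = NumericMatrix(X.nrow(), X.ncol());
  }
  double loss = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = X[i];
    if (x < 0) stop("counts must be non-negative");
    const double pi = pi_[i], mu = mu_[i], th = theta_[i];
    const double tm = th + mu;
    const double log_t = std::log(th + EPS) - std::log(tm);
    if (x == 0.0) {
      const double nb0 = std::exp(th * log_t);
      const double P0 = pi + (1.0 - pi) * nb0;
      loss += -std::log(P0 + EPS);
      if (want_grad) {
        const double invP0 = 1.0 / (P0 + EPS);
        const double f0 = -(1.0 - pi) * nb0 * invP0;
        d_pi[i] = -(1.0 - nb0) * invP0;
        d_mu[i] = f0 * (-th / tm);
        d_th[i] = f0 * (log_t + mu / tm);
      }
    } else {
      const double log_m = std::log(mu + EPS) - std::log(tm);
      double lg_ratio, dg_ratio = 0.0, lg_xp1;
      if (is_small_int(x)) {
        const int xi = (int) x;
        lg_ratio = 0.0;
        for (int k = 0; k < xi; ++k) {
          lg_ratio += std::log(th + k);
          if (want_grad) dg_ratio += 1.0 / (th + k);
        }
        lg_xp1 = lgfact[xi];
      } else {
        lg_ratio = R::lgammafn(x + th) - R::lgammafn(th);
        if (want_grad) dg_ratio = R::digamma(x + th) - R::digamma(th);
        lg_xp1 = R::lgammafn(x + 1.0);
      }
      const double s = lg_ratio - lg_xp1 + th * log_t + x * log_m;
      loss += -(std::log(1.0 - pi + EPS) + s);
      if (want_grad) {
        d_pi[i] = 1.0 / (1.0 - pi + EPS);
        d_mu[i] = -(x / (mu + EPS) - (th + x) / tm);
        d_th[i] = -(dg_ratio + log_t + (mu - x) / tm);
      }
    }
  }
  loss /= (double) n;
  if (!want_grad) return List::create(_["loss"] = loss);
  // gradients of the MEAN: divide once here
  for (R_xlen_t i = 0; i < n; ++i) {
    d_pi[i] /= (double) n; d_mu[i] /= (double) n; d_th[i] /= (double) n;
  }
  return List::create(_["loss"] = loss, _["d_pi"] = d_pi,
                      _["d_mu"] = d_mu, _["d_theta"] = d_th);
}
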