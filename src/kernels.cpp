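// Hot numerical kernels for network training: the fused ZINB negative
// log-likelihood with its gradients w.r.t. the three pre-activation heads,
// and an in-place Adam update. Everything here is a straight transcription
// of the R reference implementations in R/zinb.R and R/network.R; the R
// versions remain the documented, exported surface and the tests assert the
// two paths agree.
#include <Rcpp.h>
using namespace Rcpp;

static const double EPS_PI = 1e-6;

// digamma via upward recurrence to x >= 6 plus the asymptotic series;
// |error| < 1e-12 on the range used here (x > 0).
static inline double fast_digamma(double x) {
  double r = 0.0;
  while (x < 6.0) { r -= 1.0 / x; x += 1.0; }
  double f = 1.0 / (x * x);
  return r + std::log(x) - 0.5 / x
    - f * (1.0 / 12.0 - f * (1.0 / 120.0 - f * (1.0 / 252.0 - f / 240.0)));
}

// lgamma(x + 1) for integer counts with a small-value lookup table.
static inline double lgamma_count_p1(double x, const std::vector<double>& tab) {
  int xi = (int)x;
  if (xi >= 0 && xi < (int)tab.size() && x == (double)xi) return tab[xi];
  return std::lgamma(x + 1.0);
}

// Mean ZINB negative log-likelihood over a minibatch together with the
// gradients w.r.t. the pre-activations of the three heads:
//   pi = sigmoid(a_pi), mu = clamp(sf * exp(a_mu)), theta = clamp(softplus(a_th)).
// x: counts; pi/mu/theta: post-activation parameter matrices; a_th: theta
// pre-activation; mu_free/th_free: 1 inside the clamp bounds, 0 where the
// gradient must stop.
// [[Rcpp::export]]
List zinb_loss_grad_cpp(NumericVector x, NumericVector pi, NumericVector mu,
                        NumericVector theta, NumericVector a_th,
                        NumericVector mu_free, NumericVector th_free) {
  R_xlen_t n = x.size();
  NumericVector gpi(n), gmu(n), gth(n);
  double loss = 0.0;
  const double scale = -1.0 / (double)n;
  std::vector<double> lgtab(1024);
  for (int i = 0; i < 1024; ++i) lgtab[i] = std::lgamma((double)i + 1.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double p = pi[i];
    if (p < EPS_PI) p = EPS_PI;
    if (p > 1.0 - EPS_PI) p = 1.0 - EPS_PI;
    double m = mu[i], th = theta[i];
    double lth = std::log(th), lthm = std::log(th + m);
    double lr = lth - lthm;                        // log(th/(th+mu))
    double dpi, dmu, dth, logp;
    if (xi > 0.0) {
      double nb = std::lgamma(xi + th) - std::lgamma(th) - lgamma_count_p1(xi, lgtab)
        + th * lr + xi * (std::log(m) - lthm);
      logp = std::log1p(-p) + nb;
      dpi = -1.0 / (1.0 - p);
      dmu = xi / m - (xi + th) / (th + m);
      dth = fast_digamma(xi + th) - fast_digamma(th) + lr + 1.0 - (xi + th) / (th + m);
    } else {
      double logA = th * lr;
      double A = std::exp(logA);
      double D = p + (1.0 - p) * A;
      double a = std::log(p);
      double b = std::log1p(-p) + logA;
      logp = (a > b) ? a + std::log1p(std::exp(b - a))
                     : b + std::log1p(std::exp(a - b));
      dpi = (1.0 - A) / D;
      dmu = -(1.0 - p) * A * th / ((th + m) * D);
      dth = (1.0 - p) * A * (lr + m / (th + m)) / D;
    }
    loss -= logp;
    gpi[i] = scale * dpi * p * (1.0 - p);
    gmu[i] = scale * dmu * m * mu_free[i];
    double sig = 1.0 / (1.0 + std::exp(-a_th[i]));
    gth[i] = scale * dth * sig * th_free[i];
  }
  loss /= (double)n;
  return List::create(_["loss"] = loss, _["pi"] = gpi, _["mu"] = gmu,
                      _["theta"] = gth);
}

// In-place Adam update. params, m, v are parallel lists of numeric arrays
// owned by the trainer (they are mutated without copying); grads may hold
// R_NilValue for parameters untouched this step. Gradients are first
// jointly clipped to global L2 norm `clip` (clip <= 0 disables).
// Returns the updated step counter t.
// [[Rcpp::export]]
int adam_update_cpp(List params, List m, List v, List grads, int t,
                    double lr, double beta1, double beta2, double eps,
                    double clip) {
  int np = params.size();
  double sq = 0.0;
  if (clip > 0) {
    for (int k = 0; k < np; ++k) {
      if (Rf_isNull(grads[k])) continue;
      NumericVector g = grads[k];
      for (R_xlen_t i = 0; i < g.size(); ++i) sq += g[i] * g[i];
    }
  }
  double gscale = 1.0;
  if (clip > 0) {
    double gn = std::sqrt(sq);
    if (R_finite(gn) && gn > clip) gscale = clip / gn;
  }
  t += 1;
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < np; ++k) {
    if (Rf_isNull(grads[k])) continue;
    NumericVector g = grads[k];
    NumericVector p = params[k];
    NumericVector mk = m[k];
    NumericVector vk = v[k];
    for (R_xlen_t i = 0; i < g.size(); ++i) {
      double gi = g[i] * gscale;
      mk[i] = beta1 * mk[i] + (1.0 - beta1) * gi;
      vk[i] = beta2 * vk[i] + (1.0 - beta2) * gi * gi;
      double mhat = mk[i] / bc1;
      double vhat = vk[i] / bc2;
      p[i] -= lr * mhat / (std::sqrt(vhat) + eps);
    }
  }
  return t;
}

// Fused ZINB head activations: pi = sigmoid(a_pi), mu = clamp(sf*exp(a_mu)),
// theta = clamp(softplus(a_th)), with the pre-activations capped at 50 and
// the clamp masks returned for the backward pass. sf is the per-cell size
// factor (length nrow); pass use_sf = false to ignore it.
// [[Rcpp::export]]
List heads_cpp(NumericMatrix a_pi, NumericMatrix a_mu, NumericMatrix a_th,
               NumericVector sf, bool use_sf) {
  int n = a_pi.nrow(), m = a_pi.ncol();
  NumericMatrix pi(n, m), mu(n, m), th(n, m), athc(n, m), mfree(n, m), tfree(n, m);
  const double LO = 1e-5, HI = 1e6;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      pi(i, j) = 1.0 / (1.0 + std::exp(-a_pi(i, j)));
      double am = a_mu(i, j); if (am > 50.0) am = 50.0;
      double mr = std::exp(am);
      if (use_sf) mr *= sf[i];
      double mfr = (mr > LO && mr < HI && am < 50.0) ? 1.0 : 0.0;
      mu(i, j) = mr < LO ? LO : (mr > HI ? HI : mr);
      mfree(i, j) = mfr;
      double at = a_th(i, j); if (at > 50.0) at = 50.0;
      athc(i, j) = at;
      double tr = (at > 0 ? at : 0.0) + std::log1p(std::exp(-std::fabs(at)));
      double tfr = (tr > LO && tr < HI && at < 50.0) ? 1.0 : 0.0;
      th(i, j) = tr < LO ? LO : (tr > HI ? HI : tr);
      tfree(i, j) = tfr;
    }
  }
  return List::create(_["pi"] = pi, _["mu"] = mu, _["theta"] = th,
                      _["a_th"] = athc, _["mu_free"] = mfree,
                      _["th_free"] = tfree);
}

// y = x %*% W + rep(b, each = n), fused to avoid sweep()'s copies.
// [[Rcpp::export]]
NumericMatrix addbias_cpp(NumericMatrix xw, NumericVector b) {
  int n = xw.nrow(), k = xw.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    double bj = b[j];
    for (int i = 0; i < n; ++i) out(i, j) = xw(i, j) + bj;
  }
  return out;
}
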