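// Single-precision training engine. The double-precision R implementation
// in R/network.R is the reference; this engine replays the same forward /
// backward / Adam algebra in float32 (the customary precision for
// stochastic network training) with all matrix products going through BLAS
// sgemm. The tests check the two paths agree to float tolerance.
//
// The engine owns weights, Adam state and per-batch activation caches.
// Minibatch scheduling, pseudo-label construction and the pairwise /
// clustering gradients stay in R; per step only the batch (cells x genes)
// and small gradient matrices cross the boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

static inline float fsigmoid(float x) { return 1.0f / (1.0f + std::exp(-x)); }

static inline double fd_digamma(double x) {
  double r = 0.0;
  while (x < 6.0) { r -= 1.0 / x; x += 1.0; }
  double f = 1.0 / (x * x);
  return r + std::log(x) - 0.5 / x
    - f * (1.0 / 12.0 - f * (1.0 / 120.0 - f * (1.0 / 252.0 - f / 240.0)));
}

struct Engine {
  int n_enc = 0, n_dec = 0;
  int d_latent = 0, n_genes = 0, n_batch = 0, ks = 0;
  bool use_sf = true;
  float lr = 1e-4f, b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  int t = 0;

  std::vector<fmat> W;       // all weight matrices in registry order
  std::vector<frowvec> b;    // matching bias rows
  std::vector<fmat> mW, vW;
  std::vector<frowvec> mb, vb;

  // registry order: enc layers, cls, dec layers, pi, mu, theta
  int i_cls = 0, i_dec0 = 0, i_pi = 0, i_mu = 0, i_th = 0;

  // caches from the last forward pass
  std::vector<fmat> H, D;
  fmat z, cls_prob, pi, mu, th, a_th, mu_free, th_free;
  fmat sfcol;  // size factors of the batch, cells x 1
};

static fmat as_fmat(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static NumericMatrix as_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (size_t j = 0; j < m.n_cols; ++j)
    for (size_t i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

// [[Rcpp::export]]
SEXP engine_create(List Wl, List bl, int n_enc, int n_dec, int d_latent,
                   int n_genes, int n_batch, int ks, bool use_sf,
                   double lr) {
  Engine* e = new Engine();
  e->n_enc = n_enc; e->n_dec = n_dec; e->d_latent = d_latent;
  e->n_genes = n_genes; e->n_batch = n_batch; e->ks = ks;
  e->use_sf = use_sf; e->lr = (float)lr;
  int np = Wl.size();
  for (int i = 0; i < np; ++i) {
    e->W.push_back(as_fmat(Wl[i]));
    NumericVector bv = bl[i];
    frowvec br(bv.size());
    for (int j = 0; j < bv.size(); ++j) br(j) = (float)bv[j];
    e->b.push_back(br);
  }
  e->i_cls = n_enc;
  e->i_dec0 = n_enc + 1;
  e->i_pi = n_enc + 1 + n_dec;
  e->i_mu = e->i_pi + 1;
  e->i_th = e->i_pi + 2;
  for (int i = 0; i < np; ++i) {
    e->mW.push_back(fmat(arma::size(e->W[i]), arma::fill::zeros));
    e->vW.push_back(fmat(arma::size(e->W[i]), arma::fill::zeros));
    e->mb.push_back(frowvec(e->b[i].n_elem, arma::fill::zeros));
    e->vb.push_back(frowvec(e->b[i].n_elem, arma::fill::zeros));
  }
  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void engine_reset_adam(SEXP eptr) {
  XPtr<Engine> e(eptr);
  for (size_t i = 0; i < e->W.size(); ++i) {
    e->mW[i].zeros(); e->vW[i].zeros();
    e->mb[i].zeros(); e->vb[i].zeros();
  }
  e->t = 0;
}

static void head_activations(Engine* e, const fmat& hid) {
  const float LO = 1e-5f, HI = 1e6f;
  fmat a_pi = hid * e->W[e->i_pi]; a_pi.each_row() += e->b[e->i_pi];
  fmat a_mu = hid * e->W[e->i_mu]; a_mu.each_row() += e->b[e->i_mu];
  fmat a_th = hid * e->W[e->i_th]; a_th.each_row() += e->b[e->i_th];
  size_t n = a_pi.n_rows, m = a_pi.n_cols;
  e->pi.set_size(n, m); e->mu.set_size(n, m); e->th.set_size(n, m);
  e->a_th.set_size(n, m); e->mu_free.set_size(n, m); e->th_free.set_size(n, m);
  for (size_t j = 0; j < m; ++j) {
    for (size_t i = 0; i < n; ++i) {
      e->pi(i, j) = fsigmoid(a_pi(i, j));
      float am = std::min(a_mu(i, j), 50.0f);
      float mr = std::exp(am);
      if (e->use_sf) mr *= e->sfcol(i, 0);
      e->mu_free(i, j) = (mr > LO && mr < HI && am < 50.0f) ? 1.0f : 0.0f;
      e->mu(i, j) = std::min(std::max(mr, LO), HI);
      float at = std::min(a_th(i, j), 50.0f);
      e->a_th(i, j) = at;
      float tr = std::max(at, 0.0f) + std::log1p(std::exp(-std::fabs(at)));
      e->th_free(i, j) = (tr > LO && tr < HI && at < 50.0f) ? 1.0f : 0.0f;
      e->th(i, j) = std::min(std::max(tr, LO), HI);
    }
  }
}

// Forward pass on a minibatch; caches activations for the following
// engine_step call. Returns z and the classifier probabilities.
// [[Rcpp::export]]
List engine_forward(SEXP eptr, NumericMatrix X, NumericMatrix B,
                    NumericVector sf) {
  XPtr<Engine> e(eptr);
  int n = X.nrow();
  fmat H0(n, X.ncol() + B.ncol());
  H0.cols(0, X.ncol() - 1) = as_fmat(X);
  H0.cols(X.ncol(), H0.n_cols - 1) = as_fmat(B);
  e->sfcol.set_size(n, 1);
  for (int i = 0; i < n; ++i) e->sfcol(i, 0) = (float)sf[i];

  e->H.assign(1, H0);
  for (int i = 0; i < e->n_enc; ++i) {
    fmat A = e->H[i] * e->W[i]; A.each_row() += e->b[i];
    if (i < e->n_enc - 1) A.transform([](float x) { return x > 0 ? x : 0.0f; });
    e->H.push_back(std::move(A));
  }
  e->z = e->H[e->n_enc];

  fmat logits = e->z * e->W[e->i_cls]; logits.each_row() += e->b[e->i_cls];
  fmat mx = arma::max(logits, 1);
  logits.each_col() -= mx.col(0);
  fmat ex = arma::exp(logits);
  fmat sums = arma::sum(ex, 1);
  ex.each_col() /= sums.col(0);
  e->cls_prob = ex;

  fmat D0(n, e->d_latent + e->n_batch);
  D0.cols(0, e->d_latent - 1) = e->z;
  D0.cols(e->d_latent, D0.n_cols - 1) = H0.cols(X.ncol(), H0.n_cols - 1);
  e->D.assign(1, D0);
  for (int i = 0; i < e->n_dec; ++i) {
    fmat A = e->D[i] * e->W[e->i_dec0 + i]; A.each_row() += e->b[e->i_dec0 + i];
    A.transform([](float x) { return x > 0 ? x : 0.0f; });
    e->D.push_back(std::move(A));
  }
  head_activations(e, e->D[e->n_dec]);
  return List::create(_["z"] = as_rmat(e->z),
                      _["class_probs"] = as_rmat(e->cls_prob));
}

// ZINB loss + head-preactivation gradients (double elementwise math; the
// float transcendental variants were measured slower on this platform).
static double zinb_heads(Engine* e, const NumericMatrix& Xraw,
                         fmat& Gpi, fmat& Gmu, fmat& Gth) {
  const double EPS_PI = 1e-6;
  size_t n = e->pi.n_rows, m = e->pi.n_cols;
  Gpi.set_size(n, m); Gmu.set_size(n, m); Gth.set_size(n, m);
  double loss = 0.0;
  const double scale = -1.0 / (double)(n * m);
  static std::vector<double> lgtab;
  if (lgtab.empty()) {
    lgtab.resize(2048);
    for (int i = 0; i < 2048; ++i) lgtab[i] = std::lgamma((double)i + 1.0);
  }
  for (size_t j = 0; j < m; ++j) {
    for (size_t i = 0; i < n; ++i) {
      double xi = Xraw(i, j);
      double p = e->pi(i, j);
      if (p < EPS_PI) p = EPS_PI;
      if (p > 1.0 - EPS_PI) p = 1.0 - EPS_PI;
      double mu = e->mu(i, j), th = e->th(i, j);
      double lth = std::log(th), lthm = std::log(th + mu);
      double lr = lth - lthm;
      double dpi, dmu, dth, logp;
      if (xi > 0.0) {
        double lgx = (xi < 2048 && xi == std::floor(xi))
          ? lgtab[(int)xi] : std::lgamma(xi + 1.0);
        double nb = std::lgamma(xi + th) - std::lgamma(th) - lgx
          + th * lr + xi * (std::log(mu) - lthm);
        logp = std::log1p(-p) + nb;
        dpi = -1.0 / (1.0 - p);
        dmu = xi / mu - (xi + th) / (th + mu);
        dth = fd_digamma(xi + th) - fd_digamma(th) + lr + 1.0 - (xi + th) / (th + mu);
      } else {
        double logA = th * lr;
        double A = std::exp(logA);
        double Dd = p + (1.0 - p) * A;
        double a = std::log(p);
        double bb = std::log1p(-p) + logA;
        logp = (a > bb) ? a + std::log1p(std::exp(bb - a))
                        : bb + std::log1p(std::exp(a - bb));
        dpi = (1.0 - A) / Dd;
        dmu = -(1.0 - p) * A * th / ((th + mu) * Dd);
        dth = (1.0 - p) * A * (lr + mu / (th + mu)) / Dd;
      }
      loss -= logp;
      Gpi(i, j) = (float)(scale * dpi * p * (1.0 - p));
      Gmu(i, j) = (float)(scale * dmu * mu) * e->mu_free(i, j);
      Gth(i, j) = (float)(scale * dth * fsigmoid(e->a_th(i, j))) * e->th_free(i, j);
    }
  }
  return loss / (double)(n * m);
}

// One optimizer step from the cached forward pass. d_cls / d_z may be NULL.
// Returns the minibatch ZINB loss.
// [[Rcpp::export]]
double engine_step(SEXP eptr, NumericMatrix Xraw,
                   Nullable<NumericMatrix> d_cls, Nullable<NumericMatrix> d_z,
                   double clip) {
  XPtr<Engine> e(eptr);
  int np = e->W.size();
  std::vector<fmat> gW(np);
  std::vector<frowvec> gb(np);
  std::vector<bool> used(np, false);

  fmat Gpi, Gmu, Gth;
  double l1 = zinb_heads(e, Xraw, Gpi, Gmu, Gth);

  const fmat& hid = e->D[e->n_dec];
  gW[e->i_pi] = hid.t() * Gpi; gb[e->i_pi] = arma::sum(Gpi, 0); used[e->i_pi] = true;
  gW[e->i_mu] = hid.t() * Gmu; gb[e->i_mu] = arma::sum(Gmu, 0); used[e->i_mu] = true;
  gW[e->i_th] = hid.t() * Gth; gb[e->i_th] = arma::sum(Gth, 0); used[e->i_th] = true;
  fmat dH = Gpi * e->W[e->i_pi].t() + Gmu * e->W[e->i_mu].t()
    + Gth * e->W[e->i_th].t();
  for (int i = e->n_dec - 1; i >= 0; --i) {
    fmat mask = arma::conv_to<fmat>::from(e->D[i + 1] > 0);
    fmat dA = dH % mask;
    gW[e->i_dec0 + i] = e->D[i].t() * dA;
    gb[e->i_dec0 + i] = arma::sum(dA, 0);
    used[e->i_dec0 + i] = true;
    dH = dA * e->W[e->i_dec0 + i].t();
  }
  fmat dZ = dH.cols(0, e->d_latent - 1);
  if (d_z.isNotNull()) dZ += as_fmat(NumericMatrix(d_z));
  if (d_cls.isNotNull()) {
    fmat dc = as_fmat(NumericMatrix(d_cls));
    gW[e->i_cls] = e->z.t() * dc;
    gb[e->i_cls] = arma::sum(dc, 0);
    used[e->i_cls] = true;
    dZ += dc * e->W[e->i_cls].t();
  }
  fmat dHe = dZ;
  for (int i = e->n_enc - 1; i >= 0; --i) {
    fmat dA = dHe;
    if (i < e->n_enc - 1) {
      fmat mask = arma::conv_to<fmat>::from(e->H[i + 1] > 0);
      dA = dHe % mask;
    }
    gW[i] = e->H[i].t() * dA;
    gb[i] = arma::sum(dA, 0);
    used[i] = true;
    if (i > 0) dHe = dA * e->W[i].t();
  }

  // global-norm clip
  if (clip > 0) {
    double sq = 0.0;
    for (int i = 0; i < np; ++i) {
      if (!used[i]) continue;
      sq += (double)arma::accu(gW[i] % gW[i]);
      sq += (double)arma::accu(gb[i] % gb[i]);
    }
    double gn = std::sqrt(sq);
    if (std::isfinite(gn) && gn > clip) {
      float s = (float)(clip / gn);
      for (int i = 0; i < np; ++i) {
        if (!used[i]) continue;
        gW[i] *= s; gb[i] *= s;
      }
    }
  }

  e->t += 1;
  float bc1 = 1.0f - std::pow(e->b1, (float)e->t);
  float bc2 = 1.0f - std::pow(e->b2, (float)e->t);
  for (int i = 0; i < np; ++i) {
    if (!used[i]) continue;
    e->mW[i] = e->b1 * e->mW[i] + (1.0f - e->b1) * gW[i];
    e->vW[i] = e->b2 * e->vW[i] + (1.0f - e->b2) * (gW[i] % gW[i]);
    e->W[i] -= e->lr * (e->mW[i] / bc1) / (arma::sqrt(e->vW[i] / bc2) + e->eps);
    e->mb[i] = e->b1 * e->mb[i] + (1.0f - e->b1) * gb[i];
    e->vb[i] = e->b2 * e->vb[i] + (1.0f - e->b2) * (gb[i] % gb[i]);
    e->b[i] -= e->lr * (e->mb[i] / bc1) / (arma::sqrt(e->vb[i] / bc2) + e->eps);
  }
  return l1;
}

// ZINB loss of the cached forward pass without taking a step (used for
// lambda magnitude matching on a warm-up batch).
// [[Rcpp::export]]
double engine_recon_loss(SEXP eptr, NumericMatrix Xraw) {
  XPtr<Engine> e(eptr);
  fmat Gpi, Gmu, Gth;
  return zinb_heads(e, Xraw, Gpi, Gmu, Gth);
}

// Encoder-only pass over any number of cells (no caching; used for
// full-data latent codes between epochs).
// [[Rcpp::export]]
NumericMatrix engine_latent(SEXP eptr, NumericMatrix X, NumericMatrix B) {
  XPtr<Engine> e(eptr);
  fmat H(X.nrow(), X.ncol() + B.ncol());
  H.cols(0, X.ncol() - 1) = as_fmat(X);
  H.cols(X.ncol(), H.n_cols - 1) = as_fmat(B);
  for (int i = 0; i < e->n_enc; ++i) {
    fmat A = H * e->W[i]; A.each_row() += e->b[i];
    if (i < e->n_enc - 1) A.transform([](float x) { return x > 0 ? x : 0.0f; });
    H = std::move(A);
  }
  return as_rmat(H);
}

// Copy the weights back to R (doubles), in registry order.
// [[Rcpp::export]]
List engine_weights(SEXP eptr) {
  XPtr<Engine> e(eptr);
  List Wl(e->W.size()), bl(e->b.size());
  for (size_t i = 0; i < e->W.size(); ++i) {
    Wl[i] = as_rmat(e->W[i]);
    NumericVector bv(e->b[i].n_elem);
    for (size_t j = 0; j < e->b[i].n_elem; ++j) bv[j] = e->b[i](j);
    bl[i] = bv;
  }
  return List::create(_["W"] = Wl, _["b"] = bl);
}
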