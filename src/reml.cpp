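// Dense REML criterion for a Gaussian linear mixed model with independent
// nested random-intercept components: V = sum_l sigma2_l K_l + sigma2_e I,
// where K_l = Z_l Z_l' is the 0/1 block relationship matrix of grouping
// factor l. Rows are pre-sorted by the coarsest retained grouping, so V is
// block diagonal with blocks given by `blocks`; the criterion is accumulated
// block-wise with hand-rolled Cholesky/forward-solve loops (blocks are tiny,
// so avoiding per-block allocations and LAPACK dispatch dominates the cost).
// Called hundreds of times per fit from the optimiser.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::List;

static const double BIG = 1e10;

// In-place lower Cholesky of an nb x nb column-major matrix; returns false if
// not positive definite. Also accumulates 2*sum(log(diag)) into logdet.
static bool chol_ip(double* a, int nb, double& logdet) {
  for (int j = 0; j < nb; ++j) {
    double d = a[j + j * nb];
    for (int k = 0; k < j; ++k) d -= a[j + k * nb] * a[j + k * nb];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    const double ljj = std::sqrt(d);
    a[j + j * nb] = ljj;
    logdet += 2.0 * std::log(ljj);
    for (int i = j + 1; i < nb; ++i) {
      double s = a[i + j * nb];
      for (int k = 0; k < j; ++k) s -= a[i + k * nb] * a[j + k * nb];
      a[i + j * nb] = s / ljj;
    }
  }
  return true;
}

// Forward solve L W = B for nc right-hand sides held column-major in w.
static void fsolve_ip(const double* L, int nb, double* w, int nc) {
  for (int c = 0; c < nc; ++c) {
    double* wc = w + c * nb;
    for (int i = 0; i < nb; ++i) {
      double s = wc[i];
      for (int k = 0; k < i; ++k) s -= L[i + k * nb] * wc[k];
      wc[i] = s / L[i + i * nb];
    }
  }
}

// -2 * restricted log-likelihood, including all constants, normalised so it
// equals the log density of K'y for K an orthonormal basis of the orthogonal
// complement of col(X):
//   (n-p) log(2*pi) + log|V| + log|X'V^-1 X| - log|X'X| + r'V^-1 r
// logs2: log variance components, random levels first, residual last.
// [[Rcpp::export]]
double reml_nll(const NumericVector& logs2, const NumericMatrix& X,
                const NumericVector& y, const List& K,
                double logdet_xtx, const IntegerVector& blocks) {
  const int n = X.nrow(), p = X.ncol();
  const int m = K.size();
  std::vector<double> s2(m + 1);
  for (int l = 0; l <= m; ++l) {
    double t = logs2[l];
    if (t < -60.0) t = -60.0;
    if (t > 40.0) t = 40.0;
    s2[l] = std::exp(t);
  }
  const double s2e = s2[m] > 1e-12 ? s2[m] : 1e-12;
  std::vector<const double*> Kp(m);
  for (int l = 0; l < m; ++l) {
    NumericMatrix Kl = K[l];
    Kp[l] = Kl.begin();
  }

  int maxb = 0;
  for (int b = 0; b < blocks.size(); ++b)
    if (blocks[b] > maxb) maxb = blocks[b];
  std::vector<double> V((size_t)maxb * maxb), W((size_t)maxb * (p + 1));

  double logdetV = 0.0, quad_z = 0.0;
  std::vector<double> XtViX((size_t)p * p, 0.0), XtViy((size_t)p, 0.0);

  int at = 0;
  for (int b = 0; b < blocks.size(); ++b) {
    const int nb = blocks[b];
    const int lo = at;
    at += nb;
    // block of V
    for (int j = 0; j < nb; ++j)
      for (int i = j; i < nb; ++i) {
        double v = (i == j) ? s2e : 0.0;
        for (int l = 0; l < m; ++l)
          if (s2[l] > 0.0) v += s2[l] * Kp[l][(size_t)(lo + i) + (size_t)(lo + j) * n];
        V[i + j * nb] = v;
      }
    if (!chol_ip(V.data(), nb, logdetV)) return BIG;
    // W = L^-1 [X_b, y_b]
    for (int c = 0; c < p; ++c)
      for (int i = 0; i < nb; ++i) W[i + c * nb] = X(lo + i, c);
    for (int i = 0; i < nb; ++i) W[i + p * nb] = y[lo + i];
    fsolve_ip(V.data(), nb, W.data(), p + 1);
    const double* wy = W.data() + (size_t)p * nb;
    for (int c = 0; c < p; ++c) {
      const double* wc = W.data() + (size_t)c * nb;
      for (int c2 = c; c2 < p; ++c2) {
        const double* w2 = W.data() + (size_t)c2 * nb;
        double s = 0.0;
        for (int i = 0; i < nb; ++i) s += wc[i] * w2[i];
        XtViX[c + c2 * p] += s;
      }
      double s = 0.0;
      for (int i = 0; i < nb; ++i) s += wc[i] * wy[i];
      XtViy[c] += s;
    }
    for (int i = 0; i < nb; ++i) quad_z += wy[i] * wy[i];
  }
  if (at != n) Rcpp::stop("block sizes do not sum to n");
  // symmetrise upper triangle accumulation
  for (int c = 0; c < p; ++c)
    for (int c2 = 0; c2 < c; ++c2) XtViX[c + c2 * p] = XtViX[c2 + c * p];

  // chol of XtViX (p is small), beta, and log|X'V^-1 X|
  double logdet_xvx = 0.0;
  std::vector<double> A(XtViX);
  if (!chol_ip(A.data(), p, logdet_xvx)) return BIG;
  std::vector<double> beta(XtViy);
  fsolve_ip(A.data(), p, beta.data(), 1);  // L t = XtViy
  // back solve L' beta = t
  for (int i = p - 1; i >= 0; --i) {
    double s = beta[i];
    for (int k = i + 1; k < p; ++k) s -= A[k + i * p] * beta[k];
    beta[i] = s / A[i + i * p];
  }
  double bXtViy = 0.0;
  for (int c = 0; c < p; ++c) bXtViy += beta[c] * XtViy[c];
  const double quad = quad_z - bXtViy;  // r'V^-1 r at the GLS solution

  const double nll = (double)(n - p) * std::log(2.0 * M_PI) +
                     logdetV + logdet_xvx - logdet_xtx + quad;
  if (!std::isfinite(nll)) return BIG;
  return nll;
}
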