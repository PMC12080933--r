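// Multivariate-normal orthant probabilities and the likelihood kernels built
// on them.  Two ingredients:
//
//  * a deterministic bivariate-normal CDF using the trigonometric form of
//    the Drezner-Wesolowsky integral (Gauss-Legendre quadrature on
//    [0, asin(rho)]), accurate to ~1e-12 over the whole correlation range;
//
//  * a Genz-style sequential quasi-Monte-Carlo integrator for 3- and 4-D
//    orthants, using a fixed Richtmyer (Kronecker) point set with a baker
//    transform.  A fixed point set makes the likelihood surface smooth and
//    deterministic, which the optimisers require; randomised shifts are
//    used only when an error estimate is requested.
//
// The response-pattern likelihoods (double-pass, 4 patterns; quadruple-pass,
// 16 patterns) collapse sign-symmetric patterns before integrating: with
// equal means and exchangeable correlation within a pass-pair, the two
// orderings of a disagreement have identical probability, so only 9 of the
// 16 quadruple-pass orthants are distinct.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SQRT2 = 1.4142135623730950488;

// standard normal CDF via erfc (accurate in both tails)
static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x / SQRT2);
}

static inline double phi_pdf(double x) {
  return 0.3989422804014326779 * std::exp(-0.5 * x * x);
}

// Acklam's rational approximation to the normal quantile, followed by one
// Halley refinement; ~1e-14 relative accuracy, much faster than R's qnorm.
static double phi_inv(double p) {
  if (p <= 0.0) return -37.0;
  if (p >= 1.0) return 37.0;
  static const double a[] = {-3.969683028665376e+01, 2.209460984245205e+02,
                             -2.759285104469687e+02, 1.383577518672690e+02,
                             -3.066479806614716e+01, 2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01, 1.615858368580409e+02,
                             -1.556989798598866e+02, 6.680131188771972e+01,
                             -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
                             -2.400758277161838e+00, -2.549732539343734e+00,
                             4.374664141464968e+00,  2.938163982698783e+00};
  static const double d[] = {7.784695709041462e-03, 3.224671290700398e-01,
                             2.445134137142996e+00, 3.754408661907416e+00};
  const double plow = 0.02425, phigh = 1.0 - plow;
  double x;
  if (p < plow) {
    double q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else if (p > phigh) {
    double q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else {
    double q = p - 0.5, r = q * q;
    x = (((((a[0] * r + a[1]) * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * q /
        (((((b[0] * r + b[1]) * r + b[2]) * r + b[3]) * r + b[4]) * r + 1.0);
  }
  // one Halley step
  double e = phi_cdf(x) - p;
  double u = e / phi_pdf(x);
  x = x - u / (1.0 + 0.5 * x * u);
  return x;
}

// ---- Gauss-Legendre nodes (computed once, cached) -------------------------

struct GL {
  std::vector<double> x, w;
};

static GL gauss_legendre(int n) {
  GL gl;
  gl.x.resize(n);
  gl.w.resize(n);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p1 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    gl.x[i] = -z;
    gl.x[n - 1 - i] = z;
    gl.w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    gl.w[n - 1 - i] = gl.w[i];
  }
  return gl;
}

// ---- bivariate normal CDF -------------------------------------------------

// P(Z1 <= h, Z2 <= k) for standard bivariate normal with correlation r.
static double bvn_cdf(double h, double k, double r) {
  if (r >= 1.0 - 1e-14) return phi_cdf(std::min(h, k));
  if (r <= -1.0 + 1e-14) return std::max(0.0, phi_cdf(h) + phi_cdf(k) - 1.0);
  static GL gl = gauss_legendre(48);
  double asr = std::asin(r);
  double h2 = h * h + k * k, hk = h * k;
  double sum = 0.0;
  for (size_t i = 0; i < gl.x.size(); ++i) {
    double th = 0.5 * asr * (gl.x[i] + 1.0);
    double sn = std::sin(th), cs2 = 1.0 - sn * sn;
    sum += gl.w[i] * std::exp(-(h2 - 2.0 * hk * sn) / (2.0 * cs2));
  }
  double p = phi_cdf(h) * phi_cdf(k) + (0.5 * asr) * sum / (2.0 * M_PI);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_bvn_cdf(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bvn_cdf(h[i], k[i], r[i]);
  return out;
}

// Quadrant probability P(s1*X1 > s1*c1-like region) expressed directly:
// probability that X1 is on side s1 of c1 and X2 on side s2 of c2, with
// X ~ N((m1,m2), corr rho, unit variances).
// [[Rcpp::export]]
NumericVector cpp_bvn_region(NumericVector m1, NumericVector m2,
                             NumericVector rho, NumericVector c1,
                             NumericVector c2, IntegerVector s1,
                             IntegerVector s2) {
  int n = m1.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    // P(s*X > s*c) = P(Z <= s*(m - c)) marginally; jointly correlation is
    // s1*s2*rho after flipping each coordinate to a "less than" event.
    double hh = s1[i] * (m1[i] - c1[i]);
    double kk = s2[i] * (m2[i] - c2[i]);
    out[i] = bvn_cdf(hh, kk, s1[i] * s2[i] * rho[i]);
  }
  return out;
}

// ---- Genz sequential QMC orthant, dim 3/4 ---------------------------------

// Cholesky of a small SPD matrix; returns false if not SPD.
static bool chol_small(const double* a, int n, double* L) {
  for (int i = 0; i < n * n; ++i) L[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    double s = a[j * n + j];
    for (int k = 0; k < j; ++k) s -= L[j * n + k] * L[j * n + k];
    if (s <= 1e-12) return false;
    L[j * n + j] = std::sqrt(s);
    for (int i = j + 1; i < n; ++i) {
      double t = a[i * n + j];
      for (int k = 0; k < j; ++k) t -= L[i * n + k] * L[j * n + k];
      L[i * n + j] = t / L[j * n + j];
    }
  }
  return true;
}

// P(Y > a) for Y ~ N(0, C) with C = L L', sequential Genz integration over a
// Richtmyer point set of size npts with shift vector (length dim-1).
static double genz_orthant_lower(const double* a, const double* L, int dim,
                                 int npts, const double* shift) {
  // Kronecker sequence generators: sqrt of first primes
  static const double q[3] = {1.4142135623730951, 1.7320508075688772,
                              2.23606797749979};
  double d1 = phi_cdf(a[0] / L[0]);  // P(Y1 <= a1): excluded mass
  double f1 = 1.0 - d1;
  if (dim == 1) return f1;
  double total = 0.0;
  std::vector<double> y(dim - 1);
  for (int kpt = 1; kpt <= npts; ++kpt) {
    double f = f1;
    double dprev = d1;
    for (int i = 1; i < dim; ++i) {
      double u = kpt * q[i - 1] + shift[i - 1];
      u -= std::floor(u);
      u = std::fabs(2.0 * u - 1.0);  // baker transform
      // sample Y_{i-1} | previous, conditioned on being above its limit
      double z = phi_inv(dprev + u * (1.0 - dprev));
      y[i - 1] = z;
      double mu = 0.0;
      for (int j = 0; j < i; ++j) mu += L[i * dim + j] * y[j];
      double di = phi_cdf((a[i] - mu) / L[i * dim + i]);
      f *= (1.0 - di);
      dprev = di;
    }
    total += f;
  }
  return total / npts;
}

// Orthant probability P over region where each coordinate i is above (s=+1)
// or below (s=-1) criterion c_i, for X ~ N(mean, corr).
// Returns estimate; if nshift > 1, averages nshift shifted replicates and
// reports a standard error in attribute via the list return.
// [[Rcpp::export]]
List cpp_orthant(NumericVector mean, NumericMatrix corr, IntegerVector signs,
                 NumericVector criteria, int npts, int nshift,
                 NumericVector shifts) {
  int dim = mean.size();
  std::vector<double> C(dim * dim), a(dim), L(dim * dim);
  for (int i = 0; i < dim; ++i) {
    // flip coordinates so every event reads "above the limit"
    a[i] = -(signs[i] * (mean[i] - criteria[i]));
    for (int j = 0; j < dim; ++j)
      C[i * dim + j] = signs[i] * signs[j] * corr(i, j);
  }
  if (dim == 1) {
    double p = 1.0 - phi_cdf(a[0]);
    return List::create(_["value"] = p, _["se"] = 0.0);
  }
  if (dim == 2) {
    double p = bvn_cdf(-a[0], -a[1], C[1]);
    return List::create(_["value"] = p, _["se"] = 0.0);
  }
  if (!chol_small(C.data(), dim, L.data()))
    stop("correlation matrix is not positive definite");
  if (nshift <= 1) {
    std::vector<double> sh(dim - 1, 0.0);
    for (int i = 0; i < dim - 1; ++i) sh[i] = shifts[i % shifts.size()];
    double p = genz_orthant_lower(a.data(), L.data(), dim, npts, sh.data());
    return List::create(_["value"] = p, _["se"] = NA_REAL);
  }
  double sum = 0.0, sum2 = 0.0;
  for (int m = 0; m < nshift; ++m) {
    std::vector<double> sh(dim - 1);
    for (int i = 0; i < dim - 1; ++i) sh[i] = shifts[(m * (dim - 1) + i) % shifts.size()];
    double p = genz_orthant_lower(a.data(), L.data(), dim, npts, sh.data());
    sum += p;
    sum2 += p * p;
  }
  double mu = sum / nshift;
  double var = std::max(0.0, (sum2 / nshift - mu * mu) / (nshift - 1.0));
  return List::create(_["value"] = mu, _["se"] = std::sqrt(var));
}

// ---- likelihood kernels ---------------------------------------------------

// Double-pass negative log-likelihood.  counts: 4 x L matrix in canonical
// pattern order (--, -+, +-, ++); dz: normalised mean (d-prime) per level.
// [[Rcpp::export]]
double cpp_nll_double(NumericMatrix counts, NumericVector dz, double rho,
                      NumericVector cz) {
  int L = dz.size();
  double nll = 0.0;
  for (int l = 0; l < L; ++l) {
    double d = dz[l];
    double c1 = cz[0], c2 = cz[1];
    double pmm = bvn_cdf(-(d - c1), -(d - c2), rho);
    double ppp = bvn_cdf(d - c1, d - c2, rho);
    double ppm = bvn_cdf(d - c1, -(d - c2), -rho);  // (+,-)
    double pmp = bvn_cdf(-(d - c1), d - c2, -rho);  // (-,+)
    double p[4] = {pmm, pmp, ppm, ppp};
    for (int j = 0; j < 4; ++j) {
      if (counts(j, l) > 0) {
        double pj = std::max(p[j], 1e-300);
        nll -= counts(j, l) * std::log(pj);
      }
    }
  }
  return nll;
}

// Pattern probabilities for the structured 4x4 correlation matrix
//   [1 a c c; a 1 c c; c c 1 b; c c b 1]
// with mean (d1, d1, d2, d2) and zero criteria.  Probabilities are returned
// for all 16 canonical patterns (binary counting, - = 0, + = 1, pass 1 most
// significant); sign-symmetric patterns share a single integration.
static void quad_pattern_probs(double d1, double d2, double a, double b,
                               double c, int npts, double* p16) {
  // class representatives: pair state 0 = (-,-), 1 = (+,-), 2 = (+,+)
  static const int rep[3][2] = {{-1, -1}, {1, -1}, {1, 1}};
  static const double shift0[3] = {0.8090169943749475, 0.3819660112501051,
                                   0.9270509831248424};
  double R[16] = {1, a, c, c, a, 1, c, c, c, c, 1, b, c, c, b, 1};
  double pcls[9];
  for (int f = 0; f < 3; ++f) {
    for (int g = 0; g < 3; ++g) {
      int s[4] = {rep[f][0], rep[f][1], rep[g][0], rep[g][1]};
      double mu[4] = {d1, d1, d2, d2};
      double aa[4], C[16], Lc[16];
      for (int i = 0; i < 4; ++i) {
        aa[i] = -(s[i] * mu[i]);
        for (int j = 0; j < 4; ++j) C[i * 4 + j] = s[i] * s[j] * R[i * 4 + j];
      }
      double pr;
      if (!chol_small(C, 4, Lc)) {
        pr = 1e-12;  // treated as invalid; caller penalises non-PSD upstream
      } else {
        pr = genz_orthant_lower(aa, Lc, 4, npts, shift0);
        if (pr < 1e-12) pr = 1e-12;
      }
      pcls[f * 3 + g] = pr;
    }
  }
  for (int pat = 0; pat < 16; ++pat) {
    int s1 = (pat >> 3) & 1, s2 = (pat >> 2) & 1;
    int s3 = (pat >> 1) & 1, s4 = pat & 1;
    int f = s1 + s2, g = s3 + s4;
    p16[pat] = pcls[f * 3 + g];
  }
}

// [[Rcpp::export]]
NumericVector cpp_quad_pattern_probs(double d1, double d2, double a, double b,
                                     double c, int npts) {
  NumericVector out(16);
  double p16[16];
  quad_pattern_probs(d1, d2, a, b, c, npts, p16);
  for (int i = 0; i < 16; ++i) out[i] = p16[i];
  return out;
}

// Quadruple-pass negative log-likelihood.  counts: 16 x L in canonical
// order; d1, d2: per-level normalised means for the first and second
// pass-pair.  (a, b, c) are the within-pair-1, within-pair-2 and cross-pair
// correlations.  Non-PSD parameter triples get a smooth penalty so that
// derivative-free optimisers can recover.
// [[Rcpp::export]]
double cpp_nll_quad(NumericMatrix counts, NumericVector d1, NumericVector d2,
                    double a, double b, double c, int npts) {
  double viol = 4.0 * c * c - (1.0 + a) * (1.0 + b);
  double bound = std::max(std::fabs(a), std::fabs(b)) - 1.0;
  if (viol > -1e-9 || bound > -1e-12) {
    double pen = std::max(viol + 1e-9, 0.0) + std::max(bound + 1e-12, 0.0);
    return 1e8 * (1.0 + pen);
  }
  int L = d1.size();
  double nll = 0.0;
  double p16[16];
  for (int l = 0; l < L; ++l) {
    quad_pattern_probs(d1[l], d2[l], a, b, c, npts, p16);
    for (int j = 0; j < 16; ++j) {
      double n = counts(j, l);
      if (n > 0) nll -= n * std::log(p16[j]);
    }
  }
  return nll;
}
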