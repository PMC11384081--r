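#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sum-of-exponential term expansion.
// Function ids (0-based) follow the registry order:
// 0 f2a, 1 f3a, 2 f3b, 3 f3c, 4 f4a, 5 f4b, 6 f5a, 7 f5b, 8 f5c, 9 f6a, 10 f6b
// Shape-parameter order per function matches the R registry (A's, alpha, lambdas).
static void soe_terms_c(int fn, const double* p, double lp,
                        double* c, double* mu, int& nt) {
  switch (fn) {
  case 0:  nt = 1; c[0] = p[0]; mu[0] = p[1] + lp; break;                    // A1,l1
  case 1:  nt = 2; c[0] = p[0]; c[1] = p[1];
           mu[0] = p[2] + lp; mu[1] = lp; break;                             // A1,A2,l1
  case 2:  nt = 2; c[0] = p[0] * p[1]; c[1] = p[0] * (1.0 - p[1]);
           mu[0] = p[2] + lp; mu[1] = lp; break;                             // A1,a,l1
  case 3:  nt = 2; c[0] = p[0] * (1.0 - p[1]); c[1] = p[0] * p[1];
           mu[0] = p[2] + lp; mu[1] = lp; break;                             // A1,a,l1
  case 4:  nt = 2; c[0] = p[0]; c[1] = p[1];
           mu[0] = p[2] + lp; mu[1] = p[3] + lp; break;                      // A1,A2,l1,l2
  case 5:  nt = 2; c[0] = p[0] * p[1]; c[1] = p[0] * (1.0 - p[1]);
           mu[0] = p[2] + lp; mu[1] = p[3] + lp; break;                      // A1,a,l1,l2
  case 6:  nt = 3; c[0] = p[0]; c[1] = p[1]; c[2] = -p[2];
           mu[0] = p[3] + lp; mu[1] = p[4] + lp; mu[2] = lp; break;          // A1,A2,A3,l1,l2
  case 7:  nt = 3; c[0] = p[0]; c[1] = p[1]; c[2] = -(p[0] + p[1]);
           mu[0] = p[2] + lp; mu[1] = p[3] + lp; mu[2] = p[4] + lp; break;   // A1,A2,l1,l2,l3
  case 8:  nt = 3; c[0] = p[0]; c[1] = p[1]; c[2] = p[2];
           mu[0] = p[3] + lp; mu[1] = p[4] + lp; mu[2] = lp; break;          // A1,A2,A3,l1,l2
  case 9:  nt = 3; c[0] = p[0]; c[1] = p[1]; c[2] = -p[2];
           mu[0] = p[3] + lp; mu[1] = p[4] + lp; mu[2] = p[5] + lp; break;   // A1,A2,A3,l1,l2,l3
  case 10: nt = 3; c[0] = p[0]; c[1] = p[1]; c[2] = p[2];
           mu[0] = p[3] + lp; mu[1] = p[4] + lp; mu[2] = p[5] + lp; break;   // A1,A2,A3,l1,l2,l3
  default: stop("unknown function id");
  }
}

// [[Rcpp::export]]
List cpp_soe_terms(int fn_id, NumericVector params, double lambda_phys) {
  double c[3], mu[3];
  int nt = 0;
  soe_terms_c(fn_id, params.begin(), lambda_phys, c, mu, nt);
  return List::create(_["coef"] = NumericVector(c, c + nt),
                      _["rate"] = NumericVector(mu, mu + nt));
}

// Analytic derivatives of the term expansion: dc[j][k] = d coef_j / d p_k,
// lam[j] = index of the biological rate parameter of term j (-1 if the term
// decays with the physical rate only; d mu_j / d p_lam[j] = 1).
static void soe_dterms_c(int fn, const double* p, double dc[3][6],
                         int lam[3]) {
  for (int j = 0; j < 3; ++j) {
    lam[j] = -1;
    for (int k = 0; k < 6; ++k) dc[j][k] = 0.0;
  }
  switch (fn) {
  case 0:  dc[0][0] = 1; lam[0] = 1; break;
  case 1:  dc[0][0] = 1; dc[1][1] = 1; lam[0] = 2; break;
  case 2:  dc[0][0] = p[1]; dc[0][1] = p[0];
           dc[1][0] = 1 - p[1]; dc[1][1] = -p[0]; lam[0] = 2; break;
  case 3:  dc[0][0] = 1 - p[1]; dc[0][1] = -p[0];
           dc[1][0] = p[1]; dc[1][1] = p[0]; lam[0] = 2; break;
  case 4:  dc[0][0] = 1; dc[1][1] = 1; lam[0] = 2; lam[1] = 3; break;
  case 5:  dc[0][0] = p[1]; dc[0][1] = p[0];
           dc[1][0] = 1 - p[1]; dc[1][1] = -p[0];
           lam[0] = 2; lam[1] = 3; break;
  case 6:  dc[0][0] = 1; dc[1][1] = 1; dc[2][2] = -1;
           lam[0] = 3; lam[1] = 4; break;
  case 7:  dc[0][0] = 1; dc[1][1] = 1; dc[2][0] = -1; dc[2][1] = -1;
           lam[0] = 2; lam[1] = 3; lam[2] = 4; break;
  case 8:  dc[0][0] = 1; dc[1][1] = 1; dc[2][2] = 1;
           lam[0] = 3; lam[1] = 4; break;
  case 9:  dc[0][0] = 1; dc[1][1] = 1; dc[2][2] = -1;
           lam[0] = 3; lam[1] = 4; lam[2] = 5; break;
  case 10: dc[0][0] = 1; dc[1][1] = 1; dc[2][2] = 1;
           lam[0] = 3; lam[1] = 4; lam[2] = 5; break;
  }
}

// Per-patient inner (empirical-Bayes) problem for the Laplace approximation.
struct InnerProblem {
  int fn_id, n_shape, q, n_obs;
  const int* ptype;      // 0 = positive (log scale), 1 = fraction (logit scale)
  const int* re_idx;     // -1 if the shape parameter has no random effect
  const double* fixef_t; // transformed-scale fixed effects, length n_shape
  const double* w2;      // RE variances, length q
  double s2;             // residual variance (log scale)
  const double* t;       // observation times (min)
  const double* ly;      // log observed activities
  double lphys;

  // natural-scale individual parameters at eta
  void params_at(const double* eta, double* p) const {
    for (int k = 0; k < n_shape; ++k) {
      double v = fixef_t[k] + (re_idx[k] >= 0 ? eta[re_idx[k]] : 0.0);
      p[k] = (ptype[k] == 0) ? std::exp(v) : 1.0 / (1.0 + std::exp(-v));
    }
  }

  // log model prediction at each observation; false if f(t) <= 0 anywhere
  bool logpred(const double* eta, double* m) const {
    double p[6], c[3], mu[3];
    int nt;
    params_at(eta, p);
    soe_terms_c(fn_id, p, lphys, c, mu, nt);
    for (int j = 0; j < n_obs; ++j) {
      double f = 0.0;
      for (int a = 0; a < nt; ++a) f += c[a] * std::exp(-mu[a] * t[j]);
      if (!(f > 0.0) || !std::isfinite(f)) return false;
      m[j] = std::log(f);
    }
    return true;
  }

  // log prediction plus its analytic Jacobian wrt eta (n_obs x q, row-major
  // J[j*q + k]); false if f(t) <= 0 anywhere
  bool logpred_jac(const double* eta, double* m, double* J) const {
    double p[6], c[3], mu[3], dc[3][6];
    int nt, lam[3];
    params_at(eta, p);
    soe_terms_c(fn_id, p, lphys, c, mu, nt);
    soe_dterms_c(fn_id, p, dc, lam);
    // chain factor d p_k / d eta_k on the transformed scale
    double dp[6];
    for (int k = 0; k < n_shape; ++k)
      dp[k] = (ptype[k] == 0) ? p[k] : p[k] * (1.0 - p[k]);
    for (int j = 0; j < n_obs; ++j) {
      double e[3], f = 0.0;
      for (int a = 0; a < nt; ++a) {
        e[a] = std::exp(-mu[a] * t[j]);
        f += c[a] * e[a];
      }
      if (!(f > 0.0) || !std::isfinite(f)) return false;
      m[j] = std::log(f);
      for (int k = 0; k < n_shape; ++k) {
        int r = re_idx[k];
        if (r < 0) continue;
        double dfdp = 0.0;
        for (int a = 0; a < nt; ++a) {
          dfdp += dc[a][k] * e[a];
          if (lam[a] == k) dfdp -= c[a] * t[j] * e[a];
        }
        J[j * q + r] = dfdp * dp[k] / f;
      }
    }
    return true;
  }

  double g(const double* eta) const {
    double m[16];
    if (!logpred(eta, m)) return R_PosInf;
    double val = 0.0;
    for (int j = 0; j < n_obs; ++j) {
      double r = ly[j] - m[j];
      val += 0.5 * r * r / s2;
    }
    for (int k = 0; k < q; ++k) val += 0.5 * eta[k] * eta[k] / w2[k];
    return val;
  }
};

// Solve a small symmetric linear system in place (Gaussian elimination with
// partial pivoting); returns false if numerically singular.
static bool solve_sym(int n, double* A, double* b) {
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int col = 0; col < n; ++col) {
    int best = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(A[r * n + col]) > std::fabs(A[best * n + col])) best = r;
    if (std::fabs(A[best * n + col]) < 1e-300) return false;
    if (best != col) {
      for (int k = 0; k < n; ++k) std::swap(A[col * n + k], A[best * n + k]);
      std::swap(b[col], b[best]);
    }
    for (int r = col + 1; r < n; ++r) {
      double fac = A[r * n + col] / A[col * n + col];
      for (int k = col; k < n; ++k) A[r * n + k] -= fac * A[col * n + k];
      b[r] -= fac * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < n; ++k) s -= A[r * n + k] * b[k];
    b[r] = s / A[r * n + r];
  }
  return true;
}

// log determinant via Cholesky; returns false if not positive definite
static bool chol_logdet(int n, const double* Ain, double& ld) {
  std::vector<double> L(n * n, 0.0);
  ld = 0.0;
  for (int j = 0; j < n; ++j) {
    double d = Ain[j * n + j];
    for (int k = 0; k < j; ++k) d -= L[j * n + k] * L[j * n + k];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    double Ljj = std::sqrt(d);
    L[j * n + j] = Ljj;
    ld += 2.0 * std::log(Ljj);
    for (int i = j + 1; i < n; ++i) {
      double s = Ain[i * n + j];
      for (int k = 0; k < j; ++k) s -= L[i * n + k] * L[j * n + k];
      L[i * n + j] = s / Ljj;
    }
  }
  return true;
}

// Gauss-Newton minimisation of the inner objective; eta is updated in place.
// Returns the minimised g, or +Inf on failure.
static double inner_newton(const InnerProblem& pr, double* eta, bool& ok) {
  const int q = pr.q, n = pr.n_obs;
  double m0[16];
  double J[16 * 6];
  double g0 = pr.g(eta);
  ok = false;
  if (!std::isfinite(g0)) {
    // model non-positive at warm start; retry from zero
    for (int k = 0; k < q; ++k) eta[k] = 0.0;
    g0 = pr.g(eta);
    if (!std::isfinite(g0)) return R_PosInf;
  }
  for (int iter = 0; iter < 200; ++iter) {
    if (!pr.logpred_jac(eta, m0, J)) return R_PosInf;
    // gradient and Gauss-Newton Hessian
    double grad[6] = {0, 0, 0, 0, 0, 0};
    double H[36] = {0};
    for (int j = 0; j < n; ++j) {
      double r = pr.ly[j] - m0[j];
      for (int k = 0; k < q; ++k) {
        grad[k] -= J[j * q + k] * r / pr.s2;
        for (int l = 0; l <= k; ++l)
          H[k * q + l] += J[j * q + k] * J[j * q + l] / pr.s2;
      }
    }
    for (int k = 0; k < q; ++k) {
      grad[k] += eta[k] / pr.w2[k];
      H[k * q + k] += 1.0 / pr.w2[k];
      for (int l = 0; l < k; ++l) H[l * q + k] = H[k * q + l];
    }
    double gnorm = 0.0;
    for (int k = 0; k < q; ++k) gnorm = std::max(gnorm, std::fabs(grad[k]));
    if (gnorm < 3e-11) { ok = true; return g0; }
    double Hc[36], step[6];
    std::copy(H, H + q * q, Hc);
    std::copy(grad, grad + q, step);
    if (!solve_sym(q, Hc, step)) return g0; // singular: accept current point
    double smax = 0.0;
    for (int k = 0; k < q; ++k) smax = std::max(smax, std::fabs(step[k]));
    if (smax < 1e-12) { ok = true; return g0; }
    // line search; near the mode flat steps are accepted so the gradient
    // keeps shrinking quadratically (the objective must stay smooth in the
    // population parameters for outer FD derivatives)
    double tstep = 1.0, gnew = R_PosInf;
    double etry[6];
    bool accepted = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int k = 0; k < q; ++k) etry[k] = eta[k] - tstep * step[k];
      gnew = pr.g(etry);
      if (std::isfinite(gnew) && gnew <= g0 + 1e-13 * (1.0 + std::fabs(g0))) {
        accepted = true;
        break;
      }
      tstep *= 0.5;
    }
    if (!accepted) { ok = true; return g0; }
    for (int k = 0; k < q; ++k) eta[k] = etry[k];
    g0 = (gnew < g0) ? gnew : g0;
  }
  ok = true;
  return g0;
}

// Curvature of the inner objective at the mode, in the Gauss-Newton form
// J'J/sigma^2 + diag(1/omega^2) with J the Jacobian of the log-prediction.
// This is the standard first-order (FOCE-style) curvature: always positive
// definite (bounded below by the prior precision), exact whenever the
// log-prediction is linear in eta, and free of the near-singularity the
// full second-order Hessian develops when a patient has as many random
// effects as observations.
static bool inner_hessian(const InnerProblem& pr, const double* eta,
                          double* H) {
  const int q = pr.q, n = pr.n_obs;
  double m0[16];
  double J[16 * 6];
  if (!pr.logpred_jac(eta, m0, J)) return false;
  for (int a = 0; a < q; ++a)
    for (int b = 0; b <= a; ++b) {
      double v = 0.0;
      for (int j = 0; j < n; ++j) v += J[j * q + a] * J[j * q + b];
      v /= pr.s2;
      if (a == b) v += 1.0 / pr.w2[a];
      H[a * q + b] = v;
      H[b * q + a] = v;
    }
  return true;
}

static const double LOG2PI = 1.8378770664093454836;

// Laplace-approximated -2 log marginal likelihood of the cohort.
// The inner solver always starts from eta = 0 so the objective is an exactly
// deterministic function of the population parameters (no warm-start
// hysteresis to contaminate outer finite differences); eta_warm receives the
// per-patient modes as a side product.
// [[Rcpp::export]]
double cpp_laplace_nll(NumericVector fixef_t, NumericVector omega2,
                       double sigma, int fn_id, IntegerVector ptype,
                       IntegerVector re_idx, List tlist, List ylist,
                       double lambda_phys, NumericMatrix eta_warm) {
  const int npat = tlist.size();
  const int q = omega2.size();
  InnerProblem pr;
  pr.fn_id = fn_id;
  pr.n_shape = fixef_t.size();
  pr.q = q;
  pr.ptype = ptype.begin();
  pr.re_idx = re_idx.begin();
  pr.fixef_t = fixef_t.begin();
  pr.w2 = omega2.begin();
  pr.s2 = sigma * sigma;
  pr.lphys = lambda_phys;

  double total = 0.0;
  for (int i = 0; i < npat; ++i) {
    NumericVector ti = tlist[i], lyi = ylist[i];
    pr.t = ti.begin();
    pr.ly = lyi.begin();
    pr.n_obs = ti.size();
    if (q == 0) {
      double gi = pr.g(NULL);
      if (!std::isfinite(gi)) return R_PosInf;
      total += 2.0 * gi + pr.n_obs * (LOG2PI + std::log(pr.s2));
      continue;
    }
    double eta[6] = {0, 0, 0, 0, 0, 0};
    bool ok;
    double gi = inner_newton(pr, eta, ok);
    if (!std::isfinite(gi)) return R_PosInf;
    for (int k = 0; k < q; ++k) eta_warm(i, k) = eta[k];
    double H[36], ld;
    if (!inner_hessian(pr, eta, H) || !chol_logdet(q, H, ld)) return R_PosInf;
    double li = 2.0 * gi + pr.n_obs * (LOG2PI + std::log(pr.s2)) + ld;
    for (int k = 0; k < q; ++k) li += std::log(omega2[k]);
    total += li;
  }
  return total;
}

// Empirical-Bayes detail pass at fixed population parameters: per-patient
// eta modes, inner objective values and Laplace log-determinants.
// [[Rcpp::export]]
List cpp_laplace_eb(NumericVector fixef_t, NumericVector omega2, double sigma,
                    int fn_id, IntegerVector ptype, IntegerVector re_idx,
                    List tlist, List ylist, double lambda_phys,
                    NumericMatrix eta_warm) {
  const int npat = tlist.size();
  const int q = omega2.size();
  InnerProblem pr;
  pr.fn_id = fn_id;
  pr.n_shape = fixef_t.size();
  pr.q = q;
  pr.ptype = ptype.begin();
  pr.re_idx = re_idx.begin();
  pr.fixef_t = fixef_t.begin();
  pr.w2 = omega2.begin();
  pr.s2 = sigma * sigma;
  pr.lphys = lambda_phys;

  NumericMatrix eta_out(npat, q);
  NumericVector gvals(npat), logdets(npat);
  LogicalVector okv(npat);
  for (int i = 0; i < npat; ++i) {
    NumericVector ti = tlist[i], lyi = ylist[i];
    pr.t = ti.begin();
    pr.ly = lyi.begin();
    pr.n_obs = ti.size();
    double eta[6] = {0, 0, 0, 0, 0, 0};
    bool ok = true;
    double gi = (q > 0) ? inner_newton(pr, eta, ok) : pr.g(NULL);
    double ld = NA_REAL;
    if (q > 0 && std::isfinite(gi)) {
      double H[36];
      if (inner_hessian(pr, eta, H)) {
        double l;
        if (chol_logdet(q, H, l)) ld = l; else ok = false;
      } else ok = false;
    }
    for (int k = 0; k < q; ++k) eta_out(i, k) = eta[k];
    gvals[i] = gi;
    logdets[i] = ld;
    okv[i] = ok && std::isfinite(gi);
  }
  return List::create(_["eta"] = eta_out, _["g"] = gvals,
                      _["logdet"] = logdets, _["ok"] = okv);
}
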