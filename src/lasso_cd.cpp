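// Cyclic coordinate descent for the lasso objective
//   (1/(2N)) * sum_i (y_i - b0 - x_i'beta)^2 + lambda * sum_j |beta_j|
// with an unpenalized intercept.  Residuals are kept up to date so each
// coordinate update is O(N); convergence is declared when the largest
// absolute coefficient change in a sweep falls below `tol`.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One cyclic sweep over the given columns; returns max |delta beta|.
static double sweep_cols(const double* X, const double* y, int nobs, int ldx,
                         const std::vector<int>& cols,
                         const std::vector<double>& xss, double lambda,
                         std::vector<double>& beta, std::vector<double>& r) {
  double maxd = 0.0;
  for (size_t c = 0; c < cols.size(); ++c) {
    int j = cols[c];
    if (xss[j] <= 0.0) continue;  // constant-zero column: keep beta at 0
    const double* xj = X + (size_t)j * ldx;
    double dot = 0.0;
    for (int i = 0; i < nobs; ++i) dot += xj[i] * r[i];
    double z = dot / nobs + xss[j] * beta[j];
    double bnew = soft(z, lambda) / xss[j];
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < nobs; ++i) r[i] -= d * xj[i];
      beta[j] = bnew;
      double ad = std::fabs(d);
      if (ad > maxd) maxd = ad;
    }
  }
  return maxd;
}

static double objective(double lambda, int nobs, const std::vector<double>& beta,
                        const std::vector<double>& r) {
  double rss = 0.0, l1 = 0.0;
  for (int i = 0; i < nobs; ++i) rss += r[i] * r[i];
  for (size_t j = 0; j < beta.size(); ++j) l1 += std::fabs(beta[j]);
  return rss / (2.0 * nobs) + lambda * l1;
}

static void update_intercept(int nobs, double& b0, std::vector<double>& r) {
  double m = 0.0;
  for (int i = 0; i < nobs; ++i) m += r[i];
  m /= nobs;
  b0 += m;
  for (int i = 0; i < nobs; ++i) r[i] -= m;
}

// Fit at one lambda from a warm start.  beta/r/b0 are modified in place.
// Returns the number of full sweeps used; fills obj_trace (one entry per
// full sweep, objective after the sweep) when trace is true.
static int cd_fit(const double* X, const double* y, int nobs, int ldx, int p,
                  double lambda, double tol, int maxit,
                  std::vector<double>& beta, double& b0, std::vector<double>& r,
                  const std::vector<double>& xss, bool trace,
                  std::vector<double>& obj_trace, bool& converged) {
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int nsweep = 0;
  converged = false;
  while (nsweep < maxit) {
    update_intercept(nobs, b0, r);
    double maxd = sweep_cols(X, y, nobs, ldx, all, xss, lambda, beta, r);
    ++nsweep;
    if (trace) obj_trace.push_back(objective(lambda, nobs, beta, r));
    if (maxd < tol) { converged = true; break; }
    // iterate on the active set until it stabilizes
    std::vector<int> act;
    act.reserve(p);
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
    while (nsweep < maxit) {
      update_intercept(nobs, b0, r);
      double d = sweep_cols(X, y, nobs, ldx, act, xss, lambda, beta, r);
      ++nsweep;
      if (d < tol) break;
    }
  }
  return nsweep;
}

static void col_sumsq(const double* X, int nobs, int ldx, int p,
                      std::vector<double>& xss) {
  xss.assign(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)j * ldx;
    double s = 0.0;
    for (int i = 0; i < nobs; ++i) s += xj[i] * xj[i];
    xss[j] = s / nobs;
  }
}

// [[Rcpp::export]]
List cpp_lasso(NumericMatrix X, NumericVector y, double lambda,
               NumericVector beta_init, double tol, int maxit,
               bool trace_objective) {
  int nobs = X.nrow(), p = X.ncol();
  std::vector<double> beta(p, 0.0);
  for (int j = 0; j < p && j < beta_init.size(); ++j) beta[j] = beta_init[j];
  double b0 = 0.0;
  std::vector<double> r(nobs);
  for (int i = 0; i < nobs; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) fit += X(i, j) * beta[j];
    r[i] = y[i] - fit;
  }
  std::vector<double> xss;
  col_sumsq(REAL(X), nobs, nobs, p, xss);
  std::vector<double> obj;
  bool conv = false;
  int ns = cd_fit(REAL(X), REAL(y), nobs, nobs, p, lambda, tol, maxit,
                  beta, b0, r, xss, trace_objective, obj, conv);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0,
                      _["n_sweeps"] = ns,
                      _["converged"] = conv,
                      _["objective"] = NumericVector(obj.begin(), obj.end()));
}

// Pathwise fit over a decreasing lambda grid with warm starts.
// [[Rcpp::export]]
List cpp_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                    double tol, int maxit) {
  int nobs = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix betas(p, nl);
  NumericVector b0s(nl);
  std::vector<double> beta(p, 0.0), r(REAL(y), REAL(y) + nobs), xss;
  double b0 = 0.0;
  col_sumsq(REAL(X), nobs, nobs, p, xss);
  std::vector<double> obj;
  bool conv;
  for (int l = 0; l < nl; ++l) {
    cd_fit(REAL(X), REAL(y), nobs, nobs, p, lambdas[l], tol, maxit,
           beta, b0, r, xss, false, obj, conv);
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    b0s[l] = b0;
  }
  return List::create(_["beta"] = betas, _["intercept"] = b0s);
}

// Rolling one-step-ahead forecast errors over an expanding window.
// For each m in [m_start, m_end] (counts of fitting rows): fit on rows
// 0..m-1 of X/y at every lambda, forecast row m, accumulate squared error.
// `warm = true` warm-starts each lambda's coefficients and residuals from
// the previous window (fresh pathwise cascade per window otherwise).
// Each refit screens the dictionary by the KKT correlations at the
// warm-start point (working set = current support plus columns within 10%
// of the penalty) and runs at most `maxit` capped sweeps on that set; the
// screen is recomputed at every window so drift cannot accumulate.
// [[Rcpp::export]]
List cpp_rolling_msfe(NumericMatrix X, NumericVector y, NumericVector lambdas,
                      int m_start, int m_end, double tol, int maxit,
                      bool warm) {
  int nall = X.nrow(), p = X.ncol(), nl = lambdas.size();
  if (m_end >= nall)
    stop("forecast row out of range");
  const double* Xp = REAL(X);
  const double* yp = REAL(y);
  std::vector<std::vector<double> > betas(nl, std::vector<double>(p, 0.0));
  std::vector<std::vector<double> > res(nl);
  std::vector<int> nres(nl, 0);
  std::vector<double> b0s(nl, 0.0), sse(nl, 0.0);
  // incremental per-column sums of squares
  std::vector<double> ss(p, 0.0), xss(p, 0.0), g(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = Xp + (size_t)j * nall;
    double s = 0.0;
    for (int i = 0; i < m_start - 1; ++i) s += xj[i] * xj[i];
    ss[j] = s;
  }
  for (int l = 0; l < nl; ++l) res[l].assign(nall, 0.0);
  std::vector<int> work;
  work.reserve(p);
  for (int m = m_start; m <= m_end; ++m) {
    for (int j = 0; j < p; ++j) {
      const double* xj = Xp + (size_t)j * nall;
      ss[j] += xj[m - 1] * xj[m - 1];
      xss[j] = ss[j] / m;
    }
    std::vector<double> beta_prev(p, 0.0);
    double b0_prev = 0.0;
    for (int l = 0; l < nl; ++l) {
      std::vector<double>& beta = betas[l];
      std::vector<double>& r = res[l];
      double& b0 = b0s[l];
      if (!warm) { beta = beta_prev; b0 = b0_prev; nres[l] = 0; }
      // extend residuals to cover rows [nres, m)
      for (int i = nres[l]; i < m; ++i) {
        double fit = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) fit += Xp[(size_t)j * nall + i] * beta[j];
        r[i] = yp[i] - fit;
      }
      nres[l] = m;
      // active-set descent with KKT verification: iterate coordinate
      // descent on the working set, then scan the full dictionary for
      // violators; repeat until no violator or the sweep budget is spent
      double lam = lambdas[l];
      work.clear();
      std::vector<char> inwork(p, 0);
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) { work.push_back(j); inwork[j] = 1; }
      int sweeps = 0;
      while (true) {
        while (sweeps < maxit) {
          update_intercept(m, b0, r);
          double maxd = sweep_cols(Xp, yp, m, nall, work, xss, lam, beta,
                                   r);
          ++sweeps;
          if (maxd < tol) break;
        }
        if (sweeps >= maxit) break;
        update_intercept(m, b0, r);
        bool viol = false;
        for (int j = 0; j < p; ++j) {
          if (inwork[j]) continue;
          const double* xj = Xp + (size_t)j * nall;
          double dot = 0.0;
          for (int i = 0; i < m; ++i) dot += xj[i] * r[i];
          if (std::fabs(dot / m) > lam) {
            work.push_back(j);
            inwork[j] = 1;
            viol = true;
          }
        }
        if (!viol) break;
      }
      if (!warm) { beta_prev = beta; b0_prev = b0; }
      double pred = b0;
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) pred += Xp[(size_t)j * nall + m] * beta[j];
      double e = yp[m] - pred;
      sse[l] += e * e;
    }
  }
  int nfore = m_end - m_start + 1;
  NumericVector msfe(nl);
  for (int l = 0; l < nl; ++l) msfe[l] = sse[l] / nfore;
  return List::create(_["msfe"] = msfe, _["n_forecasts"] = nfore);
}
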