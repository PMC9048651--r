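#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Coordinate descent for (1/(2n))||y - Xb||^2 + lam * sum_j w_j |b_j|.
// Converges to max coefficient change < tol; columns need not be normalized.
// [[Rcpp::export(name = ".cd_lasso")]]
NumericVector cd_lasso(const NumericMatrix& X, const NumericVector& y,
                       double lam, const NumericVector& w,
                       NumericVector binit, double tol = 1e-10,
                       int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector b = clone(binit);
  std::vector<double> a(p);           // ||x_j||^2 / n
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    a[j] = s / n;
  }
  std::vector<double> r(n);           // residual y - Xb
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j)
    if (b[j] != 0.0) for (int i = 0; i < n; ++i) r[i] -= X(i, j) * b[j];
  for (int it = 0; it < maxit; ++it) {
    double maxdelta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (a[j] <= 0.0) { b[j] = 0.0; continue; }
      double xr = 0.0;
      for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
      double z = xr / n + a[j] * b[j];
      double bnew = soft(z, lam * w[j]) / a[j];
      double d = bnew - b[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        b[j] = bnew;
        maxdelta = std::max(maxdelta, std::fabs(d) * std::sqrt(a[j]));
      }
    }
    if (maxdelta < tol) break;
  }
  return b;
}

// Warm-started lasso path over a descending lambda grid; returns p x nlam.
// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambdas,
                            const NumericVector& w, double tol = 1e-9,
                            int maxit = 10000) {
  const int p = X.ncol(), nl = lambdas.size();
  NumericMatrix out(p, nl);
  NumericVector b(p);
  for (int l = 0; l < nl; ++l) {
    b = cd_lasso(X, y, lambdas[l], w, b, tol, maxit);
    for (int j = 0; j < p; ++j) out(j, l) = b[j];
  }
  return out;
}

// Gram-form coordinate descent: arguments are G = X'X/n and c = X'y/n, so a
// full sweep costs O(p^2) independent of n. Used for the stability-selection
// subsample paths where the same gene is solved thousands of times.
// [[Rcpp::export(name = ".cd_lasso_path_gram")]]
NumericMatrix cd_lasso_path_gram(const NumericMatrix& G, const NumericVector& c,
                                 const NumericVector& lambdas,
                                 const NumericVector& w, double tol = 1e-8,
                                 int maxit = 10000) {
  const int p = G.ncol(), nl = lambdas.size();
  NumericMatrix out(p, nl);
  std::vector<double> b(p, 0.0), Gb(p, 0.0);
  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    for (int it = 0; it < maxit; ++it) {
      double maxdelta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double a = G(j, j);
        if (a <= 0.0) { b[j] = 0.0; continue; }
        double z = c[j] - Gb[j] + a * b[j];
        double bnew = soft(z, lam * w[j]) / a;
        double d = bnew - b[j];
        if (d != 0.0) {
          for (int k = 0; k < p; ++k) Gb[k] += G(k, j) * d;
          b[j] = bnew;
          maxdelta = std::max(maxdelta, std::fabs(d) * std::sqrt(a));
        }
      }
      if (maxdelta < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, l) = b[j];
  }
  return out;
}

// Pairwise mutual information from pre-binned variables. bt (targets) and br
// (regressors) hold 1-based bin indices per row, or 0 throughout a row whose
// variable is constant (MI fixed at 0 by convention).
// [[Rcpp::export(name = ".mi_matrix")]]
NumericMatrix mi_matrix(const IntegerMatrix& br, const IntegerMatrix& bt,
                        int nbins) {
  const int ntf = br.nrow(), ng = bt.nrow(), n = bt.ncol();
  NumericMatrix mi(ntf, ng);
  std::vector<int> joint(nbins * nbins);
  std::vector<int> px(nbins), py(nbins);
  for (int i = 0; i < ntf; ++i) {
    if (br(i, 0) == 0) continue;
    for (int j = 0; j < ng; ++j) {
      if (bt(j, 0) == 0) continue;
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(px.begin(), px.end(), 0);
      std::fill(py.begin(), py.end(), 0);
      for (int s = 0; s < n; ++s) {
        int a = br(i, s) - 1, b = bt(j, s) - 1;
        ++joint[a * nbins + b];
        ++px[a];
        ++py[b];
      }
      double v = 0.0, dn = (double)n;
      for (int a = 0; a < nbins; ++a) {
        if (!px[a]) continue;
        for (int b = 0; b < nbins; ++b) {
          int c = joint[a * nbins + b];
          if (c) v += (c / dn) * std::log(c * dn / ((double)px[a] * py[b]));
        }
      }
      mi(i, j) = v > 0.0 ? v : 0.0;
    }
  }
  return mi;
}

// BIC of every predictor subset (bitmask order, mask 0 = empty model) given
// the Gram system G = X'X, Xy = X'y, yy = y'y. Singular subsets get +Inf.
// [[Rcpp::export(name = ".subset_bics")]]
NumericVector subset_bics(const NumericMatrix& G, const NumericVector& Xy,
                          double yy, int n, const NumericVector& w,
                          double eps) {
  const int p = G.ncol();
  const int nmask = 1 << p;
  NumericVector out(nmask);
  const double logn = std::log((double)n);
  std::vector<int> idx(p);
  std::vector<double> A(p * p), b(p);
  for (int mask = 0; mask < nmask; ++mask) {
    int k = 0;
    for (int j = 0; j < p; ++j) if (mask & (1 << j)) idx[k++] = j;
    double rss, wsum = 0.0;
    if (k == 0) {
      rss = yy;
    } else {
      for (int r = 0; r < k; ++r) {
        for (int c = 0; c < k; ++c) A[r * k + c] = G(idx[r], idx[c]);
        b[r] = Xy[idx[r]];
        wsum += w[idx[r]];
      }
      // Cholesky in place; bail out on non-positive pivot (singular design)
      bool ok = true;
      for (int r = 0; r < k && ok; ++r) {
        double d = A[r * k + r];
        for (int c = 0; c < r; ++c) d -= A[r * k + c] * A[r * k + c];
        if (d <= 1e-12) { ok = false; break; }
        double sd = std::sqrt(d);
        A[r * k + r] = sd;
        for (int rr = r + 1; rr < k; ++rr) {
          double v = A[rr * k + r];
          for (int c = 0; c < r; ++c) v -= A[rr * k + c] * A[r * k + c];
          A[rr * k + r] = v / sd;
        }
      }
      if (!ok) { out[mask] = R_PosInf; continue; }
      // forward/back substitution for beta, then rss = yy - b'Xy
      std::vector<double> z(k), beta(k);
      for (int r = 0; r < k; ++r) {
        double v = b[r];
        for (int c = 0; c < r; ++c) v -= A[r * k + c] * z[c];
        z[r] = v / A[r * k + r];
      }
      for (int r = k - 1; r >= 0; --r) {
        double v = z[r];
        for (int c = r + 1; c < k; ++c) v -= A[c * k + r] * beta[c];
        beta[r] = v / A[r * k + r];
      }
      double fit = 0.0;
      for (int r = 0; r < k; ++r) fit += beta[r] * b[r];
      rss = yy - fit;
      if (rss < 0.0) rss = 0.0;
    }
    out[mask] = n * std::log(std::max(rss, eps) / n) + logn * wsum;
  }
  return out;
}

// Euclidean projection of v onto the l1 ball of radius z (Duchi et al. style
// sorted-threshold scheme). Used by the l-inf prox below.
static void project_l1(std::vector<double>& v, double z) {
  const int k = (int)v.size();
  double l1 = 0.0;
  for (int i = 0; i < k; ++i) l1 += std::fabs(v[i]);
  if (l1 <= z) return;
  std::vector<double> u(k);
  for (int i = 0; i < k; ++i) u[i] = std::fabs(v[i]);
  std::sort(u.begin(), u.end(), std::greater<double>());
  double csum = 0.0, theta = 0.0;
  for (int i = 0; i < k; ++i) {
    csum += u[i];
    double t = (csum - z) / (i + 1);
    if (u[i] - t > 0) theta = t; else break;
  }
  for (int i = 0; i < k; ++i) v[i] = soft(v[i], theta);
}

// Objective of the dirty multi-task model:
//   sum_k (1/(2 n_k)) ||y_k - X_k (b_k + s_k)||^2
//   + lamB * sum_j max_k |B_jk| + lamS * sum_jk w_jk |S_jk|
static double dirty_objective(const List& Xs, const List& ys,
                              const NumericMatrix& B, const NumericMatrix& S,
                              double lamB, double lamS,
                              const NumericMatrix& W) {
  const int K = Xs.size(), p = B.nrow();
  double val = 0.0;
  for (int k = 0; k < K; ++k) {
    NumericMatrix X = Xs[k];
    NumericVector y = ys[k];
    const int n = X.nrow();
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      for (int j = 0; j < p; ++j) {
        double wjk = B(j, k) + S(j, k);
        if (wjk != 0.0) f += X(i, j) * wjk;
      }
      double r = y[i] - f;
      rss += r * r;
    }
    val += rss / (2.0 * n);
  }
  for (int j = 0; j < p; ++j) {
    double mx = 0.0;
    for (int k = 0; k < K; ++k) mx = std::max(mx, std::fabs(B(j, k)));
    val += lamB * mx;
    for (int k = 0; k < K; ++k) val += lamS * W(j, k) * std::fabs(S(j, k));
  }
  return val;
}

// [[Rcpp::export(name = ".dirty_objective")]]
double dirty_objective_r(List Xs, List ys, NumericMatrix B, NumericMatrix S,
                         double lamB, double lamS, NumericMatrix W) {
  return dirty_objective(Xs, ys, B, S, lamB, lamS, W);
}

// Alternating block-coordinate minimizer for the dirty model. Assumes
// predictors standardized per task so ||x_jk||^2 / n_k is 1 (or 0 for a
// constant column, which is then never selected). Each outer iteration does
// one full sweep of S updates (per-entry soft thresholding) and one full
// sweep of B row updates (l-inf prox via l1-ball projection); both are exact
// coordinate minimizations, so the objective never increases.
// [[Rcpp::export(name = ".dirty_fit")]]
List dirty_fit(List Xs, List ys, double lamB, double lamS, NumericMatrix W,
               double tol = 1e-4, int maxit = 200) {
  const int K = Xs.size();
  NumericMatrix X0 = Xs[0];
  const int p = X0.ncol();
  NumericMatrix B(p, K), S(p, K);
  std::vector<std::vector<double> > res(K);
  std::vector<std::vector<double> > anorm(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix X = Xs[k];
    NumericVector y = ys[k];
    const int n = X.nrow();
    res[k].assign(y.begin(), y.end());
    anorm[k].resize(p);
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
      anorm[k][j] = s / n;
    }
  }
  double obj = dirty_objective(Xs, ys, B, S, lamB, lamS, W);
  NumericVector trace(maxit + 1);
  trace[0] = obj;
  int it = 0;
  bool converged = false;
  std::vector<double> c(K), bnew(K);
  for (it = 1; it <= maxit; ++it) {
    // S-step
    for (int k = 0; k < K; ++k) {
      NumericMatrix X = Xs[k];
      const int n = X.nrow();
      for (int j = 0; j < p; ++j) {
        double a = anorm[k][j];
        if (a <= 0.0) { S(j, k) = 0.0; continue; }
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += X(i, j) * res[k][i];
        double z = xr / n + a * S(j, k);
        double snew = soft(z, lamS * W(j, k)) / a;
        double d = snew - S(j, k);
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) res[k][i] -= X(i, j) * d;
          S(j, k) = snew;
        }
      }
    }
    // B-step, row by row; requires equal curvature across tasks (standardized)
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < K; ++k) {
        double a = anorm[k][j];
        if (a <= 0.0) { c[k] = 0.0; continue; }
        NumericMatrix X = Xs[k];
        const int n = X.nrow();
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += X(i, j) * res[k][i];
        c[k] = xr / n + a * B(j, k);
      }
      // prox of lamB * max_k |.| at c: c minus projection on l1 ball lamB
      std::vector<double> proj(c);
      project_l1(proj, lamB);
      for (int k = 0; k < K; ++k) {
        bnew[k] = (anorm[k][j] > 0.0) ? c[k] - proj[k] : 0.0;
        double d = bnew[k] - B(j, k);
        if (d != 0.0) {
          NumericMatrix X = Xs[k];
          const int n = X.nrow();
          for (int i = 0; i < n; ++i) res[k][i] -= X(i, j) * d;
          B(j, k) = bnew[k];
        }
      }
    }
    double objnew = dirty_objective(Xs, ys, B, S, lamB, lamS, W);
    trace[it] = objnew;
    double denom = std::max(std::fabs(obj), 1e-12);
    if ((obj - objnew) / denom < tol) { obj = objnew; converged = true; break; }
    obj = objnew;
  }
  int nt = converged ? it + 1 : maxit + 1;
  NumericVector tr(nt);
  for (int i = 0; i < nt; ++i) tr[i] = trace[i];
  return List::create(_["B"] = B, _["S"] = S, _["objective"] = obj,
                      _["trace"] = tr, _["converged"] = converged,
                      _["iterations"] = std::min(it, maxit));
}
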