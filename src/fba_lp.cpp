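#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex with Bland's rule (anti-cycling).
// Problems here are tiny (tens of rows/columns), so a textbook tableau
// implementation is both fast enough and easy to audit.

namespace {

const double EPS = 1e-9;

struct LPResult {
  int status;            // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  std::vector<double> x; // primal solution (original variables only)
  double obj;
};

// min cost'x  s.t.  A x (dir) b,  x >= 0
// dir: -1 '<=', 0 '==', +1 '>='
//
// Big-M single-phase simplex on a flat tableau. Pricing is Dantzig (most
// negative reduced cost) for speed on these highly degenerate systems,
// switching to Bland's rule after a pivot budget to guarantee termination.
LPResult lp_core(const std::vector<std::vector<double> > &A,
                 std::vector<double> b,
                 std::vector<int> dir,
                 const std::vector<double> &cost) {
  int m = (int)A.size();
  int n = m ? (int)A[0].size() : 0;
  LPResult res;
  res.status = 0;
  res.x.assign(n, 0.0);
  res.obj = 0.0;
  if (m == 0 || n == 0) return res;

  // normalise rhs >= 0
  std::vector<std::vector<double> > a(A);
  for (int i = 0; i < m; ++i) {
    if (b[i] < 0) {
      b[i] = -b[i];
      dir[i] = -dir[i];
      for (int j = 0; j < n; ++j) a[i][j] = -a[i][j];
    }
  }

  int nslack = 0, nart = 0;
  for (int i = 0; i < m; ++i) {
    if (dir[i] != 0) ++nslack;
    if (dir[i] >= 0) ++nart;
  }
  int total = n + nslack + nart;
  int stride = total + 1;

  double cmax = 1.0;
  for (int j = 0; j < n; ++j) cmax = std::max(cmax, std::fabs(cost[j]));
  const double BIGM = 1e5 * cmax;

  std::vector<double> T((size_t)m * stride, 0.0);
  std::vector<double> c(total, 0.0);
  std::vector<int> basis(m);
  std::vector<bool> isart(total, false);
  for (int j = 0; j < n; ++j) c[j] = cost[j];
  int js = n, ja = n + nslack;
  for (int i = 0; i < m; ++i) {
    double *row = &T[(size_t)i * stride];
    for (int j = 0; j < n; ++j) row[j] = a[i][j];
    row[total] = b[i];
    if (dir[i] < 0) {               // <= : slack enters basis
      row[js] = 1.0; basis[i] = js; ++js;
    } else if (dir[i] > 0) {        // >= : surplus + artificial
      row[js] = -1.0; ++js;
      row[ja] = 1.0; isart[ja] = true; c[ja] = BIGM; basis[i] = ja; ++ja;
    } else {                        // == : artificial
      row[ja] = 1.0; isart[ja] = true; c[ja] = BIGM; basis[i] = ja; ++ja;
    }
  }

  // reduced-cost row
  std::vector<double> z(stride);
  for (int j = 0; j <= total; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += c[basis[i]] * T[(size_t)i * stride + j];
    z[j] = ((j < total) ? c[j] : 0.0) - s;
  }

  const int maxiter = 2000 + 200 * total;
  const int dantzig_budget = 200 + 10 * total;
  int iter = 0;
  while (iter++ < maxiter) {
    int enter = -1;
    if (iter <= dantzig_budget) {
      double zmin = -EPS;
      for (int j = 0; j < total; ++j)
        if (z[j] < zmin) { zmin = z[j]; enter = j; }
    } else {  // Bland: smallest index, guarantees termination
      for (int j = 0; j < total; ++j)
        if (z[j] < -EPS) { enter = j; break; }
    }
    if (enter < 0) break;
    int leave = -1; double best = 0.0;
    for (int i = 0; i < m; ++i) {
      double aij = T[(size_t)i * stride + enter];
      if (aij > EPS) {
        double ratio = T[(size_t)i * stride + total] / aij;
        if (leave < 0 || ratio < best - EPS ||
            (ratio < best + EPS && basis[i] < basis[leave])) {
          leave = i; best = ratio;
        }
      }
    }
    if (leave < 0) { res.status = 2; return res; }
    double *prow = &T[(size_t)leave * stride];
    double p = prow[enter];
    for (int j = 0; j <= total; ++j) prow[j] /= p;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double *row = &T[(size_t)i * stride];
      double f = row[enter];
      if (f != 0.0) for (int j = 0; j <= total; ++j) row[j] -= f * prow[j];
    }
    double f = z[enter];
    if (f != 0.0) for (int j = 0; j <= total; ++j) z[j] -= f * prow[j];
    basis[leave] = enter;
  }
  if (iter > maxiter) { res.status = 3; return res; }

  double art_sum = 0.0;
  for (int i = 0; i < m; ++i)
    if (isart[basis[i]]) art_sum += T[(size_t)i * stride + total];
  if (art_sum > 1e-7) { res.status = 1; return res; }

  // refine: recompute the basic solution from the original (normalised)
  // data with the final basis, discarding accumulated pivot drift
  {
    // auxiliary column j >= n is +/-1 in exactly one row
    std::vector<int> auxrow(total, -1);
    std::vector<double> auxval(total, 0.0);
    int js2 = n, ja2 = n + nslack;
    for (int i = 0; i < m; ++i) {
      if (dir[i] < 0) { auxrow[js2] = i; auxval[js2] = 1.0; ++js2; }
      else if (dir[i] > 0) {
        auxrow[js2] = i; auxval[js2] = -1.0; ++js2;
        auxrow[ja2] = i; auxval[ja2] = 1.0; ++ja2;
      } else { auxrow[ja2] = i; auxval[ja2] = 1.0; ++ja2; }
    }
    std::vector<double> B((size_t)m * (m + 1), 0.0);
    for (int i = 0; i < m; ++i) {
      for (int k = 0; k < m; ++k) {
        int col = basis[k];
        B[(size_t)i * (m + 1) + k] =
          (col < n) ? a[i][col]
                    : ((auxrow[col] == i) ? auxval[col] : 0.0);
      }
      B[(size_t)i * (m + 1) + m] = b[i];
    }
    // Gaussian elimination with partial pivoting
    bool ok = true;
    for (int p = 0; p < m && ok; ++p) {
      int piv = p;
      double best = std::fabs(B[(size_t)p * (m + 1) + p]);
      for (int i = p + 1; i < m; ++i) {
        double v = std::fabs(B[(size_t)i * (m + 1) + p]);
        if (v > best) { best = v; piv = i; }
      }
      if (best < 1e-12) { ok = false; break; }
      if (piv != p)
        for (int j = p; j <= m; ++j)
          std::swap(B[(size_t)p * (m + 1) + j], B[(size_t)piv * (m + 1) + j]);
      double d = B[(size_t)p * (m + 1) + p];
      for (int i = p + 1; i < m; ++i) {
        double f = B[(size_t)i * (m + 1) + p] / d;
        if (f != 0.0)
          for (int j = p; j <= m; ++j)
            B[(size_t)i * (m + 1) + j] -= f * B[(size_t)p * (m + 1) + j];
      }
    }
    if (ok) {
      std::vector<double> xb(m);
      for (int p = m - 1; p >= 0; --p) {
        double s = B[(size_t)p * (m + 1) + m];
        for (int j = p + 1; j < m; ++j)
          s -= B[(size_t)p * (m + 1) + j] * xb[j];
        xb[p] = s / B[(size_t)p * (m + 1) + p];
      }
      for (int k = 0; k < m; ++k)
        if (basis[k] < n) res.x[basis[k]] = xb[k];
    } else {
      for (int i = 0; i < m; ++i)
        if (basis[i] < n) res.x[basis[i]] = T[(size_t)i * stride + total];
    }
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cost[j] * res.x[j];
  res.obj = obj;
  return res;
}

} // namespace

//' Solve a small dense linear program
//'
//' Minimises \code{cost'x} subject to \code{A x (dir) b} and \code{x >= 0},
//' where \code{dir} codes the row sense (-1 for <=, 0 for ==, +1 for >=).
//' A two-phase tableau simplex with Bland's rule; intended for the small
//' metabolic LPs this package generates, not as a general-purpose solver.
//'
//' @param A constraint matrix
//' @param b right-hand side
//' @param dir integer vector of row senses
//' @param cost objective coefficients
//' @return list with \code{status} (0 optimal, 1 infeasible, 2 unbounded,
//'   3 iteration limit), \code{x}, and \code{objective}
//' @keywords internal
// [[Rcpp::export]]
List lp_solve_dense(NumericMatrix A, NumericVector b, IntegerVector dir,
                    NumericVector cost) {
  int m = A.nrow(), n = A.ncol();
  std::vector<std::vector<double> > a(m, std::vector<double>(n));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) a[i][j] = A(i, j);
  std::vector<double> bb(b.begin(), b.end());
  std::vector<int> dd(dir.begin(), dir.end());
  std::vector<double> cc(cost.begin(), cost.end());
  LPResult r = lp_core(a, bb, dd, cc);
  return List::create(_["status"] = r.status,
                      _["x"] = NumericVector(r.x.begin(), r.x.end()),
                      _["objective"] = r.obj);
}

// Lexicographic FBA solve on a compiled (irreversible) network.
//
// Stage 1: maximise flux through the objective column subject to
//   S f = 0, f >= 0, f <= ub (finite entries), sum(mask * f) <= cap.
// Stage 2: among optima, minimise total flux sum(f) (deterministic vertex).
//
// S is metabolites x reactions (dense; networks here are tiny), ub may
// contain Inf, cap may be Inf (constraint disabled).
// [[Rcpp::export]]
List fba_solve_cpp(NumericMatrix S, NumericVector ub, double cap,
                   NumericVector mask, int obj_col) {
  int m = S.nrow(), n = S.ncol();
  // active columns: upper bound meaningfully positive. Bounds below
  // 1e-8 umol/step/unit are sub-bacterium-scale; dropping them keeps the
  // tableau away from degenerate slivers that strand artificials at
  // audit-visible levels.
  std::vector<int> act;
  act.reserve(n);
  for (int j = 0; j < n; ++j) if (ub[j] > 1e-8) act.push_back(j);
  int na = (int)act.size();
  NumericVector flux(n);
  int oj = -1;
  for (int k = 0; k < na; ++k) if (act[k] == obj_col - 1) oj = k;
  if (na == 0 || oj < 0) {
    return List::create(_["status"] = 0, _["flux"] = flux,
                        _["objective"] = 0.0, _["sum_flux"] = 0.0);
  }

  // keep metabolite rows touched by an active column
  std::vector<int> rows;
  rows.reserve(m);
  for (int i = 0; i < m; ++i) {
    bool any = false;
    for (int k = 0; k < na && !any; ++k)
      if (S(i, act[k]) != 0.0) any = true;
    if (any) rows.push_back(i);
  }
  int mr = (int)rows.size();

  bool has_cap = R_finite(cap);
  // any column inside the summed-flux cap is itself bounded by the cap;
  // clamping its upper bound there leaves the feasible set unchanged and
  // keeps the tableau well scaled when uptake bounds are enormous
  std::vector<double> ube(na);
  for (int k = 0; k < na; ++k) {
    double u = ub[act[k]];
    if (has_cap && mask[act[k]] != 0.0 && u > cap) u = cap;
    ube[k] = u;
  }
  std::vector<int> ubrows;
  for (int k = 0; k < na; ++k) if (R_finite(ube[k])) ubrows.push_back(k);

  int m1 = mr + (has_cap ? 1 : 0) + (int)ubrows.size();
  std::vector<std::vector<double> > A(m1, std::vector<double>(na, 0.0));
  std::vector<double> b(m1, 0.0);
  std::vector<int> dir(m1, 0);
  for (int i = 0; i < mr; ++i)
    for (int k = 0; k < na; ++k) A[i][k] = S(rows[i], act[k]);
  int r = mr;
  if (has_cap) {
    for (int k = 0; k < na; ++k) A[r][k] = mask[act[k]];
    b[r] = cap; dir[r] = -1; ++r;
  }
  for (size_t q = 0; q < ubrows.size(); ++q) {
    A[r][ubrows[q]] = 1.0;
    b[r] = ube[ubrows[q]];
    dir[r] = -1; ++r;
  }

  std::vector<double> c1(na, 0.0);
  c1[oj] = -1.0; // maximise objective flux
  LPResult s1 = lp_core(A, b, dir, c1);
  if (s1.status != 0) {
    return List::create(_["status"] = s1.status, _["flux"] = flux,
                        _["objective"] = 0.0, _["sum_flux"] = 0.0);
  }
  double opt = s1.x[oj];
  // an optimum below 1e-8 umol/step/unit is growth of a fraction of a
  // bacterium: return the exact zero solution (always feasible) rather
  // than a vertex made of solver-tolerance noise
  if (opt < 1e-8) {
    return List::create(_["status"] = 0, _["flux"] = flux,
                        _["objective"] = 0.0, _["sum_flux"] = 0.0);
  }

  // stage 2: pin objective, minimise total flux
  std::vector<std::vector<double> > A2(A);
  std::vector<double> b2(b);
  std::vector<int> dir2(dir);
  std::vector<double> pin(na, 0.0);
  pin[oj] = 1.0;
  A2.push_back(pin);
  b2.push_back(opt * (1.0 - 1e-9));
  dir2.push_back(1);
  std::vector<double> c2(na, 1.0);
  LPResult s2 = lp_core(A2, b2, dir2, c2);

  const LPResult &best = (s2.status == 0) ? s2 : s1;
  double sumf = 0.0;
  for (int k = 0; k < na; ++k) {
    double v = best.x[k];
    if (v < 0 && v > -1e-7) v = 0.0;
    flux[act[k]] = v;
    sumf += v;
  }
  return List::create(_["status"] = 0, _["flux"] = flux,
                      _["objective"] = flux[obj_col - 1],
                      _["sum_flux"] = sumf);
}
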