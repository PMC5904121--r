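// Dense bounded-variable two-phase primal simplex.
//
// Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
// with all structural bounds finite (flux-balance models use +/-1000 as
// "unbounded"). Written for the small dense systems of core metabolic
// models (tens of metabolites x tens of reactions). The basis inverse is
// maintained by product-form (eta) updates with periodic refactorisation,
// keeping knockout screening loops fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int STATUS_LOWER = 0;
const int STATUS_UPPER = 1;
const int STATUS_BASIC = 2;

bool refactorise(const mat& A, const ivec& basis, mat& Binv) {
  const uword m = A.n_rows;
  mat B(m, m);
  for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
  return inv(Binv, B);
}

// One simplex phase (maximisation). Variables carry bounds lo/hi; `vstat`
// holds nonbasic-at-lower/upper or basic; `basis` maps row -> variable.
// `xval` is kept consistent for all variables. `Binv` must be valid on
// entry for the given basis.
int run_phase(const mat& A, const vec& cost, vec& xval, const vec& lo,
              const vec& hi, ivec& vstat, ivec& basis, mat& Binv,
              double tol, int max_iter, double& objective) {
  const uword m = A.n_rows;
  const uword n = A.n_cols;
  int iter = 0;
  int since_refactor = 0;
  const int bland_after = 4 * static_cast<int>(n + m);

  while (true) {
    if (++iter > max_iter) return 3;
    const bool bland = iter > bland_after;

    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = cost[basis[i]];
    vec y = Binv.t() * cB;

    // pricing
    int enter = -1;
    double best = tol;
    for (uword j = 0; j < n; ++j) {
      if (vstat[j] == STATUS_BASIC) continue;
      if (hi[j] - lo[j] < tol) continue; // fixed variable can never improve
      double d = cost[j] - dot(y, A.col(j));
      double gain = (vstat[j] == STATUS_LOWER) ? d : -d;
      if (gain > tol) {
        if (bland) { enter = static_cast<int>(j); break; }
        if (gain > best) { best = gain; enter = static_cast<int>(j); }
      }
    }
    if (enter < 0) { // optimal for this phase
      objective = dot(cost, xval);
      return 0;
    }

    vec w = Binv * A.col(enter);
    // entering moves by t >= 0 away from its bound
    const double dir = (vstat[enter] == STATUS_LOWER) ? 1.0 : -1.0;
    // basic variables move by -dir * w * t
    double tmax = hi[enter] - lo[enter]; // bound-to-bound flip
    int leave = -1;                      // row index of leaving basic
    for (uword i = 0; i < m; ++i) {
      const double wi = dir * w[i];
      const uword bi = basis[i];
      double limit = datum::inf;
      if (wi > tol)       limit = (xval[bi] - lo[bi]) / wi;
      else if (wi < -tol) limit = (hi[bi] - xval[bi]) / (-wi);
      if (limit < tmax - 1e-12) {
        tmax = limit;
        leave = static_cast<int>(i);
      }
    }
    if (!std::isfinite(tmax)) return 2; // unbounded ray

    if (tmax < 0) tmax = 0; // numerical guard (degenerate step)

    // apply step
    xval[enter] += dir * tmax;
    for (uword i = 0; i < m; ++i) xval[basis[i]] -= dir * w[i] * tmax;

    if (leave < 0) {
      // bound flip: entering jumps to its opposite bound, basis unchanged
      vstat[enter] = (vstat[enter] == STATUS_LOWER) ? STATUS_UPPER
                                                    : STATUS_LOWER;
      xval[enter] = (vstat[enter] == STATUS_LOWER) ? lo[enter] : hi[enter];
    } else {
      const uword out = basis[leave];
      // leaving variable rests on whichever bound it hit
      const double wl = dir * w[leave];
      vstat[out] = (wl > 0) ? STATUS_LOWER : STATUS_UPPER;
      xval[out] = (vstat[out] == STATUS_LOWER) ? lo[out] : hi[out];
      basis[leave] = enter;
      vstat[enter] = STATUS_BASIC;

      // product-form update of the basis inverse, with periodic (and
      // pivot-degeneracy triggered) refactorisation for numerical safety
      const double piv = w[leave];
      if (std::abs(piv) < 1e-9 || ++since_refactor >= 64) {
        if (!refactorise(A, basis, Binv)) return 1;
        since_refactor = 0;
      } else {
        rowvec eta = Binv.row(leave) / piv;
        for (uword i = 0; i < m; ++i) {
          if (static_cast<int>(i) == leave) continue;
          Binv.row(i) -= w[i] * eta;
        }
        Binv.row(leave) = eta;
      }
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".simplex_lp")]]
Rcpp::List simplex_lp(const arma::vec& cvec, const arma::mat& A,
                      const arma::vec& b, const arma::vec& lb,
                      const arma::vec& ub, const bool maximize = true,
                      const double tol = 1e-9, const int max_iter = 50000) {
  const uword m = A.n_rows;
  const uword n = A.n_cols;
  if (cvec.n_elem != n || b.n_elem != m || lb.n_elem != n || ub.n_elem != n)
    Rcpp::stop("inconsistent LP dimensions");
  for (uword j = 0; j < n; ++j) {
    if (!std::isfinite(lb[j]) || !std::isfinite(ub[j]))
      Rcpp::stop("simplex_lp requires finite variable bounds");
    if (lb[j] > ub[j] + tol)
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = R_NilValue);
  }

  // augmented problem: n structural + m artificial columns
  mat Aa(m, n + m, fill::zeros);
  Aa.cols(0, n - 1) = A;
  vec lo(n + m), hi(n + m), xval(n + m, fill::zeros);
  ivec vstat(n + m);
  for (uword j = 0; j < n; ++j) {
    lo[j] = lb[j];
    hi[j] = ub[j];
    // start nonbasic at the bound of smaller magnitude (0 when it is one)
    vstat[j] = (std::abs(lb[j]) <= std::abs(ub[j])) ? STATUS_LOWER
                                                    : STATUS_UPPER;
    xval[j] = (vstat[j] == STATUS_LOWER) ? lo[j] : hi[j];
  }
  vec r = b - A * xval.head(n);
  ivec basis(m);
  mat Binv(m, m, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    const double s = (r[i] >= 0) ? 1.0 : -1.0;
    Aa(i, n + i) = s;
    Binv(i, i) = s; // inverse of the diagonal artificial basis
    lo[n + i] = 0.0;
    hi[n + i] = datum::inf; // only artificials may be unbounded above
    xval[n + i] = std::abs(r[i]);
    vstat[n + i] = STATUS_BASIC;
    basis[i] = static_cast<int>(n + i);
  }

  // phase 1: maximise -(sum of artificials)
  vec c1(n + m, fill::zeros);
  for (uword i = 0; i < m; ++i) c1[n + i] = -1.0;
  double obj1 = 0.0;
  int st = run_phase(Aa, c1, xval, lo, hi, vstat, basis, Binv, tol,
                     max_iter, obj1);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  double infeas = 0.0;
  for (uword i = 0; i < m; ++i) infeas += xval[n + i];
  if (st == 1 || infeas > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  // phase 2: pin artificials to zero, restore true objective
  for (uword i = 0; i < m; ++i) { lo[n + i] = 0.0; hi[n + i] = 0.0; }
  vec c2(n + m, fill::zeros);
  for (uword j = 0; j < n; ++j) c2[j] = maximize ? cvec[j] : -cvec[j];
  double obj2 = 0.0;
  st = run_phase(Aa, c2, xval, lo, hi, vstat, basis, Binv, tol, max_iter,
                 obj2);
  if (st == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "unbounded",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  vec xout = xval.head(n);
  double obj = dot(cvec, xout);
  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = xout);
}
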