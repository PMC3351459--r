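// Bounded-variable revised simplex for the flux-balance LPs used throughout
// the package: maximize c'x subject to A x = b, l <= x <= u, with all bounds
// finite (callers resolve "unbounded" model bounds to a finite cap first).
//
// Two phases: phase 1 drives artificial variables (one per row) to zero,
// phase 2 optimizes the caller's objective with the artificials pinned at 0.
// Dantzig pricing with a Bland fallback after a degeneracy streak; the basis
// is refactorized at every iteration (problems here are small and dense).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FEAS_TOL = 1e-9;
static const double PIVOT_TOL = 1e-9;
static const double COST_TOL = 1e-9;

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
struct LpResult {
  int status;
  double objective;
  vec x;
};

// One run of the bounded simplex on max c'x, A x = b (A already includes
// artificial columns), starting from the given basis and nonbasic states.
// state: 0 = nonbasic at lower, 1 = nonbasic at upper, 2 = basic.
static int simplex_core(const mat& A, const vec& b, const vec& c,
                        const vec& l, const vec& u,
                        uvec& basis, ivec& state, vec& x,
                        int max_iter) {
  const uword m = A.n_rows;
  const uword n = A.n_cols;
  int degen_streak = 0;
  bool bland = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));

    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = c(basis(i));

    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 1; // singular basis
    // recompute basic values from nonbasic ones for numerical hygiene
    vec rhs = b;
    for (uword j = 0; j < n; ++j)
      if (state(j) != 2 && x(j) != 0.0) rhs -= A.col(j) * x(j);
    vec xB;
    if (!solve(xB, B, rhs, solve_opts::no_approx)) return 1;
    for (uword i = 0; i < m; ++i) x(basis(i)) = xB(i);

    // pricing
    uword q = n; // entering column
    double best = COST_TOL;
    int dir = 0; // +1 entering rises from lower, -1 falls from upper
    for (uword j = 0; j < n; ++j) {
      if (state(j) == 2) continue;
      double dj = c(j) - dot(y, A.col(j));
      if (state(j) == 0 && dj > COST_TOL) {
        if (bland) { q = j; dir = +1; break; }
        if (dj > best) { best = dj; q = j; dir = +1; }
      } else if (state(j) == 1 && dj < -COST_TOL) {
        if (bland) { q = j; dir = -1; break; }
        if (-dj > best) { best = -dj; q = j; dir = -1; }
      }
    }
    if (q == n) return 0; // optimal

    vec w;
    if (!solve(w, B, A.col(q), solve_opts::no_approx)) return 1;

    // ratio test: step t >= 0 along +/- direction of x_q
    double t = u(q) - l(q); // bound flip
    uword leave = m;        // index into basis, m = bound flip
    int leave_to = 0;       // 0 -> lower, 1 -> upper
    for (uword i = 0; i < m; ++i) {
      double wi = dir * w(i); // basic change is -t * wi
      double cand;
      if (wi > PIVOT_TOL) {
        cand = (x(basis(i)) - l(basis(i))) / wi;
        if (cand < t - FEAS_TOL) { t = cand; leave = i; leave_to = 0; }
      } else if (wi < -PIVOT_TOL) {
        cand = (u(basis(i)) - x(basis(i))) / (-wi);
        if (cand < t - FEAS_TOL) { t = cand; leave = i; leave_to = 1; }
      }
    }
    if (!std::isfinite(t)) return 2; // unbounded (finite bounds make this rare)
    if (t < 0) t = 0;

    if (t <= FEAS_TOL) {
      if (++degen_streak > 40) bland = true;
    } else {
      degen_streak = 0; bland = false;
    }

    // apply step
    x(q) += dir * t;
    for (uword i = 0; i < m; ++i) x(basis(i)) -= t * dir * w(i);

    if (leave == m) {
      state(q) = (dir == +1) ? 1 : 0; // hit its other bound, stays nonbasic
    } else {
      uword p = basis(leave);
      x(p) = (leave_to == 0) ? l(p) : u(p);
      state(p) = leave_to;
      basis(leave) = q;
      state(q) = 2;
    }
  }
  return 3;
}

// [[Rcpp::export(name = ".lp_simplex")]]
Rcpp::List lp_simplex(const arma::mat& A, const arma::vec& b,
                      const arma::vec& c, const arma::vec& l,
                      const arma::vec& u, int max_iter = 20000) {
  const uword m = A.n_rows;
  const uword n = A.n_cols;

  for (uword j = 0; j < n; ++j) {
    if (l(j) > u(j) + FEAS_TOL) {
      return Rcpp::List::create(Rcpp::Named("status") = 1,
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = R_NilValue);
    }
  }

  // start: every structural variable at the bound of smaller magnitude
  vec x(n + m, fill::zeros);
  ivec state(n + m);
  for (uword j = 0; j < n; ++j) {
    bool at_lower = std::abs(l(j)) <= std::abs(u(j));
    x(j) = at_lower ? l(j) : u(j);
    state(j) = at_lower ? 0 : 1;
  }

  vec r = b;
  for (uword j = 0; j < n; ++j)
    if (x(j) != 0.0) r -= A.col(j) * x(j);

  // artificial columns: +/- unit so the artificial starts nonnegative
  mat Afull(m, n + m);
  Afull.cols(0, n - 1) = A;
  Afull.cols(n, n + m - 1).zeros();
  vec lf(n + m), uf(n + m);
  lf.subvec(0, n - 1) = l;
  uf.subvec(0, n - 1) = u;
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    double s = (r(i) >= 0) ? 1.0 : -1.0;
    Afull(i, n + i) = s;
    lf(n + i) = 0.0;
    uf(n + i) = std::abs(r(i)) + 1.0; // headroom; phase 1 drives to 0
    x(n + i) = std::abs(r(i));
    basis(i) = n + i;
    state(n + i) = 2;
  }

  // phase 1: maximize -(sum of artificials)
  vec c1(n + m, fill::zeros);
  for (uword i = 0; i < m; ++i) c1(n + i) = -1.0;
  int st = simplex_core(Afull, b, c1, lf, uf, basis, state, x, max_iter);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  double art = 0;
  for (uword i = 0; i < m; ++i) art += std::abs(x(n + i));
  if (art > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  // pin artificials at zero for phase 2
  for (uword i = 0; i < m; ++i) { uf(n + i) = 0.0; x(n + i) = 0.0; }
  vec c2(n + m, fill::zeros);
  c2.subvec(0, n - 1) = c;
  st = simplex_core(Afull, b, c2, lf, uf, basis, state, x, max_iter);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  vec xs = x.subvec(0, n - 1);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = dot(c, xs),
                            Rcpp::Named("x") = xs);
}
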