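// Dense bounded-variable revised simplex.
//
// Solves   min c'x  s.t.  A x = b,  l <= x <= u   (all bounds finite).
// Two phases with artificial variables; explicit basis inverse maintained by
// product-form updates and periodically refactorised.  Dantzig pricing with a
// Bland fallback after a fixed iteration count guarantees termination on the
// degenerate problems that flux balance models routinely produce.
//
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit /
// numerical failure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double TOL_DJ   = 1e-9;   // reduced-cost (optimality) tolerance
const double TOL_PIV  = 1e-9;   // smallest acceptable pivot element
const int    REFACTOR = 100;    // pivots between basis refactorisations

enum VStat { AT_LB = 0, AT_UB = 1, BASIC = 2 };

struct Work {
  mat A;                 // m x N (structural + artificial columns)
  vec b, c, l, u;
  int m, n, N;           // rows, structural cols, total cols
  std::vector<int> stat; // per-variable status
  std::vector<int> basis;// basis[i] = column basic in row i
  mat Binv;
  vec xB;
  vec x;                 // full solution (nonbasic entries live here)

  void refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
    Binv = inv(B);
  }
  void recompute_xB() {
    vec rhs = b;
    for (int j = 0; j < N; ++j)
      if (stat[j] != BASIC && x[j] != 0.0) rhs -= A.col(j) * x[j];
    xB = Binv * rhs;
  }
};

// One simplex phase on the current cost vector. Returns 0 optimal, 2
// unbounded, 3 iteration limit.
int phase(Work &w, const vec &cost, long maxit) {
  long iter = 0, since_refactor = 0;
  long bland_after = 4L * (w.N + w.m);

  for (;;) {
    if (++iter > maxit) return 3;
    bool bland = iter > bland_after;

    // duals and reduced costs
    vec cB(w.m);
    for (int i = 0; i < w.m; ++i) cB[i] = cost[w.basis[i]];
    rowvec y = cB.t() * w.Binv;

    int q = -1;
    double best = 0.0;
    for (int j = 0; j < w.N; ++j) {
      if (w.stat[j] == BASIC) continue;
      if (j >= w.n && w.u[j] <= w.l[j]) continue;  // retired artificial
      double dj = cost[j] - dot(y, w.A.col(j));
      double viol = 0.0;
      if (w.stat[j] == AT_LB && dj < -TOL_DJ) viol = -dj;
      else if (w.stat[j] == AT_UB && dj > TOL_DJ) viol = dj;
      if (viol > 0.0) {
        if (bland) { q = j; break; }           // first (smallest) index
        if (viol > best + 1e-15) { best = viol; q = j; }
      }
    }
    if (q < 0) return 0;  // optimal for this phase

    double sigma = (w.stat[q] == AT_LB) ? 1.0 : -1.0;
    vec d = w.Binv * w.A.col(q);   // change in xB per unit increase of t

    // ratio test: xB_new = xB - sigma * t * d,  t in [0, u_q - l_q].
    // Pass 1 finds the minimum ratio, pass 2 picks the leaving row among
    // (near-)ties: smallest variable index under Bland, largest pivot
    // magnitude otherwise.
    const double TIE = 1e-10;
    double tmin = w.u[q] - w.l[q];
    for (int i = 0; i < w.m; ++i) {
      double coef = sigma * d[i];
      double t;
      if (coef > TOL_PIV)       t = (w.xB[i] - w.l[w.basis[i]]) / coef;
      else if (coef < -TOL_PIV) t = (w.xB[i] - w.u[w.basis[i]]) / coef;
      else continue;
      if (t < 0.0) t = 0.0;
      if (t < tmin) tmin = t;
    }
    if (tmin > 1e290) return 2;  // unbounded (cannot occur with finite bounds)

    int r = -1;             // leaving row (-1 = bound flip)
    int leave_to = AT_LB;
    double piv_best = 0.0;
    for (int i = 0; i < w.m; ++i) {
      double coef = sigma * d[i];
      double t;
      int to;
      if (coef > TOL_PIV)       { t = (w.xB[i] - w.l[w.basis[i]]) / coef; to = AT_LB; }
      else if (coef < -TOL_PIV) { t = (w.xB[i] - w.u[w.basis[i]]) / coef; to = AT_UB; }
      else continue;
      if (t < 0.0) t = 0.0;
      if (t > tmin + TIE) continue;
      bool take = (r < 0) ||
                  (bland ? (w.basis[i] < w.basis[r])
                         : (std::abs(d[i]) > piv_best));
      if (take) { r = i; leave_to = to; piv_best = std::abs(d[i]); }
    }
    double tmax = tmin;

    if (r < 0) {
      // entering variable flips to its opposite bound
      w.xB -= sigma * tmax * d;
      w.x[q] = (w.stat[q] == AT_LB) ? w.u[q] : w.l[q];
      w.stat[q] = (w.stat[q] == AT_LB) ? AT_UB : AT_LB;
      continue;
    }

    // pivot: q enters on row r, basis[r] leaves to bound `leave_to`
    int p = w.basis[r];
    w.xB -= sigma * tmax * d;
    double xq = (w.stat[q] == AT_LB) ? w.l[q] + tmax : w.u[q] - tmax;
    w.x[p] = (leave_to == AT_LB) ? w.l[p] : w.u[p];
    w.stat[p] = leave_to;
    w.basis[r] = q;
    w.stat[q] = BASIC;
    w.x[q] = 0.0;  // tracked through xB from now on
    w.xB[r] = xq;

    // product-form update of Binv
    double alpha = d[r];
    if (std::abs(alpha) < TOL_PIV || ++since_refactor >= REFACTOR) {
      w.refactor();
      w.recompute_xB();
      since_refactor = 0;
    } else {
      rowvec br = w.Binv.row(r) / alpha;
      for (int i = 0; i < w.m; ++i) {
        if (i == r) continue;
        if (d[i] != 0.0) w.Binv.row(i) -= d[i] * br;
      }
      w.Binv.row(r) = br;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".simplex_cpp")]]
Rcpp::List simplex_cpp(const arma::mat &A, const arma::vec &b,
                       const arma::vec &c, const arma::vec &l,
                       const arma::vec &u) {
  Work w;
  w.m = (int)A.n_rows; w.n = (int)A.n_cols; w.N = w.n + w.m;
  w.A = join_rows(A, eye(w.m, w.m));
  w.b = b;
  w.c = join_cols(c, zeros(w.m));
  w.l = join_cols(l, zeros(w.m));
  w.u = join_cols(u, zeros(w.m));  // artificial ubs set below
  w.stat.assign(w.N, AT_LB);
  w.x = w.l;                        // structurals start at lower bound
  w.basis.resize(w.m);

  // start from the bound of smaller magnitude (fewer big-M artefacts)
  for (int j = 0; j < w.n; ++j) {
    if (std::abs(w.u[j]) < std::abs(w.l[j])) { w.stat[j] = AT_UB; w.x[j] = w.u[j]; }
  }

  vec r = b;
  for (int j = 0; j < w.n; ++j)
    if (w.x[j] != 0.0) r -= w.A.col(j) * w.x[j];
  double big = 2.0 * (norm(r, "inf") + 1.0);
  for (int i = 0; i < w.m; ++i) {
    int aj = w.n + i;
    if (r[i] < 0.0) w.A.col(aj) *= -1.0;
    w.u[aj] = big;
    w.basis[i] = aj;
    w.stat[aj] = BASIC;
  }
  w.Binv = eye(w.m, w.m);
  for (int i = 0; i < w.m; ++i) if (r[i] < 0.0) w.Binv(i, i) = -1.0;
  w.xB = abs(r);

  long maxit = 20000L + 200L * (long)(w.N + w.m);

  // phase 1: minimise sum of artificials
  vec c1 = join_cols(zeros(w.n), ones(w.m));
  int st = phase(w, c1, maxit);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = 3);

  double infeas = 0.0;
  for (int i = 0; i < w.m; ++i)
    if (w.basis[i] >= w.n) infeas += std::abs(w.xB[i]);
  for (int j = w.n; j < w.N; ++j)
    if (w.stat[j] != BASIC) infeas += std::abs(w.x[j]);
  double feastol = 1e-8 * (1.0 + norm(b, "inf"));
  if (infeas > std::max(1e-7, feastol))
    return Rcpp::List::create(Rcpp::Named("status") = 1);

  // retire artificials: clamp to zero so phase 2 cannot move them
  for (int j = w.n; j < w.N; ++j) { w.u[j] = 0.0; w.x[j] = 0.0; }

  st = phase(w, w.c, maxit);
  if (st == 2) return Rcpp::List::create(Rcpp::Named("status") = 2);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = 3);

  // assemble solution
  w.refactor();
  w.recompute_xB();
  vec xfull = w.x;
  for (int i = 0; i < w.m; ++i) xfull[w.basis[i]] = w.xB[i];
  vec xs = xfull.subvec(0, w.n - 1);
  double obj = dot(c, xs);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0,
      Rcpp::Named("x") = Rcpp::NumericVector(xs.begin(), xs.end()),
      Rcpp::Named("objective") = obj);
}
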