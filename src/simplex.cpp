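// Dense two-phase simplex and the CCR linear programs built on it.
//
// The multiplier-form CCR program for facility o is
//   max u'y_o  s.t.  v'x_o = 1,  u'y_k - v'x_k <= 0 (k in reference set),
//                    optional assurance-region rows, u, v >= 0.
// We solve its dual (the input-oriented CRS envelopment form, R+J rows,
// K + #restriction + 2 columns), which is far smaller, and recover the
// multiplier weights (u, v) as the dual prices of its rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double TOL = 1e-9;

struct LPResult {
  int status;  // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  double obj;
  vec x;
  vec y;  // dual prices, one per row, signed for the original row senses
};

// Pivot on (prow, pcol) of tableau T, update basis.
inline void pivot(mat& T, uvec& basis, uword prow, uword pcol) {
  T.row(prow) /= T(prow, pcol);
  for (uword i = 0; i < T.n_rows; ++i) {
    if (i == prow) continue;
    double f = T(i, pcol);
    if (std::abs(f) > 0.0) T.row(i) -= f * T.row(prow);
  }
  basis(prow) = pcol;
}

// Run simplex iterations on T (last row = reduced costs, last col = rhs),
// minimizing. Columns with allowed(j) == 0 never enter.
// Returns 0 optimal, 2 unbounded, 3 iteration cap.
int iterate(mat& T, uvec& basis, const uvec& allowed) {
  const uword m = T.n_rows - 1, N = T.n_cols - 1;
  const uword cap = 50 * (m + N) + 1000;
  for (uword it = 0; it < cap; ++it) {
    bool bland = it > 10 * (m + N);
    // entering column
    uword pcol = N;  // sentinel
    double best = -TOL;
    for (uword j = 0; j < N; ++j) {
      if (!allowed(j)) continue;
      double rc = T(m, j);
      if (bland) {
        if (rc < -TOL) { pcol = j; break; }
      } else if (rc < best) {
        best = rc; pcol = j;
      }
    }
    if (pcol == N) return 0;  // optimal
    // ratio test
    uword prow = m;
    double rbest = datum::inf;
    for (uword i = 0; i < m; ++i) {
      double a = T(i, pcol);
      if (a > TOL) {
        double r = T(i, N) / a;
        if (r < rbest - TOL || (r < rbest + TOL && (prow == m || basis(i) < basis(prow)))) {
          rbest = r; prow = i;
        }
      }
    }
    if (prow == m) return 2;  // unbounded
    pivot(T, basis, prow, pcol);
  }
  return 3;
}

// Minimize c'x subject to A x (dir) b, x >= 0.
// dir: -1 "<=", 0 "=", +1 ">=".
LPResult lp_solve(const vec& c, mat A, const ivec& dir, vec b) {
  const uword m = A.n_rows, n = A.n_cols;
  ivec d = dir;
  vec flip = ones<vec>(m);  // track row sign flips for the dual
  for (uword i = 0; i < m; ++i) {
    if (b(i) < 0) { A.row(i) *= -1.0; b(i) *= -1.0; d(i) = -d(i); flip(i) = -1.0; }
  }
  uword nslack = 0, nart = 0;
  for (uword i = 0; i < m; ++i) {
    if (d(i) != 0) ++nslack;
    if (d(i) != -1) ++nart;  // ">=" and "=" rows need an artificial
  }
  const uword N = n + nslack + nart;
  mat Astd(m, N, fill::zeros);
  Astd.cols(0, n - 1) = A;
  vec cstd(N, fill::zeros);
  cstd.subvec(0, n - 1) = c;
  uvec basis(m);
  uvec is_art(N, fill::zeros);
  uword js = n, ja = n + nslack;
  for (uword i = 0; i < m; ++i) {
    if (d(i) == -1) {            // slack, initial basic
      Astd(i, js) = 1.0; basis(i) = js; ++js;
    } else if (d(i) == 1) {      // surplus + artificial
      Astd(i, js) = -1.0; ++js;
      Astd(i, ja) = 1.0; is_art(ja) = 1; basis(i) = ja; ++ja;
    } else {                     // artificial only
      Astd(i, ja) = 1.0; is_art(ja) = 1; basis(i) = ja; ++ja;
    }
  }

  mat T(m + 1, N + 1, fill::zeros);
  T.submat(0, 0, m - 1, N - 1) = Astd;
  T.col(N).subvec(0, m - 1) = b;

  LPResult res;
  res.x = vec(n, fill::zeros);
  res.y = vec(m, fill::zeros);
  res.obj = datum::nan;

  uvec allowed(N, fill::ones);
  // Phase 1: minimize sum of artificials.
  if (nart > 0) {
    for (uword j = 0; j < N; ++j) T(m, j) = is_art(j) ? 1.0 : 0.0;
    T(m, N) = 0.0;
    for (uword i = 0; i < m; ++i)
      if (is_art(basis(i))) T.row(m) -= T.row(i);
    int st = iterate(T, basis, allowed);
    if (st == 3) { res.status = 3; return res; }
    if (-T(m, N) > 1e-7 * (1.0 + norm(b, "inf"))) { res.status = 1; return res; }
    // drive remaining artificials out of the basis where possible
    for (uword i = 0; i < m; ++i) {
      if (is_art(basis(i))) {
        for (uword j = 0; j < n + nslack; ++j) {
          if (std::abs(T(i, j)) > TOL) { pivot(T, basis, i, j); break; }
        }
      }
    }
    for (uword j = 0; j < N; ++j) if (is_art(j)) allowed(j) = 0;
  }

  // Phase 2: true objective.
  for (uword j = 0; j < N; ++j) T(m, j) = allowed(j) ? cstd(j) : 0.0;
  T(m, N) = 0.0;
  for (uword i = 0; i < m; ++i) {
    double cb = cstd(basis(i));
    if (cb != 0.0 && !is_art(basis(i))) T.row(m) -= cb * T.row(i);
  }
  int st = iterate(T, basis, allowed);
  if (st != 0) { res.status = st; return res; }

  for (uword i = 0; i < m; ++i)
    if (basis(i) < n) res.x(basis(i)) = T(i, N);
  res.obj = dot(c, res.x);

  // Duals: solve B' y = c_B on the (possibly flipped) rows, then unflip.
  mat B(m, m);
  vec cB(m);
  for (uword i = 0; i < m; ++i) { B.col(i) = Astd.col(basis(i)); cB(i) = cstd(basis(i)); }
  vec y;
  if (solve(y, B.t(), cB, solve_opts::no_approx)) res.y = y % flip;
  res.status = 0;
  return res;
}

// Build and solve the dual of the CCR multiplier program for one facility.
// Xref: K x R, Yref: K x J reference technology; xo, yo the evaluated unit.
// Bound vectors (length J-1 / R-1) add assurance-region rows; pass empty
// vectors for unrestricted DEA.
LPResult ccr_dual(const mat& Xref, const mat& Yref,
                  const vec& xo, const vec& yo,
                  const vec& Lout, const vec& Uout,
                  const vec& Lin, const vec& Uin) {
  const uword K = Xref.n_rows, R = Xref.n_cols, J = Yref.n_cols;
  const bool ob = Lout.n_elem > 0, ib = Lin.n_elem > 0;
  const uword nob = ob ? 2 * (J - 1) : 0, nib = ib ? 2 * (R - 1) : 0;
  const uword ncol = K + nob + nib + 2;
  mat D(J + R, ncol, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    for (uword j = 0; j < J; ++j) D(j, k) = Yref(k, j);
    for (uword r = 0; r < R; ++r) D(J + r, k) = -Xref(k, r);
  }
  uword col = K;
  if (ob) {
    for (uword j = 1; j < J; ++j) {
      D(0, col) = Lout(j - 1); D(j, col) = -1.0; ++col;  // L_j u_1 - u_j <= 0
      D(0, col) = -Uout(j - 1); D(j, col) = 1.0; ++col;  // u_j - U_j u_1 <= 0
    }
  }
  if (ib) {
    for (uword r = 1; r < R; ++r) {
      D(J, col) = Lin(r - 1); D(J + r, col) = -1.0; ++col;
      D(J, col) = -Uin(r - 1); D(J + r, col) = 1.0; ++col;
    }
  }
  for (uword r = 0; r < R; ++r) {  // nu+ / nu- (free normalization multiplier)
    D(J + r, col) = xo(r);
    D(J + r, col + 1) = -xo(r);
  }
  vec c(ncol, fill::zeros);
  c(col) = 1.0; c(col + 1) = -1.0;
  vec rhs(J + R, fill::zeros);
  rhs.subvec(0, J - 1) = yo;
  ivec dir(J + R);
  dir.fill(1);  // all >=
  return lp_solve(c, D, dir, rhs);
}

}  // namespace

// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::vec& c, const arma::mat& A,
                        const arma::ivec& dir, const arma::vec& b,
                        bool maximize = false) {
  LPResult r = lp_solve(maximize ? vec(-c) : c, A, dir, b);
  double obj = r.obj;
  vec y = r.y;
  if (maximize && r.status == 0) { obj = -obj; y = -y; }
  return Rcpp::List::create(
      Rcpp::Named("status") = r.status,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("solution") = r.x,
      Rcpp::Named("duals") = y);
}

// Score every facility in `eval_idx` (1-based) against the technology spanned
// by rows `ref_idx`; with exclude_self the evaluated row is dropped from its
// own reference set (super-efficiency). Returns per-facility scores, the
// multiplier weights attaining them, the envelopment intensities, and an LP
// status code (1 = infeasible leave-one-out program, score reported +Inf).
// [[Rcpp::export(name = ".ccr_batch_cpp")]]
Rcpp::List ccr_batch_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::uvec& ref_idx, const arma::uvec& eval_idx,
                         bool exclude_self,
                         const arma::vec& Lout, const arma::vec& Uout,
                         const arma::vec& Lin, const arma::vec& Uin) {
  const uword R = X.n_cols, J = Y.n_cols, ne = eval_idx.n_elem;
  vec scores(ne, fill::zeros);
  ivec status(ne, fill::zeros);
  mat U(ne, J, fill::zeros), V(ne, R, fill::zeros);
  mat Xref0 = X.rows(ref_idx - 1), Yref0 = Y.rows(ref_idx - 1);
  for (uword e = 0; e < ne; ++e) {
    uword o = eval_idx(e) - 1;
    mat Xref = Xref0, Yref = Yref0;
    if (exclude_self) {
      uvec keep = find(ref_idx != eval_idx(e));
      if (keep.n_elem == ref_idx.n_elem) {
        // evaluated unit not in reference set anyway
      } else {
        Xref = Xref0.rows(keep);
        Yref = Yref0.rows(keep);
      }
    }
    LPResult r = ccr_dual(Xref, Yref, X.row(o).t(), Y.row(o).t(),
                          Lout, Uout, Lin, Uin);
    status(e) = r.status;
    if (r.status == 1) {
      scores(e) = datum::inf;  // multiplier program unbounded
    } else if (r.status == 0) {
      scores(e) = r.obj;
      U.row(e) = r.y.subvec(0, J - 1).t();
      V.row(e) = r.y.subvec(J, J + R - 1).t();
    } else {
      scores(e) = datum::nan;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("scores") = scores,
      Rcpp::Named("u") = U,
      Rcpp::Named("v") = V,
      Rcpp::Named("status") = status);
}
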