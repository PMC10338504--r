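// Batch kernels for the round-outcome Markov chain of a memory-one strategy
// pair. Outcome order: (s1,CC),(s1,CD),(s1,DC),(s1,DD),(s2,CC),...,(s2,DD).
// Strategy rows are 8-entry (state 1 block, state 2 block); q is
// (q1_CC,q1_CD,q1_DD,q2_CC,q2_CD,q2_DD).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// q slot for action pair index 0..3 (CC,CD,DC,DD): mixed pairs share one entry
static const int QIDX[4] = {0, 1, 1, 2};

static void fill_transition(mat &M, const double *p, const double *pt,
                            const double *q) {
  for (int w = 0; w < 8; ++w) {
    int s = w / 4;           // current state (0-based)
    int ap = w % 4;          // previous action pair
    int a = ap / 2, at = ap % 2;
    double qv = q[3 * s + QIDX[ap]];
    for (int w2 = 0; w2 < 8; ++w2) {
      int s2 = w2 / 4;
      int ap2 = w2 % 4;
      double x = (s2 == 0) ? qv : 1.0 - qv;
      double pf = p[4 * s2 + 2 * a + at];      // focal, next state, (a, at)
      double y = (ap2 / 2 == 0) ? pf : 1.0 - pf;
      double pc = pt[4 * s2 + 2 * at + a];     // co-player, transposed order
      double yt = (ap2 % 2 == 0) ? pc : 1.0 - pc;
      M(w, w2) = x * y * yt;
    }
  }
}

// stationary distribution: solve v' (M - I + ones) = 1'
static bool stationary(const mat &M, vec &v) {
  mat A = M.t();
  A.diag() -= 1.0;
  A += 1.0; // adds 1 to every element (ones matrix)
  bool ok = solve(v, A, ones<vec>(8), solve_opts::fast);
  if (!ok) return false;
  double s = accu(v);
  if (std::abs(s - 1.0) > 1e-4 || v.min() < -1e-4) return false;
  v = clamp(v, 0.0, datum::inf);
  v /= accu(v);
  return true;
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::vec &p, const arma::vec &pt,
                                const arma::vec &q) {
  mat M(8, 8);
  fill_transition(M, p.memptr(), pt.memptr(), q.memptr());
  return M;
}

static inline double payoff_focal(const vec &v, double b1, double b2, double c) {
  return b1 * (v(0) + v(2)) + b2 * (v(4) + v(6)) - c * (v(0) + v(1) + v(4) + v(5));
}
static inline double payoff_coplayer(const vec &v, double b1, double b2, double c) {
  return b1 * (v(0) + v(1)) + b2 * (v(4) + v(5)) - c * (v(0) + v(2) + v(4) + v(6));
}
static inline double coop_rate(const vec &v) {
  return v(0) + 0.5 * (v(1) + v(2)) + v(4) + 0.5 * (v(5) + v(6));
}

// All ordered-pair payoffs and cooperation rates for one strategy set.
// P: n x 8 matrix of effective (error-adjusted) strategies. One linear solve
// per unordered pair gives the focal payoff, co-player payoff and the
// (player-symmetric) cooperation rate.
// [[Rcpp::export]]
Rcpp::List cpp_pair_matrices(const arma::mat &P, const arma::vec &q,
                             double b1, double b2, double c) {
  int n = P.n_rows;
  mat PI(n, n), G(n, n);
  mat M(8, 8);
  vec v;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      rowvec pi_ = P.row(i), pj_ = P.row(j);
      fill_transition(M, pi_.memptr(), pj_.memptr(), q.memptr());
      if (!stationary(M, v))
        Rcpp::stop("no unique stationary distribution for pair (%d, %d)", i + 1, j + 1);
      PI(i, j) = payoff_focal(v, b1, b2, c);
      PI(j, i) = payoff_coplayer(v, b1, b2, c);
      G(i, j) = coop_rate(v);
      G(j, i) = G(i, j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("pi") = PI, Rcpp::Named("gamma") = G);
}

// Self-play payoff and cooperation rate for each strategy in a set.
// [[Rcpp::export]]
arma::mat cpp_selfplay(const arma::mat &P, const arma::vec &q,
                       double b1, double b2, double c) {
  int n = P.n_rows;
  mat out(n, 2);
  mat M(8, 8);
  vec v;
  for (int i = 0; i < n; ++i) {
    rowvec pi_ = P.row(i);
    fill_transition(M, pi_.memptr(), pi_.memptr(), q.memptr());
    if (!stationary(M, v))
      Rcpp::stop("no unique stationary distribution for strategy %d", i + 1);
    out(i, 0) = payoff_focal(v, b1, b2, c);
    out(i, 1) = coop_rate(v);
  }
  return out;
}
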