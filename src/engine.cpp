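#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Core Monte Carlo engine. All stochastic choices consume R's RNG stream
// (unif_rand), so set.seed() at the R level makes whole runs bit-reproducible
// and pure-R reference implementations can replay the same stream.
//
// Conventions (documented in the methods vignette and relied on by tests):
//  - sites are indexed linearly in column-major order (R's layout), 0-based;
//  - synchronous payoff accrual walks sites in linear order and resolves each
//    site's South then East edge, drawing the owner's abstention first, then
//    the neighbour's (each undirected edge is realized exactly once; on the
//    side-2 torus edges carry multiplicity two, keeping every degree at 4);
//  - neighbour order is N, S, W, E everywhere;
//  - utilities are compared with absolute tolerance 1e-9 in the synchronous
//    imitation rule (payoffs are short sums of {0, L, 1, T}, so true ties are
//    representable).

static const double TIE_TOL = 1e-9;

static inline int wrap(int i, int n) { return (i % n + n) % n; }

// payoff to the first argument's strategy when both actually play
static inline double pd_payoff(int sx, int sy, double T, double R, double P,
                               double S) {
  if (sx == 0) return (sy == 0) ? R : S;
  return (sy == 0) ? T : P;
}

struct Geometry {
  int side, N;
  std::vector<int> nb;  // N*4 neighbour linear indices, order N,S,W,E
  explicit Geometry(int side_) : side(side_), N(side_ * side_), nb(N * 4) {
    for (int col = 0; col < side; ++col) {
      for (int row = 0; row < side; ++row) {
        int i = col * side + row;
        nb[i * 4 + 0] = col * side + wrap(row - 1, side);           // N
        nb[i * 4 + 1] = col * side + wrap(row + 1, side);           // S
        nb[i * 4 + 2] = wrap(col - 1, side) * side + row;           // W
        nb[i * 4 + 3] = wrap(col + 1, side) * side + row;           // E
      }
    }
  }
};

// one synchronous payoff accrual pass; utilities written into u
static void accrue_sync(const Geometry &g, const int *s, const int *a,
                        const double *levels, double T, double L, double R,
                        double P, double S, double *u) {
  std::fill(u, u + g.N, 0.0);
  for (int i = 0; i < g.N; ++i) {
    // owned edges: South (nb index 1) then East (nb index 3)
    for (int e = 1; e <= 3; e += 2) {
      int j = g.nb[i * 4 + e];
      bool abst_i = unif_rand() < levels[a[i]];
      bool abst_j = unif_rand() < levels[a[j]];
      if (abst_i || abst_j) {
        u[i] += L;
        u[j] += L;
      } else {
        u[i] += pd_payoff(s[i], s[j], T, R, P, S);
        u[j] += pd_payoff(s[j], s[i], T, R, P, S);
      }
    }
  }
}

// synchronous best-neighbour imitation from a fixed utility ledger;
// writes the new state into s_new/a_new (deterministic, consumes no RNG)
static void imitate_sync(const Geometry &g, const int *s, const int *a,
                         const double *u, int *s_new, int *a_new) {
  for (int i = 0; i < g.N; ++i) {
    double best = -HUGE_VAL;
    int best_j = -1, ties = 0;
    for (int k = 0; k < 4; ++k) {
      int j = g.nb[i * 4 + k];
      if (u[j] > best + TIE_TOL) {
        best = u[j];
        best_j = j;
        ties = 1;
      } else if (std::fabs(u[j] - best) <= TIE_TOL) {
        ++ties;
      }
    }
    // adopt only a strictly unique best neighbour that strictly beats self
    if (ties == 1 && best > u[i] + TIE_TOL) {
      s_new[i] = s[best_j];
      a_new[i] = a[best_j];
    } else {
      s_new[i] = s[i];
      a_new[i] = a[i];
    }
  }
}

// utility of agent x from fresh interactions with all four neighbours;
// abstention draws: x's first, then the neighbour's, in N,S,W,E order
static double fresh_utility(const Geometry &g, const int *s, const int *a,
                            const double *levels, double T, double L, double R,
                            double P, double S, int x) {
  double u = 0.0;
  for (int k = 0; k < 4; ++k) {
    int y = g.nb[x * 4 + k];
    bool abst_x = unif_rand() < levels[a[x]];
    bool abst_y = unif_rand() < levels[a[y]];
    if (abst_x || abst_y) u += L;
    else u += pd_payoff(s[x], s[y], T, R, P, S);
  }
  return u;
}

static inline int pick(int n) {
  int i = (int)(n * unif_rand());
  return (i >= n) ? n - 1 : i;
}

// numerically stable Fermi probability W = 1 / (1 + exp((ux - uy) / (kappa K)))
static inline double fermi_w(double ux, double uy, double kappa, double K) {
  double z = (ux - uy) / (kappa * K);
  if (z > 0) {
    double e = std::exp(-z);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(z));
}

// one asynchronous elementary move; site < 0 means draw the focal agent
// uniformly. RNG order: [site draw], u_x draws, neighbour pick, u_y draws,
// Fermi coin (only when u_y > u_x). Returns whether x copied y.
static bool async_move(const Geometry &g, int *s, int *a,
                       const double *levels, double T, double L, double R,
                       double P, double S, double K, int site) {
  int x = (site < 0) ? pick(g.N) : site;
  double ux = fresh_utility(g, s, a, levels, T, L, R, P, S, x);
  int y = g.nb[x * 4 + pick(4)];
  double uy = fresh_utility(g, s, a, levels, T, L, R, P, S, y);
  if (uy > ux && unif_rand() < fermi_w(ux, uy, (double)4, K)) {
    s[x] = s[y];
    a[x] = a[y];
    return true;
  }
  return false;
}

static bool homogeneous(int N, const int *s, const int *a) {
  for (int i = 1; i < N; ++i) {
    if (s[i] != s[0] || a[i] != a[0]) return false;
  }
  return true;
}

static bool all_at_level(int N, const int *a, int lev) {
  for (int i = 0; i < N; ++i) {
    if (a[i] != lev) return false;
  }
  return true;
}

// append one metrics row: step, mean_eps, mean_alpha, frac_coop, frac_defect,
// then one occupancy fraction per alpha level
static void record_row(std::vector<double> &rows, int step, int N,
                       const int *s, const int *a, const double *levels,
                       int nlev) {
  double sum_eps = 0, sum_alpha = 0;
  int ncoop = 0;
  std::vector<double> hist(nlev, 0.0);
  for (int i = 0; i < N; ++i) {
    double alpha = levels[a[i]];
    sum_alpha += alpha;
    if (s[i] == 0) {
      ++ncoop;
      sum_eps += 1.0 - alpha;
    }
    hist[a[i]] += 1.0;
  }
  rows.push_back((double)step);
  rows.push_back(sum_eps / N);
  rows.push_back(sum_alpha / N);
  rows.push_back((double)ncoop / N);
  rows.push_back((double)(N - ncoop) / N);
  for (int l = 0; l < nlev; ++l) rows.push_back(hist[l] / N);
}

// [[Rcpp::export]]
NumericMatrix engine_accrue_sync(IntegerMatrix s, IntegerMatrix a_idx,
                                 NumericVector levels, double T, double L,
                                 double R, double P, double S) {
  Geometry g(s.nrow());
  NumericMatrix u(s.nrow(), s.ncol());
  accrue_sync(g, s.begin(), a_idx.begin(), levels.begin(), T, L, R, P, S,
              u.begin());
  return u;
}

// [[Rcpp::export]]
List engine_imitate_sync(IntegerMatrix s, IntegerMatrix a_idx,
                         NumericMatrix u) {
  Geometry g(s.nrow());
  IntegerMatrix s_new(s.nrow(), s.ncol());
  IntegerMatrix a_new(s.nrow(), s.ncol());
  imitate_sync(g, s.begin(), a_idx.begin(), u.begin(), s_new.begin(),
               a_new.begin());
  return List::create(_["s"] = s_new, _["alpha_idx"] = a_new);
}

// [[Rcpp::export]]
List engine_async_move(IntegerMatrix s, IntegerMatrix a_idx,
                       NumericVector levels, double T, double L, double R,
                       double P, double S, double K, int site) {
  Geometry g(s.nrow());
  IntegerMatrix s2 = clone(s);
  IntegerMatrix a2 = clone(a_idx);
  bool copied = async_move(g, s2.begin(), a2.begin(), levels.begin(), T, L, R,
                           P, S, K, site);
  return List::create(_["s"] = s2, _["alpha_idx"] = a2, _["copied"] = copied);
}

// [[Rcpp::export]]
List engine_async_step(IntegerMatrix s, IntegerMatrix a_idx,
                       NumericVector levels, double T, double L, double R,
                       double P, double S, double K) {
  Geometry g(s.nrow());
  IntegerMatrix s2 = clone(s);
  IntegerMatrix a2 = clone(a_idx);
  for (int m = 0; m < g.N; ++m) {
    async_move(g, s2.begin(), a2.begin(), levels.begin(), T, L, R, P, S, K,
               -1);
  }
  return List::create(_["s"] = s2, _["alpha_idx"] = a2);
}

// [[Rcpp::export]]
double engine_fermi(double ux, double uy, double kappa, double K) {
  return fermi_w(ux, uy, kappa, K);
}

// [[Rcpp::export]]
List engine_run(IntegerMatrix s, IntegerMatrix a_idx, NumericVector levels,
                double T, double L, double R, double P, double S, double K,
                bool synchronous, int steps, int record_every,
                bool stop_when_absorbing) {
  Geometry g(s.nrow());
  int nlev = levels.size();
  IntegerMatrix s2 = clone(s);
  IntegerMatrix a2 = clone(a_idx);
  std::vector<double> u(g.N), rows;
  std::vector<int> s_buf(g.N), a_buf(g.N);

  record_row(rows, 0, g.N, s2.begin(), a2.begin(), levels.begin(), nlev);
  int step = 0;
  for (step = 1; step <= steps; ++step) {
    if (synchronous) {
      accrue_sync(g, s2.begin(), a2.begin(), levels.begin(), T, L, R, P, S,
                  u.data());
      imitate_sync(g, s2.begin(), a2.begin(), u.data(), s_buf.data(),
                   a_buf.data());
      std::copy(s_buf.begin(), s_buf.end(), s2.begin());
      std::copy(a_buf.begin(), a_buf.end(), a2.begin());
    } else {
      for (int m = 0; m < g.N; ++m) {
        async_move(g, s2.begin(), a2.begin(), levels.begin(), T, L, R, P, S,
                   K, -1);
      }
    }
    if (step % record_every == 0 || step == steps) {
      record_row(rows, step, g.N, s2.begin(), a2.begin(), levels.begin(),
                 nlev);
    }
    if (stop_when_absorbing) {
      bool absorbing = homogeneous(g.N, s2.begin(), a2.begin()) ||
                       (!synchronous && all_at_level(g.N, a2.begin(),
                                                     nlev - 1));
      if (absorbing) {
        if (step % record_every != 0 && step != steps) {
          record_row(rows, step, g.N, s2.begin(), a2.begin(), levels.begin(),
                     nlev);
        }
        break;
      }
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }
  int ncol = 5 + nlev;
  int nrow = (int)(rows.size() / ncol);
  NumericMatrix metrics(nrow, ncol);
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) metrics(r, c) = rows[r * ncol + c];
  }
  return List::create(_["metrics"] = metrics, _["s"] = s2,
                      _["alpha_idx"] = a2,
                      _["steps_run"] = std::min(step, steps));
}
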