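// Core numerical kernels: dense two-phase simplex, hit-and-run and
// artificially-centered hit-and-run chain loops.
//
// The simplex is deliberately self-contained and conservative: row
// equilibration by powers of two (exact in binary floating point), Dantzig
// pricing with a Bland's-rule fallback against cycling, artificial variables
// never re-enter the basis.

#include <RcppArmadillo.h>
#include <cmath>

using namespace Rcpp;

static const double TOL_PIV = 1e-9;   // smallest usable pivot element
static const double TOL_RC  = 1e-9;   // reduced-cost optimality tolerance

static void pivot_tab(arma::mat& T, arma::ivec& basis, int r, int j) {
  T.row(r) /= T(r, j);
  for (arma::uword i = 0; i < T.n_rows; ++i) {
    if ((int)i == r) continue;
    double f = T(i, j);
    if (f != 0.0) T.row(i) -= f * T.row(r);
  }
  basis[r] = j;
}

// entering column: Dantzig unless bland, restricted to columns [0, ncand)
static int choose_entering(const arma::mat& T, int ncand, bool bland) {
  int m = T.n_rows - 1;
  int best = -1;
  double bestv = -TOL_RC;
  for (int j = 0; j < ncand; ++j) {
    double z = T(m, j);
    if (z < -TOL_RC) {
      if (bland) return j;
      if (z < bestv) { bestv = z; best = j; }
    }
  }
  return best;
}

// leaving row by ratio test; Bland tie-break on basis column index
static int choose_leaving(const arma::mat& T, const arma::ivec& basis, int j) {
  int m = T.n_rows - 1, ncol = T.n_cols - 1;
  int best = -1;
  double bestratio = 0.0;
  for (int i = 0; i < m; ++i) {
    double a = T(i, j);
    if (a > TOL_PIV) {
      double ratio = T(i, ncol) / a;
      if (best < 0 || ratio < bestratio - 1e-12 ||
          (ratio <= bestratio + 1e-12 && basis[i] < basis[best])) {
        best = i; bestratio = ratio;
      }
    }
  }
  return best;
}

// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
// [[Rcpp::export]]
List simplex_core(const arma::mat& A, const arma::vec& b, const arma::vec& cobj,
                  const arma::ivec& is_eq, int max_iter) {
  int m = A.n_rows, n = A.n_cols;
  arma::mat As = A;
  arma::vec bs = b;

  // equilibrate rows by powers of two (exact scaling)
  for (int i = 0; i < m; ++i) {
    double mx = std::max(arma::abs(As.row(i)).max(), std::fabs(bs[i]));
    if (mx > 0) {
      int e; std::frexp(mx, &e);
      double s = std::ldexp(1.0, e - 1);
      As.row(i) /= s; bs[i] /= s;
    }
  }

  // force b >= 0; remember flipped rows (their slack gets coefficient -1)
  arma::ivec sgn(m, arma::fill::ones);
  for (int i = 0; i < m; ++i)
    if (bs[i] < 0) { As.row(i) *= -1.0; bs[i] *= -1.0; sgn[i] = -1; }

  // column layout: structural | slacks (ineq rows) | artificials
  std::vector<int> slack_col(m, -1), art_col(m, -1);
  int nc = n;
  for (int i = 0; i < m; ++i) if (!is_eq[i]) slack_col[i] = nc++;
  int first_art = nc;
  for (int i = 0; i < m; ++i)
    if (is_eq[i] || sgn[i] < 0) art_col[i] = nc++;
  int n_art = nc - first_art;

  arma::mat T(m + 1, nc + 1, arma::fill::zeros);
  T.submat(0, 0, m - 1, n - 1) = As;
  for (int i = 0; i < m; ++i) {
    if (slack_col[i] >= 0) T(i, slack_col[i]) = (double)sgn[i];
    if (art_col[i] >= 0)   T(i, art_col[i]) = 1.0;
    T(i, nc) = bs[i];
  }

  arma::ivec basis(m);
  for (int i = 0; i < m; ++i)
    basis[i] = (art_col[i] >= 0) ? art_col[i] : slack_col[i];

  int iter = 0;
  int bland_after = 50 * (m + nc) + 200;
  int ncand = n + (first_art - n);   // structural + slack columns only

  // ---- phase 1 ----
  if (n_art > 0) {
    for (int i = 0; i < m; ++i)
      if (art_col[i] >= 0) {
        T.row(m) -= T.row(i);
        T(m, art_col[i]) += 1.0;   // keep artificial reduced costs at 0
      }
    while (true) {
      if (iter++ > max_iter) return List::create(_["status"] = 3);
      int j = choose_entering(T, ncand, iter > bland_after);
      if (j < 0) break;
      int r = choose_leaving(T, basis, j);
      if (r < 0) break;  // phase-1 unbounded cannot happen; treat as optimal
      pivot_tab(T, basis, r, j);
    }
    double infeas = -T(m, nc);
    if (infeas > 1e-7 * (1.0 + arma::abs(bs).max()))
      return List::create(_["status"] = 1, _["infeas"] = infeas);
    // drive surviving artificials out of the basis where possible
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= first_art) {
        int jj = -1;
        for (int j = 0; j < ncand; ++j)
          if (std::fabs(T(i, j)) > 1e-7) { jj = j; break; }
        if (jj >= 0) pivot_tab(T, basis, i, jj);
        // else: redundant row, artificial stays basic at value ~0
      }
    }
  }

  // ---- phase 2 ----
  arma::rowvec z(nc + 1, arma::fill::zeros);
  z.subvec(0, n - 1) = cobj.t();
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n && cobj[basis[i]] != 0.0)
      z -= cobj[basis[i]] * T.row(i);
  }
  T.row(m) = z;

  int status = 0;
  while (true) {
    if (iter++ > max_iter) { status = 3; break; }
    int j = choose_entering(T, ncand, iter > bland_after);
    if (j < 0) break;
    int r = choose_leaving(T, basis, j);
    if (r < 0) { status = 2; break; }
    pivot_tab(T, basis, r, j);
  }

  arma::vec x(n, arma::fill::zeros);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T(i, nc);
  double value = arma::dot(cobj, x);
  double resid = arma::abs(As * x - bs).max();
  return List::create(_["status"] = status, _["x"] = x,
                      _["value"] = value, _["residual"] = resid,
                      _["iterations"] = iter);
}

// One hit-and-run chord: given slack s = h - G x and t = G theta, the feasible
// segment is lam in [lmin, lmax].
static bool chord_from(const arma::vec& s, const arma::vec& t,
                       double& lmin, double& lmax) {
  lmin = -std::numeric_limits<double>::infinity();
  lmax =  std::numeric_limits<double>::infinity();
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    double ti = t[i];
    if (ti > 1e-300) {
      double r = s[i] / ti;
      if (r < lmax) lmax = r;
    } else if (ti < -1e-300) {
      double r = s[i] / ti;
      if (r > lmin) lmin = r;
    }
  }
  return std::isfinite(lmin) && std::isfinite(lmax);
}

// Hit-and-run chain. Directions: theta = normalize(A u), u uniform on the unit
// sphere (Marsaglia: D iid standard normals, normalized); A = identity when
// use_bias is false. Uses R's RNG so set.seed() governs the whole stream.
// status: 0 ok, 1 frozen dynamics (resample cap hit)
// [[Rcpp::export]]
List hr_chain_core(const arma::mat& G, const arma::vec& h, const arma::vec& x0,
                   const arma::mat& Abias, bool use_bias, int n_points,
                   int thin, double chord_floor, int resample_cap) {
  int D = G.n_cols;
  arma::mat out(n_points, D);
  arma::vec x = x0;
  arma::vec s = h - G * x;
  long long resamples = 0;
  int stored = 0, step = 0;

  while (stored < n_points) {
    // one accepted HR step (with direction resampling on degenerate chords)
    int tries = 0;
    double lmin, lmax;
    arma::vec theta(D), t;
    while (true) {
      for (int k = 0; k < D; ++k) theta[k] = R::norm_rand();
      if (use_bias) theta = Abias * theta;
      double nrm = arma::norm(theta);
      if (nrm <= 0) { ++tries; continue; }
      theta /= nrm;
      t = G * theta;
      bool ok = chord_from(s, t, lmin, lmax);
      if (ok && (lmax - lmin) > chord_floor) break;
      ++resamples;
      if (++tries > resample_cap)
        return List::create(_["status"] = 1, _["stored"] = stored,
                            _["resamples"] = (double)resamples);
    }
    // draw strictly inside the chord (endpoints nudged by the floor)
    double lo = lmin + chord_floor, hi = lmax - chord_floor;
    if (hi <= lo) { lo = lmin; hi = lmax; }
    double lam = lo + (hi - lo) * R::unif_rand();
    x += lam * theta;
    s -= lam * t;
    if (++step % 256 == 0) s = h - G * x;  // refresh slacks against drift
    if (step % thin == 0) out.row(stored++) = x.t();
  }
  return List::create(_["status"] = 0, _["points"] = out,
                      _["resamples"] = (double)resamples);
}

// Artificially-centered hit-and-run (non-Markovian baseline). Directions are
// normalize(P_k - mean of pool) for a uniformly chosen previous point P_k.
// The pool holds the warm-up states plus every recorded state.
// [[Rcpp::export]]
List achr_chain_core(const arma::mat& G, const arma::vec& h, const arma::vec& x0,
                     int n_points, int thin, int warmup,
                     double chord_floor, int resample_cap) {
  int D = G.n_cols;
  arma::mat pool(warmup + n_points, D);
  arma::mat out(n_points, D);
  arma::vec x = x0;
  arma::vec s = h - G * x;
  long long resamples = 0;

  // warm-up: plain HR steps, every state pooled
  int pooled = 0;
  for (int w = 0; w < warmup; ++w) {
    int tries = 0; double lmin, lmax; arma::vec theta(D), t;
    while (true) {
      for (int k = 0; k < D; ++k) theta[k] = R::norm_rand();
      double nrm = arma::norm(theta);
      if (nrm <= 0) { ++tries; continue; }
      theta /= nrm;
      t = G * theta;
      bool ok = chord_from(s, t, lmin, lmax);
      if (ok && (lmax - lmin) > chord_floor) break;
      ++resamples;
      if (++tries > resample_cap)
        return List::create(_["status"] = 1, _["stored"] = 0,
                            _["resamples"] = (double)resamples);
    }
    double lo = lmin + chord_floor, hi = lmax - chord_floor;
    if (hi <= lo) { lo = lmin; hi = lmax; }
    double lam = lo + (hi - lo) * R::unif_rand();
    x += lam * theta; s -= lam * t;
    pool.row(pooled++) = x.t();
  }
  arma::vec center = arma::mean(pool.rows(0, pooled - 1), 0).t();

  int stored = 0, step = 0;
  while (stored < n_points) {
    int tries = 0; double lmin, lmax; arma::vec theta(D), t;
    while (true) {
      int idx = (int)std::floor(R::unif_rand() * pooled);
      if (idx >= pooled) idx = pooled - 1;
      theta = pool.row(idx).t() - center;
      double nrm = arma::norm(theta);
      if (nrm <= 1e-300) { ++tries; if (tries > resample_cap)
          return List::create(_["status"] = 1, _["stored"] = stored,
                              _["resamples"] = (double)resamples);
        continue; }
      theta /= nrm;
      t = G * theta;
      bool ok = chord_from(s, t, lmin, lmax);
      if (ok && (lmax - lmin) > chord_floor) break;
      ++resamples;
      if (++tries > resample_cap)
        return List::create(_["status"] = 1, _["stored"] = stored,
                            _["resamples"] = (double)resamples);
    }
    double lo = lmin + chord_floor, hi = lmax - chord_floor;
    if (hi <= lo) { lo = lmin; hi = lmax; }
    double lam = lo + (hi - lo) * R::unif_rand();
    x += lam * theta;
    s -= lam * t;
    if (++step % 256 == 0) s = h - G * x;
    if (step % thin == 0) {
      out.row(stored) = x.t();
      // update running center with the new pooled point
      center = (center * pooled + x) / (pooled + 1);
      pool.row(pooled++) = x.t();
      ++stored;
    }
  }
  return List::create(_["status"] = 0, _["points"] = out,
                      _["resamples"] = (double)resamples);
}
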