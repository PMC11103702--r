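#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Uniform point on the unit sphere (Marsaglia 1972), driven by R's RNG so
// that draws are reproducible under set.seed().
static inline void unit_vector(double &x, double &y, double &z) {
  double u1, u2, s;
  do {
    u1 = 2.0 * unif_rand() - 1.0;
    u2 = 2.0 * unif_rand() - 1.0;
    s = u1 * u1 + u2 * u2;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  x = u1 * f;
  y = u2 * f;
  z = 1.0 - 2.0 * s;
}

struct Chain {
  const double *r;       // steric radii
  double tol;            // relative overlap tolerance
  int base;              // one-shot rejection below this size
  double max_attempts;   // per recursion level
};

// Auxiliary walk for beads [lo, hi) written into X (row-major n x 3),
// starting at the origin of the local frame.
static void aux_walk(std::vector<double> &X, const Chain &ch, int lo, int hi) {
  X[3 * lo] = X[3 * lo + 1] = X[3 * lo + 2] = 0.0;
  for (int k = lo + 1; k < hi; ++k) {
    double ux, uy, uz;
    unit_vector(ux, uy, uz);
    double d = ch.r[k - 1] + ch.r[k];
    X[3 * k] = X[3 * (k - 1)] + d * ux;
    X[3 * k + 1] = X[3 * (k - 1) + 1] + d * uy;
    X[3 * k + 2] = X[3 * (k - 1) + 2] + d * uz;
  }
}

static inline double dist2(const std::vector<double> &X, int i, int j) {
  double dx = X[3 * i] - X[3 * j];
  double dy = X[3 * i + 1] - X[3 * j + 1];
  double dz = X[3 * i + 2] - X[3 * j + 2];
  return dx * dx + dy * dy + dz * dz;
}

// Any overlap among non-adjacent pairs within [lo, hi)?
static bool self_overlap(const std::vector<double> &X, const Chain &ch,
                         int lo, int hi) {
  for (int i = lo; i < hi - 2; ++i)
    for (int j = i + 2; j < hi; ++j) {
      double thr = (ch.r[i] + ch.r[j]) * (1.0 - ch.tol);
      if (dist2(X, i, j) < thr * thr) return true;
    }
  return false;
}

// Any overlap between halves [lo, mid) and [mid, hi)? The junction pair
// (mid-1, mid) touches by construction and is exempt. Pairs are scanned
// outward from the junction, where overlaps are most likely.
static bool cross_overlap(const std::vector<double> &X, const Chain &ch,
                          int lo, int mid, int hi) {
  for (int j = mid; j < hi; ++j)
    for (int i = mid - 1; i >= lo; --i) {
      if (i == mid - 1 && j == mid) continue;
      double thr = (ch.r[i] + ch.r[j]) * (1.0 - ch.tol);
      if (dist2(X, i, j) < thr * thr) return true;
    }
  return false;
}

// Exact SARWS sample for beads [lo, hi) by recursive dimerization: draw
// valid sub-walks for each half, join with a fresh uniform bond direction,
// accept iff the halves do not overlap; on rejection redraw BOTH halves
// (required for the product measure to condition correctly).
static void sample_range(std::vector<double> &X, const Chain &ch,
                         int lo, int hi) {
  int n = hi - lo;
  if (n <= ch.base) {
    double att = 0.0;
    do {
      if (++att > ch.max_attempts)
        stop("SARWS sampling failed: attempt budget (%g) exceeded for a %d-bead segment",
             ch.max_attempts, n);
      aux_walk(X, ch, lo, hi);
    } while (self_overlap(X, ch, lo, hi));
    return;
  }
  int mid = lo + n / 2;
  double d = ch.r[mid - 1] + ch.r[mid];
  double att = 0.0;
  for (;;) {
    if (++att > ch.max_attempts)
      stop("SARWS sampling failed: attempt budget (%g) exceeded joining %d+%d beads",
           ch.max_attempts, mid - lo, hi - mid);
    sample_range(X, ch, lo, mid);
    sample_range(X, ch, mid, hi);
    double ux, uy, uz;
    unit_vector(ux, uy, uz);
    double sx = X[3 * (mid - 1)] + d * ux - X[3 * mid];
    double sy = X[3 * (mid - 1) + 1] + d * uy - X[3 * mid + 1];
    double sz = X[3 * (mid - 1) + 2] + d * uz - X[3 * mid + 2];
    for (int k = mid; k < hi; ++k) {
      X[3 * k] += sx;
      X[3 * k + 1] += sy;
      X[3 * k + 2] += sz;
    }
    if (!cross_overlap(X, ch, lo, mid, hi)) return;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_sarws(NumericVector r_steric, int base, double tol,
                               double max_attempts) {
  int n = r_steric.size();
  std::vector<double> X(3 * n);
  Chain ch{REAL(r_steric), tol, base < 1 ? 1 : base, max_attempts};
  sample_range(X, ch, 0, n);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = X[3 * i + c];
  return out;
}

// [[Rcpp::export]]
List cpp_sample_ensemble(NumericVector r_steric, int nconf, int base,
                         double tol, double max_attempts) {
  List out(nconf);
  for (int k = 0; k < nconf; ++k)
    out[k] = cpp_sample_sarws(r_steric, base, tol, max_attempts);
  return out;
}

// Trace-contracted, 2*pi*eta-scaled generalized Rotne-Prager-Yamakawa pair
// mobility for spheres of radii ai, aj at centre distance r. Equals 1/r
// beyond contact, 1/max(ai, aj) at full containment, and the polydisperse
// overlap closed form in between; continuous at both branch points.
static inline double grpy_pair_trace(double ai, double aj, double r) {
  double s = ai + aj;
  double d = std::fabs(ai - aj);
  if (r >= s) return 1.0 / r;
  if (r <= d) return 1.0 / (ai > aj ? ai : aj);
  double r2 = r * r, r3 = r2 * r;
  double t1 = d * d + 3.0 * r2;
  double t2 = d * d - r2;
  return (16.0 * r3 * s - t1 * t1 + t2 * t2) / (32.0 * r3 * ai * aj);
}

// [[Rcpp::export]]
double cpp_pair_trace(double ai, double aj, double r) {
  return grpy_pair_trace(ai, aj, r);
}

// Ensemble means of the bare inverse distance 1/r_ij (Kirkwood) and of the
// GRPY trace mobility (matrix A), accumulated in one pass over conformers.
// Diagonals are left at zero; the caller sets them.
// [[Rcpp::export]]
List cpp_mean_pair_matrices(List conformations, NumericVector hydro_radius) {
  int n = hydro_radius.size();
  int m = conformations.size();
  NumericMatrix inv_r(n, n), grpy(n, n);
  for (int k = 0; k < m; ++k) {
    NumericMatrix X = conformations[k];
    if (X.nrow() != n)
      stop("conformation %d has %d beads, expected %d", k + 1, X.nrow(), n);
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = X(i, 0) - X(j, 0);
        double dy = X(i, 1) - X(j, 1);
        double dz = X(i, 2) - X(j, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        inv_r(i, j) += 1.0 / r;
        grpy(i, j) += grpy_pair_trace(hydro_radius[i], hydro_radius[j], r);
      }
  }
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      inv_r(i, j) /= m;
      grpy(i, j) /= m;
      inv_r(j, i) = inv_r(i, j);
      grpy(j, i) = grpy(i, j);
    }
  return List::create(Named("inv_r") = inv_r, Named("grpy") = grpy);
}
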