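#include <Rcpp.h>
#include <set>
#include <utility>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discretized Gauss double-integral machinery on a Calpha trace.
//
// For a trace r_1..r_n the bond midpoints are R_i = (r_i + r_{i+1})/2 and
// the bond vectors dR_i = r_{i+1} - r_i, i = 1..n-1.  The pairwise kernel
//   K(i,j) = (1/4pi) (R_i - R_j) . (dR_i x dR_j) / |R_i - R_j|^3
// is symmetric in (i,j) (swapping negates both the displacement and the
// cross product) and zero on the diagonal.  The score of a subchain pair
// [a1,a2] x [b1,b2] (residue ranges; bonds a1..a2-1, b1..b2-1) is the
// rectangle sum of K, served in O(1) from a 2D prefix table.

// [[Rcpp::export]]
NumericMatrix cpp_gauss_kernel(const NumericMatrix& xyz) {
  const int n = xyz.nrow();
  const int nb = n - 1;
  NumericMatrix K(nb, nb);
  if (nb < 1) return K;
  std::vector<double> mx(nb), my(nb), mz(nb), dx(nb), dy(nb), dz(nb);
  for (int i = 0; i < nb; ++i) {
    mx[i] = 0.5 * (xyz(i, 0) + xyz(i + 1, 0));
    my[i] = 0.5 * (xyz(i, 1) + xyz(i + 1, 1));
    mz[i] = 0.5 * (xyz(i, 2) + xyz(i + 1, 2));
    dx[i] = xyz(i + 1, 0) - xyz(i, 0);
    dy[i] = xyz(i + 1, 1) - xyz(i, 1);
    dz[i] = xyz(i + 1, 2) - xyz(i, 2);
  }
  const double pre = 1.0 / (4.0 * M_PI);
  for (int i = 1; i < nb; ++i) {
    for (int j = 0; j < i; ++j) {
      const double rx = mx[i] - mx[j];
      const double ry = my[i] - my[j];
      const double rz = mz[i] - mz[j];
      const double cx = dy[i] * dz[j] - dz[i] * dy[j];
      const double cy = dz[i] * dx[j] - dx[i] * dz[j];
      const double cz = dx[i] * dy[j] - dy[i] * dx[j];
      const double r2 = rx * rx + ry * ry + rz * rz;
      const double v = pre * (rx * cx + ry * cy + rz * cz) / (r2 * std::sqrt(r2));
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// Padded 2D prefix table P: (nb+1)x(nb+1), P(a,b) = sum K[1..a, 1..b].
// [[Rcpp::export]]
NumericMatrix cpp_prefix(const NumericMatrix& K) {
  const int nb = K.nrow();
  NumericMatrix P(nb + 1, nb + 1);
  for (int i = 1; i <= nb; ++i)
    for (int j = 1; j <= nb; ++j)
      P(i, j) = K(i - 1, j - 1) + P(i - 1, j) + P(i, j - 1) - P(i - 1, j - 1);
  return P;
}

static inline double rect(const NumericMatrix& P,
                          int a1, int a2, int b1, int b2) {
  // bond index ranges, 1-based inclusive
  return P(a2, b2) - P(a1 - 1, b2) - P(a2, b1 - 1) + P(a1 - 1, b1 - 1);
}

// Rectangle score for residue ranges [a1,a2] x [b1,b2] (bonds a..a2-1).
// [[Rcpp::export]]
double cpp_range_score(const NumericMatrix& P,
                       int a1, int a2, int b1, int b2) {
  return rect(P, a1, a2 - 1, b1, b2 - 1);
}

// Best thread for loop [i1,i2]: scan every contiguous residue range
// [j1,j2] with j2-j1 >= m0, wholly on one side of the loop, separated by
// s >= smin.  Deterministic tie-break: N side before C side, then
// lexicographic (j1,j2); strictly larger |g| replaces the incumbent.
// [[Rcpp::export]]
List cpp_best_thread(const NumericMatrix& P, int i1, int i2, int n,
                     int m0, int smin) {
  double best = 0.0;
  bool found = false;
  int bj1 = NA_INTEGER, bj2 = NA_INTEGER;
  char bside = '?';
  // N side: j2 <= i1 - smin
  const int nmax = i1 - smin;
  for (int j1 = 1; j1 + m0 <= nmax; ++j1) {
    for (int j2 = j1 + m0; j2 <= nmax; ++j2) {
      const double g = rect(P, i1, i2 - 1, j1, j2 - 1);
      if (!found || std::fabs(g) > std::fabs(best)) {
        found = true; best = g; bj1 = j1; bj2 = j2; bside = 'N';
      }
    }
  }
  // C side: j1 >= i2 + smin
  for (int j1 = i2 + smin; j1 + m0 <= n; ++j1) {
    for (int j2 = j1 + m0; j2 <= n; ++j2) {
      const double g = rect(P, i1, i2 - 1, j1, j2 - 1);
      if (!found || std::fabs(g) > std::fabs(best)) {
        found = true; best = g; bj1 = j1; bj2 = j2; bside = 'C';
      }
    }
  }
  return List::create(_["found"] = found, _["g"] = found ? best : NA_REAL,
                      _["j1"] = bj1, _["j2"] = bj2,
                      _["side"] = std::string(1, bside));
}

// Extreme (largest-modulus, signed) score over all unordered pairs of
// disjoint loops.  loops: 2-column matrix of residue ranges (i1 < i2).
// [[Rcpp::export]]
List cpp_best_loop_pair(const NumericMatrix& P, const IntegerMatrix& loops,
                        int smin) {
  const int m = loops.nrow();
  double best = 0.0;
  bool found = false;
  int ba = NA_INTEGER, bb = NA_INTEGER;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      int a1 = loops(a, 0), a2 = loops(a, 1);
      int b1 = loops(b, 0), b2 = loops(b, 1);
      // disjoint with gap >= smin, either order along the chain
      if (!((a2 + smin <= b1) || (b2 + smin <= a1))) continue;
      const double g = rect(P, a1, a2 - 1, b1, b2 - 1);
      if (!found || std::fabs(g) > std::fabs(best)) {
        found = true; best = g; ba = a + 1; bb = b + 1;
      }
    }
  }
  return List::create(_["found"] = found, _["g"] = found ? best : NA_REAL,
                      _["a"] = ba, _["b"] = bb);
}

// All residue pairs with |i-j| >= minsep whose points are within cutoff.
// Used for the Calpha-proxy contact maps of synthetic traces.
// [[Rcpp::export]]
IntegerMatrix cpp_point_contacts(const NumericMatrix& xyz, double cutoff,
                                 int minsep) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minsep; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        ii.push_back(i + 1); jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k]; out(k, 1) = jj[k];
  }
  return out;
}

// Minimum inter-residue atom distances below cutoff for atom lists given
// as a flat atom matrix plus a residue index per atom.
// [[Rcpp::export]]
IntegerMatrix cpp_atom_contacts(const NumericMatrix& xyz,
                                const IntegerVector& resid, int nres,
                                double cutoff, int minsep) {
  const int m = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::set<std::pair<int, int> > hits;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      const int ri = resid[i], rj = resid[j];
      const int lo = ri < rj ? ri : rj, hi = ri < rj ? rj : ri;
      if (hi - lo < minsep) continue;
      if (hits.count(std::make_pair(lo, hi))) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2)
        hits.insert(std::make_pair(lo, hi));
    }
  }
  IntegerMatrix out(hits.size(), 2);
  int k = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = hits.begin();
       it != hits.end(); ++it, ++k) {
    out(k, 0) = it->first; out(k, 1) = it->second;
  }
  return out;
}
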