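#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order Gaussian overlap volume between two atom sets.
// Each atom i is an isotropic Gaussian p * exp(-alpha_i * |r - R_i|^2)
// whose integral equals the atom's hard-sphere volume. The pairwise
// product-Gaussian integral has the closed form
//   p^2 * (pi / (ai + aj))^{3/2} * exp(-ai*aj/(ai+aj) * d^2).
// [[Rcpp::export]]
double cpp_overlap_volume(NumericMatrix xyzA, NumericVector alphaA,
                          NumericMatrix xyzB, NumericVector alphaB,
                          double p) {
  const double p2 = p * p;
  const double pi = M_PI;
  double total = 0.0;
  for (int i = 0; i < xyzA.nrow(); ++i) {
    const double ax = xyzA(i, 0), ay = xyzA(i, 1), az = xyzA(i, 2);
    const double ai = alphaA[i];
    for (int j = 0; j < xyzB.nrow(); ++j) {
      const double dx = ax - xyzB(j, 0);
      const double dy = ay - xyzB(j, 1);
      const double dz = az - xyzB(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double aj = alphaB[j];
      const double s = ai + aj;
      const double expo = -(ai * aj / s) * d2;
      if (expo < -30.0) continue;  // overlap below 1e-13 of peak
      total += p2 * std::pow(pi / s, 1.5) * std::exp(expo);
    }
  }
  return total;
}

// Same-type feature overlap for pharmacophore (color) scoring: only pairs
// with matching integer type codes contribute.
// [[Rcpp::export]]
double cpp_feature_overlap(IntegerVector typeA, NumericMatrix xyzA,
                           IntegerVector typeB, NumericMatrix xyzB,
                           double alpha, double p) {
  const double p2 = p * p;
  const double pref = std::pow(M_PI / (2.0 * alpha), 1.5);
  double total = 0.0;
  for (int i = 0; i < xyzA.nrow(); ++i) {
    for (int j = 0; j < xyzB.nrow(); ++j) {
      if (typeA[i] != typeB[j]) continue;
      const double dx = xyzA(i, 0) - xyzB(j, 0);
      const double dy = xyzA(i, 1) - xyzB(j, 1);
      const double dz = xyzA(i, 2) - xyzB(j, 2);
      const double expo = -0.5 * alpha * (dx * dx + dy * dy + dz * dz);
      if (expo < -30.0) continue;
      total += p2 * pref * std::exp(expo);
    }
  }
  return total;
}

// Hard-sphere union volume on a regular grid (descriptor panel).
// [[Rcpp::export]]
double cpp_grid_volume(NumericMatrix xyz, NumericVector radii, double grid) {
  const int n = xyz.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (radii[i] > rmax) rmax = radii[i];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], xyz(i, k));
      hi[k] = std::max(hi[k], xyz(i, k));
    }
  }
  for (int k = 0; k < 3; ++k) { lo[k] -= rmax + grid; hi[k] += rmax + grid; }
  long count = 0;
  std::vector<double> r2(n);
  for (int i = 0; i < n; ++i) r2[i] = radii[i] * radii[i];
  for (double x = lo[0]; x <= hi[0]; x += grid)
    for (double y = lo[1]; y <= hi[1]; y += grid)
      for (double z = lo[2]; z <= hi[2]; z += grid) {
        for (int i = 0; i < n; ++i) {
          const double dx = x - xyz(i, 0), dy = y - xyz(i, 1),
                       dz = z - xyz(i, 2);
          if (dx * dx + dy * dy + dz * dz <= r2[i]) { ++count; break; }
        }
      }
  return count * grid * grid * grid;
}

// van der Waals surface area by quasi-uniform sphere sampling
// (Fibonacci lattice per atom; a point counts when outside every other
// sphere).
// [[Rcpp::export]]
double cpp_vdw_surface(NumericMatrix xyz, NumericVector radii, int npts) {
  const int n = xyz.nrow();
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  double area = 0.0;
  std::vector<double> r2(n);
  for (int i = 0; i < n; ++i) r2[i] = radii[i] * radii[i];
  for (int i = 0; i < n; ++i) {
    int exposed = 0;
    for (int k = 0; k < npts; ++k) {
      const double zc = 1.0 - 2.0 * (k + 0.5) / npts;
      const double rad = std::sqrt(std::max(0.0, 1.0 - zc * zc));
      const double th = golden * k;
      const double px = xyz(i, 0) + radii[i] * rad * std::cos(th);
      const double py = xyz(i, 1) + radii[i] * rad * std::sin(th);
      const double pz = xyz(i, 2) + radii[i] * zc;
      bool buried = false;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < r2[j] - 1e-9) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area += 4.0 * M_PI * r2[i] * exposed / npts;
  }
  return area;
}

// Minimum distance over atom pairs excluded from bonding (used by the
// conformer clash check); pairs is a 2-column 1-based index matrix.
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix xyz, IntegerMatrix pairs) {
  double best = R_PosInf;
  for (int k = 0; k < pairs.nrow(); ++k) {
    const int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < best) best = d;
  }
  return best;
}
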