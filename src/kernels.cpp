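#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice layer labels shared with the R side.
static const int OUTSIDE = 0, SURFACE = 1, NEAR_SURFACE = 2, CORE = 3;

// Mark lattice points lying inside any atom's van der Waals sphere
// (closed ball: distance <= radius). Grid point (i,j,k), 0-based, sits at
// origin + (i,j,k) * spacing. Column-major layout: i fastest.
// [[Rcpp::export]]
IntegerVector cpp_mark_inside(NumericMatrix xyz, NumericVector radius,
                              NumericVector origin, double spacing, int n) {
  IntegerVector inside(static_cast<R_xlen_t>(n) * n * n, 0);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double r = radius[a], r2 = r * r;
    int i0 = (int)std::ceil((ax - r - ox) / spacing);
    int i1 = (int)std::floor((ax + r - ox) / spacing);
    int j0 = (int)std::ceil((ay - r - oy) / spacing);
    int j1 = (int)std::floor((ay + r - oy) / spacing);
    int k0 = (int)std::ceil((az - r - oz) / spacing);
    int k1 = (int)std::floor((az + r - oz) / spacing);
    if (i0 < 0) i0 = 0; if (i1 > n - 1) i1 = n - 1;
    if (j0 < 0) j0 = 0; if (j1 > n - 1) j1 = n - 1;
    if (k0 < 0) k0 = 0; if (k1 > n - 1) k1 = n - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + k * spacing - az, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + j * spacing - ay, d2yz = dy * dy + dz2;
        if (d2yz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * spacing - ax;
          if (dx * dx + d2yz <= r2)
            inside[i + (R_xlen_t)n * (j + (R_xlen_t)n * k)] = 1;
        }
      }
    }
  }
  return inside;
}

static inline int lab_at(const IntegerVector &v, int n, int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= n || j >= n || k >= n) return OUTSIDE;
  return v[i + (R_xlen_t)n * (j + (R_xlen_t)n * k)];
}

// Three-layer onion classification of the inside mask under face
// (6-)connectivity; off-grid neighbours count as outside.
//   surface:      inside with an outside face-neighbour
//   near-surface: remaining inside with a surface face-neighbour
//   core:         all remaining inside points
// [[Rcpp::export]]
IntegerVector cpp_classify_layers(IntegerVector inside, int n) {
  R_xlen_t total = (R_xlen_t)n * n * n;
  IntegerVector lab(total, OUTSIDE);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        R_xlen_t id = i + (R_xlen_t)n * (j + (R_xlen_t)n * k);
        if (!inside[id]) continue;
        bool out_nb =
          !lab_at(inside, n, i - 1, j, k) || !lab_at(inside, n, i + 1, j, k) ||
          !lab_at(inside, n, i, j - 1, k) || !lab_at(inside, n, i, j + 1, k) ||
          !lab_at(inside, n, i, j, k - 1) || !lab_at(inside, n, i, j, k + 1);
        lab[id] = out_nb ? SURFACE : CORE; // CORE is provisional
      }
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        R_xlen_t id = i + (R_xlen_t)n * (j + (R_xlen_t)n * k);
        if (lab[id] != CORE) continue;
        bool surf_nb =
          lab_at(lab, n, i - 1, j, k) == SURFACE ||
          lab_at(lab, n, i + 1, j, k) == SURFACE ||
          lab_at(lab, n, i, j - 1, k) == SURFACE ||
          lab_at(lab, n, i, j + 1, k) == SURFACE ||
          lab_at(lab, n, i, j, k - 1) == SURFACE ||
          lab_at(lab, n, i, j, k + 1) == SURFACE;
        if (surf_nb) lab[id] = -NEAR_SURFACE; // mark without disturbing scan
      }
  for (R_xlen_t id = 0; id < total; ++id)
    if (lab[id] == -NEAR_SURFACE) lab[id] = NEAR_SURFACE;
  return lab;
}

// Exponential neighbour sums of the LSC scoring function. For every point
// with label target_label, sum exp(-(r - shift)^2) over near-surface and
// core points (i,j,k) within the +/- box_radius index box, r being the
// Euclidean index-space distance. include_self controls the r = 0 term when
// the point itself qualifies. Other points get 0.
// [[Rcpp::export]]
NumericVector cpp_layer_sums(IntegerVector lab, int n, int target_label,
                             int box_radius, double shift, bool include_self) {
  R_xlen_t total = (R_xlen_t)n * n * n;
  NumericVector out(total, 0.0);
  const int b = box_radius;
  // precompute kernel weights over the offset box
  const int side = 2 * b + 1;
  std::vector<double> w(side * side * side);
  for (int dk = -b; dk <= b; ++dk)
    for (int dj = -b; dj <= b; ++dj)
      for (int di = -b; di <= b; ++di) {
        double r = std::sqrt((double)(di * di + dj * dj + dk * dk));
        w[(di + b) + side * ((dj + b) + side * (dk + b))] =
          std::exp(-(r - shift) * (r - shift));
      }
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        R_xlen_t id = i + (R_xlen_t)n * (j + (R_xlen_t)n * k);
        if (lab[id] != target_label) continue;
        double s = 0.0;
        for (int dk = -b; dk <= b; ++dk)
          for (int dj = -b; dj <= b; ++dj)
            for (int di = -b; di <= b; ++di) {
              if (!include_self && di == 0 && dj == 0 && dk == 0) continue;
              int l = lab_at(lab, n, i + di, j + dj, k + dk);
              if (l == NEAR_SURFACE || l == CORE)
                s += w[(di + b) + side * ((dj + b) + side * (dk + b))];
            }
        out[id] = s;
      }
  return out;
}
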