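#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Monte-Carlo projection approximation: per-orientation projected area of a
// set of disks (atom radius + probe radius), orientations drawn uniformly
// via normalized quaternions from R's RNG so set.seed() governs everything.
// Hit testing uses a 2-D cell list over disk centers (cell size = largest
// disk radius), so each probe inspects at most a 3x3 neighbourhood.

static inline void quat_to_rot(double q0, double q1, double q2, double q3,
                               double R[3][3]) {
  double n = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
  q0 /= n; q1 /= n; q2 /= n; q3 /= n;
  R[0][0] = 1 - 2 * (q2 * q2 + q3 * q3);
  R[0][1] = 2 * (q1 * q2 - q0 * q3);
  R[0][2] = 2 * (q1 * q3 + q0 * q2);
  R[1][0] = 2 * (q1 * q2 + q0 * q3);
  R[1][1] = 1 - 2 * (q1 * q1 + q3 * q3);
  R[1][2] = 2 * (q2 * q3 - q0 * q1);
  R[2][0] = 2 * (q1 * q3 - q0 * q2);
  R[2][1] = 2 * (q2 * q3 + q0 * q1);
  R[2][2] = 1 - 2 * (q1 * q1 + q2 * q2);
}

// [[Rcpp::export]]
NumericVector pa_rotation_areas(NumericMatrix coords, NumericVector radii,
                                int n_rotations, int n_probes) {
  const int n = coords.nrow();
  if (n < 1) stop("no atoms");
  if (n_rotations < 1 || n_probes < 1) stop("non-positive sampling counts");
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  if (rmax <= 0) stop("radii must be positive");

  NumericVector areas(n_rotations);
  std::vector<double> px(n), py(n);
  GetRNGstate();
  for (int rot = 0; rot < n_rotations; ++rot) {
    double R[3][3];
    quat_to_rot(norm_rand(), norm_rand(), norm_rand(), norm_rand(), R);
    double xmin = std::numeric_limits<double>::max(), xmax = -xmin;
    double ymin = xmin, ymax = -xmin;
    for (int i = 0; i < n; ++i) {
      double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
      px[i] = R[0][0] * x + R[0][1] * y + R[0][2] * z;
      py[i] = R[1][0] * x + R[1][1] * y + R[1][2] * z;
      xmin = std::min(xmin, px[i] - radii[i]);
      xmax = std::max(xmax, px[i] + radii[i]);
      ymin = std::min(ymin, py[i] - radii[i]);
      ymax = std::max(ymax, py[i] + radii[i]);
    }
    const double cell = rmax;
    const int ncx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
    const int ncy = std::max(1, (int)std::ceil((ymax - ymin) / cell));
    std::vector<std::vector<int> > cells((size_t)ncx * ncy);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, (int)((px[i] - xmin) / cell));
      int cy = std::min(ncy - 1, (int)((py[i] - ymin) / cell));
      cells[(size_t)cx * ncy + cy].push_back(i);
    }
    const double bw = xmax - xmin, bh = ymax - ymin;
    long hits = 0;
    for (int p = 0; p < n_probes; ++p) {
      double qx = xmin + unif_rand() * bw;
      double qy = ymin + unif_rand() * bh;
      int cx = std::min(ncx - 1, (int)((qx - xmin) / cell));
      int cy = std::min(ncy - 1, (int)((qy - ymin) / cell));
      bool hit = false;
      for (int dx = -1; dx <= 1 && !hit; ++dx) {
        int ix = cx + dx;
        if (ix < 0 || ix >= ncx) continue;
        for (int dy = -1; dy <= 1 && !hit; ++dy) {
          int iy = cy + dy;
          if (iy < 0 || iy >= ncy) continue;
          const std::vector<int>& bucket = cells[(size_t)ix * ncy + iy];
          for (size_t k = 0; k < bucket.size(); ++k) {
            int i = bucket[k];
            double ddx = qx - px[i], ddy = qy - py[i];
            if (ddx * ddx + ddy * ddy <= radii[i] * radii[i]) { hit = true; break; }
          }
        }
      }
      if (hit) ++hits;
    }
    areas[rot] = bw * bh * (double)hits / (double)n_probes;
  }
  PutRNGstate();
  return areas;
}

// Minimum reference-to-query distance per query group (e.g. protein atoms vs
// the atoms of each lipid), using a 3-D cell list over reference atoms with
// cell size = cutoff.  Distances beyond the cutoff are reported as Inf; the
// comparison d^2 <= cutoff^2 makes the cutoff inclusive.

// [[Rcpp::export]]
NumericVector min_dist_per_group(NumericMatrix ref, NumericMatrix query,
                                 IntegerVector group, int n_groups,
                                 double cutoff) {
  const int nr = ref.nrow(), nq = query.nrow();
  if (cutoff <= 0) stop("cutoff must be positive");
  NumericVector out(n_groups, R_PosInf);
  if (nr == 0 || nq == 0) return out;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = ref(0, d); hi[d] = ref(0, d); }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i, d));
      hi[d] = std::max(hi[d], ref(i, d));
    }
  const double cell = cutoff;
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell) + 1);
  std::vector<std::vector<int> > cells((size_t)nc[0] * nc[1] * nc[2]);
  for (int i = 0; i < nr; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d)
      c[d] = std::min(nc[d] - 1, std::max(0, (int)((ref(i, d) - lo[d]) / cell)));
    cells[((size_t)c[0] * nc[1] + c[1]) * nc[2] + c[2]].push_back(i);
  }
  const double cut2 = cutoff * cutoff;
  for (int j = 0; j < nq; ++j) {
    int g = group[j];
    if (g < 0 || g >= n_groups) stop("group index out of range");
    double qx = query(j, 0), qy = query(j, 1), qz = query(j, 2);
    int c[3] = { (int)std::floor((qx - lo[0]) / cell),
                 (int)std::floor((qy - lo[1]) / cell),
                 (int)std::floor((qz - lo[2]) / cell) };
    double best = out[g];
    for (int dx = -1; dx <= 1; ++dx) {
      int ix = c[0] + dx; if (ix < 0 || ix >= nc[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = c[1] + dy; if (iy < 0 || iy >= nc[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int iz = c[2] + dz; if (iz < 0 || iz >= nc[2]) continue;
          const std::vector<int>& bucket =
            cells[((size_t)ix * nc[1] + iy) * nc[2] + iz];
          for (size_t k = 0; k < bucket.size(); ++k) {
            int i = bucket[k];
            double ddx = qx - ref(i, 0), ddy = qy - ref(i, 1),
                   ddz = qz - ref(i, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= cut2) best = std::min(best, std::sqrt(d2));
          }
        }
      }
    }
    out[g] = best;
  }
  return out;
}
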