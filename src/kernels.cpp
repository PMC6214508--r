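#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for +Inf so the lower-envelope arithmetic stays valid.
static const double BIG = 1e15;

// 1D squared distance transform (lower envelope of parabolas), physical step.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  const double s2 = step * step;
  auto intersect = [&](int q, int p) {
    return ((f[q] + q * (double)q * s2) - (f[p] + p * (double)p * s2)) /
           (2.0 * s2 * (q - p));
  };
  for (int q = 1; q < n; q++) {
    double s = intersect(q, v[k]);
    while (s <= z[k]) {
      k--;
      s = intersect(q, v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = (q - p) * (double)(q - p) * s2 + f[p];
  }
}

// Squared Euclidean distance (voxel-centre to voxel-centre, mm) from every
// voxel to the nearest true voxel of `mask`. All-false mask gives BIG.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> f, d;
  // x axis
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; x++) g[base + x] = d[x];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; y++) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; z++) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return g;
}

static inline int mirror_idx(int i, int n) {
  // symmetric (half-sample mirror) boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// Correlation of a 3D array with a 1D kernel along one axis (0,1,2), mirror
// padding: out[i] = sum_t k[t] * a[i + t - center].
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector a, IntegerVector dim,
                        NumericVector kernel, int axis, int center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nk = kernel.size();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = nd[axis];
  const R_xlen_t st = stride[axis];

  // iterate over all lines along `axis`
  const int ou = (axis == 0) ? 1 : 0;
  const int ov = (axis == 2) ? 1 : 2;
  for (int v = 0; v < nd[ov]; v++)
    for (int u = 0; u < nd[ou]; u++) {
      R_xlen_t base = (R_xlen_t)u * stride[ou] + (R_xlen_t)v * stride[ov];
      for (int i = 0; i < na; i++) {
        double acc = 0.0;
        for (int t = 0; t < nk; t++) {
          int j = mirror_idx(i + t - center, na);
          acc += kernel[t] * a[base + (R_xlen_t)j * st];
        }
        out[base + (R_xlen_t)i * st] = acc;
      }
    }
  return out;
}

// Resample a volume onto a new grid. Both grids share the physical origin of
// the first voxel corner; voxel centre i sits at (i + 0.5) * spacing. `shift`
// (mm) samples the input at x + shift (rigid translation of the output frame).
// Out-of-range positions are clamped to the edge. nn = nearest neighbour.
// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector a, IntegerVector dim,
                         NumericVector spacing, IntegerVector odim,
                         NumericVector ospacing, NumericVector shift,
                         bool nn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  R_xlen_t o = 0;
  for (int z = 0; z < oz; z++)
    for (int y = 0; y < oy; y++)
      for (int x = 0; x < ox; x++, o++) {
        double px = (x + 0.5) * ospacing[0] + shift[0];
        double py = (y + 0.5) * ospacing[1] + shift[1];
        double pz = (z + 0.5) * ospacing[2] + shift[2];
        double u = px / spacing[0] - 0.5;
        double v = py / spacing[1] - 0.5;
        double w = pz / spacing[2] - 0.5;
        if (u < 0) u = 0; if (u > nx - 1) u = nx - 1;
        if (v < 0) v = 0; if (v > ny - 1) v = ny - 1;
        if (w < 0) w = 0; if (w > nz - 1) w = nz - 1;
        if (nn) {
          out[o] = a[idx((int)std::lround(u), (int)std::lround(v),
                         (int)std::lround(w))];
        } else {
          int x0 = (int)std::floor(u), y0 = (int)std::floor(v),
              z0 = (int)std::floor(w);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = u - x0, fy = v - y0, fz = w - z0;
          double c00 = a[idx(x0, y0, z0)] * (1 - fx) + a[idx(x1, y0, z0)] * fx;
          double c10 = a[idx(x0, y1, z0)] * (1 - fx) + a[idx(x1, y1, z0)] * fx;
          double c01 = a[idx(x0, y0, z1)] * (1 - fx) + a[idx(x1, y0, z1)] * fx;
          double c11 = a[idx(x0, y1, z1)] * (1 - fx) + a[idx(x1, y1, z1)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[o] = c0 * (1 - fz) + c1 * fz;
        }
      }
  return out;
}

// The 13 unique 3D direction offsets (distance-1 neighbours up to sign).
static const int OFFS[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
    {1, -1, 1}, {1, 1, -1}, {1, -1, -1}};

// Symmetric co-occurrence counts over the 13 offsets, summed (merged-matrix
// convention), plus the gray-level difference histogram (|i-j| = 0..ng-1).
// gray: 0 = outside region, 1..ng in region.
// [[Rcpp::export(name = ".glcm_counts")]]
List glcm_counts(IntegerVector gray, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, ng);
  NumericVector diff(ng);
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int g1 = gray[idx(x, y, z)];
        if (g1 <= 0) continue;
        for (int d = 0; d < 13; d++) {
          int x2 = x + OFFS[d][0], y2 = y + OFFS[d][1], z2 = z + OFFS[d][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int g2 = gray[idx(x2, y2, z2)];
          if (g2 <= 0) continue;
          m(g1 - 1, g2 - 1) += 1.0;
          m(g2 - 1, g1 - 1) += 1.0;
          diff[std::abs(g1 - g2)] += 2.0;
        }
      }
  return List::create(_["counts"] = m, _["diff"] = diff);
}

// Run-length counts aggregated over the requested directions (1-based
// indices into the 13 unique offsets). Runs are maximal constant-level
// segments; out-of-region voxels break runs.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerVector gray, IntegerVector dim, int ng,
                           IntegerVector directions) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  NumericMatrix m(ng, lmax);
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  for (int di = 0; di < directions.size(); di++) {
    const int d = directions[di] - 1;
    if (d < 0 || d >= 13) stop("direction index out of range");
    const int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          // line start: predecessor out of bounds
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz)
            continue;
          int cx = x, cy = y, cz = z;
          int level = 0, len = 0;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz) {
            int g = gray[idx(cx, cy, cz)];
            if (g == level) {
              len++;
            } else {
              if (level > 0) m(level - 1, len - 1) += 1.0;
              level = (g > 0) ? g : 0;
              len = (g > 0) ? 1 : 0;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (level > 0) m(level - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// NGTDM accumulation over the 26-neighbourhood: per gray level, the count of
// valid voxels n_i and the summed absolute deviation s_i from the neighbour
// mean. Voxels with no in-region neighbour are skipped.
// [[Rcpp::export(name = ".ngtdm_stats")]]
List ngtdm_stats(IntegerVector gray, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector nvec(ng), svec(ng);
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int g = gray[idx(x, y, z)];
        if (g <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int g2 = gray[idx(x2, y2, z2)];
              if (g2 > 0) {
                sum += g2;
                cnt++;
              }
            }
        if (cnt > 0) {
          nvec[g - 1] += 1.0;
          svec[g - 1] += std::fabs(g - sum / cnt);
        }
      }
  return List::create(_["n"] = nvec, _["s"] = svec);
}

// Harrell concordance pair statistics with per-subject contributions for
// jackknife inference. Comparable pair: the earlier time is an event; an
// event tied in time with a censoring counts as earlier; two events at the
// same time are not comparable. Tied risks score 0.5.
// [[Rcpp::export(name = ".concordance_pairs")]]
List concordance_pairs(NumericVector risk, NumericVector time,
                       IntegerVector event) {
  const int n = risk.size();
  NumericVector S(n), W(n);
  double total = 0.0, ncomp = 0.0, nconc = 0.0, ntied = 0.0;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      int earlier = -1;
      if (time[i] < time[j]) {
        if (event[i] == 1) earlier = i;
      } else if (time[j] < time[i]) {
        if (event[j] == 1) earlier = j;
      } else {
        if (event[i] == 1 && event[j] == 0) earlier = i;
        else if (event[j] == 1 && event[i] == 0) earlier = j;
      }
      if (earlier < 0) continue;
      int other = (earlier == i) ? j : i;
      double s;
      if (risk[earlier] > risk[other]) {
        s = 1.0;
        nconc += 1.0;
      } else if (risk[earlier] == risk[other]) {
        s = 0.5;
        ntied += 1.0;
      } else {
        s = 0.0;
      }
      ncomp += 1.0;
      total += s;
      S[i] += s; S[j] += s;
      W[i] += 1.0; W[j] += 1.0;
    }
  }
  return List::create(_["n_comparable"] = ncomp, _["n_concordant"] = nconc,
                      _["n_tied"] = ntied, _["score"] = total, _["S"] = S,
                      _["W"] = W);
}
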