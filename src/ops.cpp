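// Low-level 3D image kernels shared by the segmentation / morphometry /
// association modules. Arrays are column-major with dims = (nz, ny, nx),
// i.e. linear index = z + nz*(y + ny*x); spacings are physical voxel
// pitches in micrometres, ordered (z, y, x) to match the array dims.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (long long)ny * x);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflect-101 boundary. sigma per axis in voxels;
// an axis with sigma <= 0 is left untouched.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &a, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  int n = axis == 0 ? nz : (axis == 1 ? ny : nx);
  if (n == 1) return;
  std::vector<double> line(n), out(n);

  // iterate over all lines along `axis`
  int d1 = axis == 0 ? ny : nz;
  int d2 = axis == 2 ? ny : nx;
  for (int i1 = 0; i1 < d1; ++i1) {
    for (int i2 = 0; i2 < d2; ++i2) {
      for (int t = 0; t < n; ++t) {
        int z = axis == 0 ? t : (axis == 1 ? i1 : i1);
        int y = axis == 1 ? t : (axis == 0 ? i1 : i2);
        int x = axis == 2 ? t : i2;
        line[t] = a[lin(z, y, x, nz, ny)];
      }
      for (int t = 0; t < n; ++t) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int u = t + j;
          if (u < 0) u = -u;                 // reflect-101
          if (u >= n) u = 2 * n - 2 - u;
          if (u < 0) u = 0;                  // tiny-axis guard
          if (u >= n) u = n - 1;
          acc += k[j + r] * line[u];
        }
        out[t] = acc;
      }
      for (int t = 0; t < n; ++t) {
        int z = axis == 0 ? t : (axis == 1 ? i1 : i1);
        int y = axis == 1 ? t : (axis == 0 ? i1 : i2);
        int x = axis == 2 ? t : i2;
        a[lin(z, y, x, nz, ny)] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector arr, IntegerVector dims,
                               NumericVector sigma_vox) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(a, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(a, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6- or 26-connectivity), iterative flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;

  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }

  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (auto &d : nb) {
        int zz = z + d[0], yy = y + d[1], xx = x + d[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = lin(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm run separably) with feature transform: for every
// voxel, the distance (center-to-center, micrometres) to the nearest voxel
// where `feature` is TRUE, plus the 0-based linear index of that voxel.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double> &f, double h, int n,
                 std::vector<double> &dout, std::vector<int> &arg) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      zz[0] = -INF;
      zz[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q * h * h) - (f[p] + p * (double)p * h * h)) /
          (2.0 * h * (q - p));
      if (s <= zz[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= zz[k] && k == 0) {
      // new parabola dominates everywhere
      v[0] = q;
      zz[0] = -INF;
      zz[1] = INF;
    } else {
      ++k;
      v[k] = q;
      zz[k] = s;
      zz[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int i = 0; i < n; ++i) {
      dout[i] = INF;
      arg[i] = -1;
    }
    return;
  }
  int j = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * h;
    while (j < k && zz[j + 1] < xi) ++j;
    int p = v[j];
    dout[i] = (xi - p * h) * (xi - p * h) + f[p];
    arg[i] = p;
  }
}

// [[Rcpp::export]]
List cpp_edt3d(LogicalVector feature, IntegerVector dims,
               NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  std::vector<double> D(n);
  std::vector<int> F(n);
  for (long long i = 0; i < n; ++i) {
    D[i] = feature[i] ? 0.0 : INF;
    F[i] = feature[i] ? (int)i : -1;
  }

  std::vector<double> fl, dl;
  std::vector<int> al, Fl;

  for (int axis = 0; axis < 3; ++axis) {
    int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
    double h = spacing[axis];
    if (len == 1) continue;
    fl.assign(len, 0);
    dl.assign(len, 0);
    al.assign(len, 0);
    Fl.assign(len, 0);
    int d1 = axis == 0 ? ny : nz;
    int d2 = axis == 2 ? ny : nx;
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i2 = 0; i2 < d2; ++i2) {
        for (int t = 0; t < len; ++t) {
          int z = axis == 0 ? t : i1;
          int y = axis == 1 ? t : (axis == 0 ? i1 : i2);
          int x = axis == 2 ? t : i2;
          int j = lin(z, y, x, nz, ny);
          fl[t] = D[j];
          Fl[t] = F[j];
        }
        dt1d(fl, h, len, dl, al);
        for (int t = 0; t < len; ++t) {
          int z = axis == 0 ? t : i1;
          int y = axis == 1 ? t : (axis == 0 ? i1 : i2);
          int x = axis == 2 ? t : i2;
          int j = lin(z, y, x, nz, ny);
          D[j] = dl[t];
          F[j] = al[t] >= 0 ? Fl[al[t]] : -1;
        }
      }
    }
  }

  NumericVector dist(n);
  IntegerVector feat(n);
  for (long long i = 0; i < n; ++i) {
    dist[i] = D[i] == INF ? R_PosInf : std::sqrt(D[i]);
    feat[i] = F[i];
  }
  dist.attr("dim") = dims;
  feat.attr("dim") = dims;
  return List::create(_["dist"] = dist, _["feature"] = feat);
}

// ---------------------------------------------------------------------------
// Marching-tetrahedra isosurface area. The scalar field is sampled at voxel
// centers; each grid cell (cube spanned by 8 neighbouring centers) is split
// into 6 tetrahedra around the 0-7 diagonal and the level-set crossing is
// triangulated per tetrahedron. Returns total triangle area (um^2 when
// spacing is in um).
// ---------------------------------------------------------------------------

struct P3 {
  double z, y, x;
};

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  double cz = uy * vx - ux * vy;
  double cy = ux * vz - uz * vx;
  double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

static inline P3 interp(const P3 &p1, const P3 &p2, double v1, double v2,
                        double level) {
  double t = (level - v1) / (v2 - v1);
  P3 p;
  p.z = p1.z + t * (p2.z - p1.z);
  p.y = p1.y + t * (p2.y - p1.y);
  p.x = p1.x + t * (p2.x - p1.x);
  return p;
}

// [[Rcpp::export]]
double cpp_surface_area_mt(NumericVector field, IntegerVector dims,
                           NumericVector spacing, double level) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if (nz < 2 || ny < 2 || nx < 2) return 0.0;
  double hz = spacing[0], hy = spacing[1], hx = spacing[2];

  // cube vertex bit layout: bit0 = x, bit1 = y, bit2 = z
  static const int tets[6][4] = {{0, 7, 1, 3}, {0, 7, 3, 2}, {0, 7, 2, 6},
                                 {0, 7, 6, 4}, {0, 7, 4, 5}, {0, 7, 5, 1}};
  double total = 0.0;
  double vals[8];
  P3 pos[8];

  for (int x = 0; x < nx - 1; ++x) {
    for (int y = 0; y < ny - 1; ++y) {
      for (int z = 0; z < nz - 1; ++z) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int cx = c & 1, cy = (c >> 1) & 1, cz = (c >> 2) & 1;
          double v = field[lin(z + cz, y + cy, x + cx, nz, ny)];
          vals[c] = v;
          pos[c] = {(z + cz) * hz, (y + cy) * hy, (x + cx) * hx};
          if (v > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int m = 0;
          for (int c = 0; c < 4; ++c)
            if (vals[T[c]] > level) m |= (1 << c);
          if (m == 0 || m == 15) continue;
          int inside[4], outside[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (m & (1 << c)) inside[ni++] = T[c];
            else outside[no++] = T[c];
          }
          if (ni == 1 || ni == 3) {
            int lone = ni == 1 ? inside[0] : outside[0];
            int *others = ni == 1 ? outside : inside;
            P3 q0 = interp(pos[lone], pos[others[0]], vals[lone],
                           vals[others[0]], level);
            P3 q1 = interp(pos[lone], pos[others[1]], vals[lone],
                           vals[others[1]], level);
            P3 q2 = interp(pos[lone], pos[others[2]], vals[lone],
                           vals[others[2]], level);
            total += tri_area(q0, q1, q2);
          } else { // 2 in, 2 out -> quad
            int i0 = inside[0], i1 = inside[1];
            int o0 = outside[0], o1 = outside[1];
            P3 q0 = interp(pos[i0], pos[o0], vals[i0], vals[o0], level);
            P3 q1 = interp(pos[i0], pos[o1], vals[i0], vals[o1], level);
            P3 q2 = interp(pos[i1], pos[o1], vals[i1], vals[o1], level);
            P3 q3 = interp(pos[i1], pos[o0], vals[i1], vals[o0], level);
            total += tri_area(q0, q1, q2);
            total += tri_area(q0, q2, q3);
          }
        }
      }
    }
  }
  return total;
}

// ---------------------------------------------------------------------------
// Local maxima in a box neighbourhood (radius per axis, voxels). Returns
// 1-based linear indices of voxels whose value exceeds `floor_` and is >=
// every neighbour in the box. Plateau duplicates are resolved by the caller.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector arr, IntegerVector dims,
                               IntegerVector rad, double floor_) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int rz = rad[0], ry = rad[1], rx = rad[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = arr[lin(z, y, x, nz, ny)];
        if (!(v > floor_)) continue;
        bool ok = true;
        for (int dz = -rz; dz <= rz && ok; ++dz)
          for (int dy = -ry; dy <= ry && ok; ++dy)
            for (int dx = -rx; dx <= rx && ok; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (arr[lin(zz, yy, xx, nz, ny)] > v) ok = false;
            }
        if (ok) hits.push_back(lin(z, y, x, nz, ny) + 1);
      }
  return IntegerVector(hits.begin(), hits.end());
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a 3D field onto a regular grid with the given
// output spacing (same physical extent, sample 0 at voxel center 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_resample_iso(NumericVector arr, IntegerVector dims,
                      NumericVector spacing, double target) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double ez = (nz - 1) * spacing[0];
  double ey = (ny - 1) * spacing[1];
  double ex = (nx - 1) * spacing[2];
  int mz = std::max(2, (int)std::floor(ez / target + 1e-9) + 1);
  int my = std::max(2, (int)std::floor(ey / target + 1e-9) + 1);
  int mx = std::max(2, (int)std::floor(ex / target + 1e-9) + 1);
  NumericVector out((long long)mz * my * mx);
  for (int x = 0; x < mx; ++x) {
    double fx = std::min(x * target / spacing[2], (double)nx - 1);
    int x0 = (int)fx;
    int x1 = std::min(x0 + 1, nx - 1);
    double tx = fx - x0;
    for (int y = 0; y < my; ++y) {
      double fy = std::min(y * target / spacing[1], (double)ny - 1);
      int y0 = (int)fy;
      int y1 = std::min(y0 + 1, ny - 1);
      double ty = fy - y0;
      for (int z = 0; z < mz; ++z) {
        double fz = std::min(z * target / spacing[0], (double)nz - 1);
        int z0 = (int)fz;
        int z1 = std::min(z0 + 1, nz - 1);
        double tz = fz - z0;
        double c00 = arr[lin(z0, y0, x0, nz, ny)] * (1 - tz) +
                     arr[lin(z1, y0, x0, nz, ny)] * tz;
        double c01 = arr[lin(z0, y0, x1, nz, ny)] * (1 - tz) +
                     arr[lin(z1, y0, x1, nz, ny)] * tz;
        double c10 = arr[lin(z0, y1, x0, nz, ny)] * (1 - tz) +
                     arr[lin(z1, y1, x0, nz, ny)] * tz;
        double c11 = arr[lin(z0, y1, x1, nz, ny)] * (1 - tz) +
                     arr[lin(z1, y1, x1, nz, ny)] * tz;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[lin(z, y, x, mz, my)] = c0 * (1 - tx) + c1 * tx;
      }
    }
  }
  IntegerVector od = IntegerVector::create(mz, my, mx);
  out.attr("dim") = od;
  return List::create(_["data"] = out, _["dims"] = od,
                      _["spacing"] = NumericVector::create(target, target,
                                                           target));
}
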