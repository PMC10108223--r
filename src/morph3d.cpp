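// Low-level 3D raster operations shared by the segmentation and
// quantification layers: 26-connected labeling, hysteresis flood fill,
// anisotropic Euclidean distance transform, 3D median filtering, slice-wise
// rolling-ball (grayscale opening) background, and topology-preserving
// directional thinning.
//
// Arrays follow the package convention: dimension (z, y, x), column-major as
// stored by R, so linear index = z + nz * (y + ny * x), all 0-based here.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int lidx(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur / (nz * ny), rem = cur % (nz * ny);
      int y = rem / nz, z = rem % nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                xx < 0 || xx >= nx) continue;
            int j = lidx(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) {
              labels[j] = next_label;
              stack.push_back(j);
            }
          }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// [[Rcpp::export]]
LogicalVector cpp_hysteresis(NumericVector img, IntegerVector dims,
                             double low, double high) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  LogicalVector out(n, false);
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (img[i] > high) { out[i] = true; stack.push_back(i); }
  }
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int x = cur / (nz * ny), rem = cur % (nz * ny);
    int y = rem / nz, z = rem % nz;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
              xx < 0 || xx >= nx) continue;
          int j = lidx(zz, yy, xx, nz, ny);
          if (!out[j] && img[j] > low) {
            out[j] = true;
            stack.push_back(j);
          }
        }
  }
  return out;
}

// ---- anisotropic squared EDT (Felzenszwalb & Huttenlocher, per axis) ------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -HUGE_VAL; zb[1] = HUGE_VAL;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = (f[q] + w2 * q * q - f[p] - w2 * p * p) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dims,
                      NumericVector spacing_zyx) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const double wz = spacing_zyx[0], wy = spacing_zyx[1], wx = spacing_zyx[2];
  // large finite sentinel: true infinities make the envelope intersection
  // arithmetic produce -inf/NaN and corrupt the parabola stack
  const double INF2 = 1e18;
  NumericVector d(n);
  for (int i = 0; i < n; ++i) d[i] = fg[i] ? INF2 : 0.0;

  std::vector<double> f, out;
  // pass along z
  f.resize(nz); out.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lidx(z, y, x, nz, ny)];
      dt1d(f, out, nz, wz);
      for (int z = 0; z < nz; ++z) d[lidx(z, y, x, nz, ny)] = out[z];
    }
  // pass along y
  f.resize(ny); out.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[lidx(z, y, x, nz, ny)];
      dt1d(f, out, ny, wy);
      for (int y = 0; y < ny; ++y) d[lidx(z, y, x, nz, ny)] = out[y];
    }
  // pass along x
  f.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[lidx(z, y, x, nz, ny)];
      dt1d(f, out, nx, wx);
      for (int x = 0; x < nx; ++x) d[lidx(z, y, x, nz, ny)] = out[x];
    }
  for (int i = 0; i < n; ++i) d[i] = std::sqrt(d[i]);
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector img, IntegerVector dims,
                           int rz, int ry, int rx) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(img.size());
  std::vector<double> box;
  box.reserve((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        box.clear();
        for (int dz = -rz; dz <= rz; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -rx; dx <= rx; ++dx) {
              int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              box.push_back(img[lidx(zz, yy, xx, nz, ny)]);
            }
          }
        }
        size_t m = box.size() / 2;
        std::nth_element(box.begin(), box.begin() + m, box.end());
        double med = box[m];
        if (box.size() % 2 == 0) {
          std::nth_element(box.begin(), box.begin() + m - 1, box.end());
          med = (med + box[m - 1]) / 2.0;
        }
        out[lidx(z, y, x, nz, ny)] = med;
      }
  return out;
}

// grayscale opening of one slice with a non-flat ball structuring element
// (heights sqrt(r^2 - s^2) - r <= 0); returns the background estimate
// [[Rcpp::export]]
NumericMatrix cpp_rollball(NumericMatrix slice, double radius) {
  const int h = slice.nrow(), w = slice.ncol();
  const int r = (int)std::floor(radius);
  std::vector<std::pair<std::pair<int,int>, double> > se;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj) {
      double d2 = (double)di * di + (double)dj * dj;
      if (d2 <= radius * radius) {
        se.push_back(std::make_pair(std::make_pair(di, dj),
                                    std::sqrt(radius * radius - d2) - radius));
      }
    }
  NumericMatrix ero(h, w), out(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double m = HUGE_VAL;
      for (size_t k = 0; k < se.size(); ++k) {
        int ii = i + se[k].first.first, jj = j + se[k].first.second;
        if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
        double v = slice(ii, jj) - se[k].second;
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double m = -HUGE_VAL;
      for (size_t k = 0; k < se.size(); ++k) {
        int ii = i + se[k].first.first, jj = j + se[k].first.second;
        if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
        double v = ero(ii, jj) + se[k].second;
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// ---- topology-preserving directional thinning -----------------------------
// A voxel is "simple" (deletable without changing topology, 26/6 duality) iff
// (a) its foreground 26-neighbours form exactly one 26-connected component
// and (b) the background voxels of its 18-neighbourhood that are 6-reachable
// from a background face-neighbour form exactly one 6-connected component.
// Checked by explicit component analysis of the 3x3x3 neighbourhood.

static bool is_simple(const std::vector<signed char>& nb) {
  // nb: 27 flags (dz,dy,dx in row-major order dz slowest), centre index 13
  // (a) fg components under 26-connectivity, centre excluded
  int fgc = 0;
  bool seen[27] = {false};
  int nfg = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++nfg;
  if (nfg == 0) return false;
  std::vector<int> stack;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++fgc;
    if (fgc > 1) return false;
    seen[i] = true; stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / 9, cy = (cur % 9) / 3, cx = cur % 3;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seen[j] || !nb[j]) continue;
        int jz = j / 9, jy = (j % 9) / 3, jx = j % 3;
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jx - cx) <= 1) {
          seen[j] = true; stack.push_back(j);
        }
      }
    }
  }
  if (fgc != 1) return false;

  // (b) bg 6-components within N18 touching a face neighbour
  // N18 = positions with at least one zero offset (excludes the 8 corners)
  bool inN18[27], bg[27];
  for (int i = 0; i < 27; ++i) {
    int z = i / 9 - 1, y = (i % 9) / 3 - 1, x = i % 3 - 1;
    inN18[i] = !(z != 0 && y != 0 && x != 0) && i != 13;
    bg[i] = !nb[i];
  }
  bool seenb[27] = {false};
  int bgc = 0;
  static const int face_ids[6] = {4, 22, 10, 16, 12, 14}; // +-z, +-y, +-x
  for (int fi = 0; fi < 6; ++fi) {
    int i = face_ids[fi];
    if (!bg[i] || seenb[i]) continue;
    ++bgc;
    if (bgc > 1) return false;
    seenb[i] = true; stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / 9, cy = (cur % 9) / 3, cx = cur % 3;
      for (int j = 0; j < 27; ++j) {
        if (!inN18[j] || seenb[j] || !bg[j]) continue;
        int jz = j / 9, jy = (j % 9) / 3, jx = j % 3;
        int manh = std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx);
        if (manh == 1) { seenb[j] = true; stack.push_back(j); }
      }
    }
  }
  return bgc == 1;
}

static void fill_nb(const std::vector<signed char>& m, int z, int y, int x,
                    int nz, int ny, int nx, std::vector<signed char>& nb) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        nb[k] = (zz >= 0 && zz < nz && yy >= 0 && yy < ny &&
                 xx >= 0 && xx < nx) ? m[lidx(zz, yy, xx, nz, ny)] : 0;
      }
}

static int count_fg_neighbours(const std::vector<signed char>& nb) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  std::vector<signed char> m(n);
  for (int i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  // border directions: offsets (dz,dy,dx) of the background neighbour
  static const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},
                                 {0,0,-1},{0,0,1}};
  std::vector<signed char> nb(27);
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int di = 0; di < 6; ++di) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            int i = lidx(z, y, x, nz, ny);
            if (!m[i]) continue;
            int zz = z + dirs[di][0], yy = y + dirs[di][1],
                xx = x + dirs[di][2];
            bool border = (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                           xx < 0 || xx >= nx) ||
                          !m[lidx(zz, yy, xx, nz, ny)];
            if (!border) continue;
            fill_nb(m, z, y, x, nz, ny, nx, nb);
            if (count_fg_neighbours(nb) <= 1) continue;  // endpoint kept
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential re-check: earlier deletions may make later ones unsafe
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        int x = i / (nz * ny), rem = i % (nz * ny);
        int y = rem / nz, z = rem % nz;
        fill_nb(m, z, y, x, nz, ny, nx, nb);
        if (count_fg_neighbours(nb) <= 1) continue;
        if (is_simple(nb)) { m[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbour_count26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector out(n, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lidx(z, y, x, nz, ny);
        if (!mask[i]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) continue;
              if (mask[lidx(zz, yy, xx, nz, ny)]) ++c;
            }
        out[i] = c;
      }
  return out;
}
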