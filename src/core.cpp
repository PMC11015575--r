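#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
#include <functional>
#include <unordered_map>
using namespace Rcpp;

// Arrays are R arrays with dim = (nz, ny, nx): linear index = z + nz*(y + ny*x).

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---- 3D connected-component labelling (6- or 26-connectivity) ----

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = lin(zz, yy, xx, nz, ny);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) ----

static const double BIGD = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb,
                 int n, double s2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Distance (um) from each foreground voxel to the nearest background voxel
// (background includes the outside of the grid when pad_background is true).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                        bool pad_background = false) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? BIGD : 0.0;

  int maxdim = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxdim), d(maxdim), zb(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along z
  double s2 = spacing[0] * spacing[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = D[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nz, s2);
      for (int z = 0; z < nz; ++z) D[lin(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = D[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, ny, s2);
      for (int y = 0; y < ny; ++y) D[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  s2 = spacing[2] * spacing[2];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = D[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nx, s2);
      for (int x = 0; x < nx; ++x) D[lin(z, y, x, nz, ny)] = d[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double dist = std::sqrt(D[i]);
    if (pad_background && mask[i]) {
      // distance to the grid boundary caps the interior distance
      int x = (int)(i / ((R_xlen_t)nz * ny));
      R_xlen_t rem = i - (R_xlen_t)x * nz * ny;
      int y = (int)(rem / nz);
      int z = (int)(rem - (R_xlen_t)y * nz);
      double bz = spacing[0] * (std::min(z, nz - 1 - z) + 1);
      double by = spacing[1] * (std::min(y, ny - 1 - y) + 1);
      double bx = spacing[2] * (std::min(x, nx - 1 - x) + 1);
      dist = std::min(dist, std::min(bz, std::min(by, bx)));
    }
    out[i] = dist;
  }
  return out;
}

// ---- separable Gaussian blur, reflected boundaries ----

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector x, IntegerVector dim, NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (x.size() != n) stop("length mismatch");
  std::vector<double> a(x.begin(), x.end()), b(n);

  for (int axis = 0; axis < 3; ++axis) {
    double sg = sigma_vox[axis];
    if (sg <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * sg));
    std::vector<double> k(2 * r + 1);
    double ks = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (sg * sg));
      ks += k[i + r];
    }
    for (auto &v : k) v /= ks;

    int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // compute base index of the line
      R_xlen_t base;
      if (axis == 0) {
        base = line * nz;
      } else if (axis == 1) {
        R_xlen_t xz = line;            // over (z, x): z fastest
        int z = (int)(xz % nz);
        R_xlen_t xx = xz / nz;
        base = z + (R_xlen_t)nz * ny * xx;
      } else {
        base = line;                   // over (z, y) contiguous block
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;                 // reflect
          if (p >= len) p = 2 * len - 1 - p;
          acc += k[j + r] * a[base + (R_xlen_t)p * stride];
        }
        b[base + (R_xlen_t)i * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---- 3D curve thinning (26-connected foreground / 6-connected background) ----

// simple-point test on a 3x3x3 neighbourhood; cube[27] foreground flags,
// centre at index 13 (ordering: idx = (dz+1) + 3*((dy+1) + 3*(dx+1)))
static bool is_simple(const uint8_t cube[27]) {
  // C*: number of 26-components of foreground in N26 (centre excluded) == 1
  int comp = 0;
  uint8_t seen[27] = {0};
  int stack[27], top;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !cube[i] || seen[i]) continue;
    ++comp;
    if (comp > 1) return false;
    top = 0; stack[top++] = i; seen[i] = 1;
    while (top) {
      int cur = stack[--top];
      int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seen[j] || !cube[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 && std::abs(jx - cx) <= 1)
          { seen[j] = 1; stack[top++] = j; }
      }
    }
  }
  if (comp != 1) return false;

  // C-bar: 6-components of background within N18 that touch a face neighbour == 1
  uint8_t inN18[27] = {0};
  for (int i = 0; i < 27; ++i) {
    int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
    int manh = std::abs(z) + std::abs(y) + std::abs(x);
    if (i != 13 && manh <= 2) inN18[i] = 1;
  }
  const int faceIdx[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  uint8_t seenb[27] = {0};
  comp = 0;
  for (int fi = 0; fi < 6; ++fi) {
    int i = faceIdx[fi];
    if (cube[i] || seenb[i]) continue;
    ++comp;
    if (comp > 1) return false;
    top = 0; stack[top++] = i; seenb[i] = 1;
    while (top) {
      int cur = stack[--top];
      int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (!inN18[j] || seenb[j] || cube[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        if (std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx) == 1)
          { seenb[j] = 1; stack[top++] = j; }
      }
    }
  }
  return comp == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize3(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<uint8_t> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  std::vector<int> fg;
  for (R_xlen_t i = 0; i < n; ++i) if (m[i]) fg.push_back((int)i);

  const int dirz[6] = {1, -1, 0, 0, 0, 0};
  const int diry[6] = {0, 0, 1, -1, 0, 0};
  const int dirx[6] = {0, 0, 0, 0, 1, -1};

  auto at = [&](int z, int y, int x) -> uint8_t {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return m[lin(z, y, x, nz, ny)];
  };

  uint8_t cube[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int idx : fg) {
        if (!m[idx]) continue;
        int x = idx / (nz * ny);
        int rem = idx - x * nz * ny;
        int y = rem / nz;
        int z = rem - y * nz;
        if (at(z + dirz[d], y + diry[d], x + dirx[d]) == 0)
          cand.push_back(idx);
      }
      for (int idx : cand) {
        if (!m[idx]) continue;
        int x = idx / (nz * ny);
        int rem = idx - x * nz * ny;
        int y = rem / nz;
        int z = rem - y * nz;
        int nn = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              cube[(a + 1) + 3 * ((b + 1) + 3 * (c + 1))] = at(z + a, y + b, x + c);
              if (!(a == 0 && b == 0 && c == 0)) nn += at(z + a, y + b, x + c);
            }
        // keep endpoints (<=1 neighbour) and curve voxels (2 neighbours):
        // a degree-2 voxel is either a bridge (not simple anyway) or a
        // corner of a 26-connected digital line, whose removal would let
        // staircase-shaped curves erode from the tip inwards
        if (nn <= 2) continue;
        if (is_simple(cube)) {
          m[idx] = 0;
          changed = true;
        }
      }
    }
    // compact the foreground list
    std::vector<int> fg2;
    fg2.reserve(fg.size());
    for (int idx : fg) if (m[idx]) fg2.push_back(idx);
    fg.swap(fg2);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// ---- components / adjacency on sparse voxel coordinate sets ----

static inline long long ckey(int z, int y, int x) {
  return ((long long)x << 42) | ((long long)y << 21) | (long long)z;
}

// number of 26-connected components among the given voxel coordinates
// (n x 3 matrix of non-negative integer (z,y,x) indices)
// [[Rcpp::export]]
int cpp_count_components_coords(IntegerMatrix coords) {
  int n = coords.nrow();
  if (n == 0) return 0;
  std::unordered_map<long long, int> idx;
  idx.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    idx[ckey(coords(i, 0), coords(i, 1), coords(i, 2))] = i;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  for (int i = 0; i < n; ++i) {
    int z = coords(i, 0), y = coords(i, 1), x = coords(i, 2);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          auto it = idx.find(ckey(z + a, y + b, x + c));
          if (it != idx.end()) {
            int ri = find(i), rj = find(it->second);
            if (ri != rj) parent[ri] = rj;
          }
        }
  }
  int comp = 0;
  for (int i = 0; i < n; ++i) if (find(i) == i) ++comp;
  return comp;
}

// 26-adjacency edge list (1-based, i < j) among the given voxel coordinates
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency_coords(IntegerMatrix coords) {
  int n = coords.nrow();
  std::unordered_map<long long, int> idx;
  idx.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    idx[ckey(coords(i, 0), coords(i, 1), coords(i, 2))] = i;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    int z = coords(i, 0), y = coords(i, 1), x = coords(i, 2);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          auto it = idx.find(ckey(z + a, y + b, x + c));
          if (it != idx.end() && it->second > i) {
            ei.push_back(i + 1);
            ej.push_back(it->second + 1);
          }
        }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) { out(k, 0) = ei[k]; out(k, 1) = ej[k]; }
  return out;
}

// ---- rasterization: voxels within radius r (um) of any of the given centres ----

// centres: n x 3 matrix of physical (z, y, x) coordinates in um; voxel centre
// of index (z,y,x) sits at (z*sz, y*sy, x*sx). Returns unique 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_ball_indices(IntegerVector dim, NumericVector spacing,
                               NumericMatrix centres, double r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double r2 = r * r;
  std::vector<uint8_t> hit((size_t)nz * ny * nx, 0);
  std::vector<int> out;
  for (int i = 0; i < centres.nrow(); ++i) {
    double cz = centres(i, 0), cy = centres(i, 1), cx = centres(i, 2);
    int z0 = std::max(0, (int)std::ceil((cz - r) / sz));
    int z1 = std::min(nz - 1, (int)std::floor((cz + r) / sz));
    int y0 = std::max(0, (int)std::ceil((cy - r) / sy));
    int y1 = std::min(ny - 1, (int)std::floor((cy + r) / sy));
    int x0 = std::max(0, (int)std::ceil((cx - r) / sx));
    int x1 = std::min(nx - 1, (int)std::floor((cx + r) / sx));
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * sx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * sy - cy;
        double dyx = ddx * ddx + ddy * ddy;
        if (dyx > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * sz - cz;
          if (dyx + ddz * ddz <= r2) {
            int j = lin(z, y, x, nz, ny);
            if (!hit[j]) { hit[j] = 1; out.push_back(j + 1); }
          }
        }
      }
    }
  }
  return IntegerVector(out.begin(), out.end());
}
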