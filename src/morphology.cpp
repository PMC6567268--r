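// 3D binary morphology kernels for voxelized vascular stacks.
// Grids are logical arrays with dim = c(nz, ny, nx), column-major, so the
// linear index of (z, y, x) (0-based) is z + nz * (y + ny * x).

#include <Rcpp.h>
#include <array>
#include <climits>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Offsets {
  std::vector<std::array<int, 3>> d;  // (dz, dy, dx)
};

// Neighborhood by face/edge/vertex adjacency: 6, 18 or 26 neighbors.
Offsets neighborhood(int conn) {
  if (conn != 6 && conn != 18 && conn != 26)
    stop("connectivity must be 6, 18 or 26");
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if ((conn == 6 && m > 1) || (conn == 18 && m > 2)) continue;
        o.d.push_back({dz, dy, dx});
      }
  return o;
}

inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

void check_dim(const IntegerVector& dim, R_xlen_t n) {
  if (dim.size() != 3) stop("dim must have length 3");
  if ((R_xlen_t)dim[0] * dim[1] * dim[2] != n)
    stop("dim does not match vector length");
}

// One dilation pass, clipped at the stack faces (no wraparound/padding).
void dilate_into(const std::vector<uint8_t>& in, std::vector<uint8_t>& out,
                 int nz, int ny, int nx, const Offsets& off) {
  std::copy(in.begin(), in.end(), out.begin());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (!in[lin(z, y, x, nz, ny)]) continue;
        for (const auto& d : off.d) {
          int zz = z + d[0], yy = y + d[1], xx = x + d[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          out[lin(zz, yy, xx, nz, ny)] = 1;
        }
      }
}

std::vector<uint8_t> to_u8(const LogicalVector& v) {
  std::vector<uint8_t> u(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) u[i] = (v[i] == TRUE) ? 1 : 0;
  return u;
}

LogicalVector to_lgl(const std::vector<uint8_t>& u, const IntegerVector& dim) {
  LogicalVector v(u.size());
  for (size_t i = 0; i < u.size(); ++i) v[i] = (u[i] != 0);
  v.attr("dim") = dim;
  return v;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector vox, IntegerVector dim, int conn) {
  check_dim(dim, vox.size());
  int nz = dim[0], ny = dim[1], nx = dim[2];
  Offsets off = neighborhood(conn);
  std::vector<uint8_t> in = to_u8(vox), out(in.size());
  dilate_into(in, out, nz, ny, nx, off);
  return to_lgl(out, dim);
}

// Erosion dual to cpp_dilate; voxels outside the stack count as background
// (a closing therefore retracts to the original extent at the faces; the
// caller's union-with-input preserves clipped original signal).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector vox, IntegerVector dim, int conn) {
  check_dim(dim, vox.size());
  int nz = dim[0], ny = dim[1], nx = dim[2];
  Offsets off = neighborhood(conn);
  std::vector<uint8_t> in = to_u8(vox), out(in.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!in[i]) { out[i] = 0; continue; }
        uint8_t keep = 1;
        for (const auto& d : off.d) {
          int zz = z + d[0], yy = y + d[1], xx = x + d[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
            keep = 0;
            break;
          }
          if (!in[lin(zz, yy, xx, nz, ny)]) { keep = 0; break; }
        }
        out[i] = keep;
      }
  return to_lgl(out, dim);
}

namespace {

// Does foreground voxel i (coords z,y,x) have any background 26-neighbor?
inline bool has_bg_neighbor(const std::vector<uint8_t>& v, int z, int y,
                            int x, int nz, int ny, int nx) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        if (!v[lin(zz, yy, xx, nz, ny)]) return true;
      }
  return false;
}

}  // namespace

// Occupancy (% foreground) after each dilation step, cycling through the
// structuring-element sequence `scheme` (values 6/18/26), until occupancy
// reaches target_pct or the grid is full. Element 1 of the result is the
// occupancy before any dilation. Uses front tracking: only foreground
// voxels with a background 26-neighbor can generate additions, so each
// step costs O(front size), not O(grid size); the result is identical to
// full-grid dilation.
// [[Rcpp::export]]
NumericVector cpp_occupancy_trace(LogicalVector vox, IntegerVector dim,
                                  double target_pct, IntegerVector scheme,
                                  int max_steps) {
  check_dim(dim, vox.size());
  int nz = dim[0], ny = dim[1], nx = dim[2];
  if (scheme.size() < 1) stop("scheme must be non-empty");
  std::vector<Offsets> offs;
  for (int k = 0; k < scheme.size(); ++k) offs.push_back(neighborhood(scheme[k]));
  std::vector<uint8_t> cur = to_u8(vox);
  R_xlen_t n = (R_xlen_t)cur.size();
  long long cnt = 0;
  for (uint8_t v : cur) cnt += v;
  if (cnt == 0) stop("cannot dilate an empty stack");

  // initial front: foreground voxels adjacent (26) to background
  std::vector<int> front, additions, next_front;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (cur[i] && has_bg_neighbor(cur, z, y, x, nz, ny, nx))
          front.push_back(i);
      }

  std::vector<double> occ;
  occ.push_back(100.0 * cnt / (double)n);
  int step = 0;
  while (occ.back() < target_pct && cnt < (long long)n) {
    if (step >= max_steps) stop("target occupancy not reached in max_steps");
    const Offsets& off = offs[step % offs.size()];
    additions.clear();
    for (int i : front) {
      int z = i % nz, rem = i / nz;
      int y = rem % ny, x = rem / ny;
      bool interior = z > 0 && z < nz - 1 && y > 0 && y < ny - 1 &&
                      x > 0 && x < nx - 1;
      for (const auto& d : off.d) {
        int zz = z + d[0], yy = y + d[1], xx = x + d[2];
        if (!interior &&
            (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx))
          continue;
        int j = lin(zz, yy, xx, nz, ny);
        if (!cur[j]) {
          cur[j] = 1;
          additions.push_back(j);
        }
      }
    }
    cnt += (long long)additions.size();
    // new front: any old-front or newly added voxel still facing background
    next_front.clear();
    auto keep_if_front = [&](int i) {
      int z = i % nz, rem = i / nz;
      int y = rem % ny, x = rem / ny;
      if (has_bg_neighbor(cur, z, y, x, nz, ny, nx)) next_front.push_back(i);
    };
    for (int i : front) keep_if_front(i);
    for (int i : additions) keep_if_front(i);
    front.swap(next_front);
    occ.push_back(100.0 * cnt / (double)n);
    ++step;
  }
  return NumericVector(occ.begin(), occ.end());
}

// Connected-component labeling of foreground (conn = 6, 18 or 26).
// Returns labels (0 = background), component sizes, and whether each
// component touches any stack face.
// [[Rcpp::export]]
List cpp_label(LogicalVector vox, IntegerVector dim, int conn) {
  check_dim(dim, vox.size());
  int nz = dim[0], ny = dim[1], nx = dim[2];
  Offsets off = neighborhood(conn);
  std::vector<uint8_t> in = to_u8(vox);
  IntegerVector labels(vox.size(), 0);
  std::vector<int> sizes;
  std::vector<int> face;
  std::vector<int> stack_;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!in[i] || labels[i] != 0) continue;
        ++next;
        int size = 0, touches = 0;
        labels[i] = next;
        stack_.clear();
        stack_.push_back(i);
        while (!stack_.empty()) {
          int j = stack_.back();
          stack_.pop_back();
          ++size;
          int xz = j % nz, rem = j / nz;
          int xy = rem % ny, xx = rem / ny;
          if (xz == 0 || xz == nz - 1 || xy == 0 || xy == ny - 1 ||
              xx == 0 || xx == nx - 1)
            touches = 1;
          for (const auto& d : off.d) {
            int zz = xz + d[0], yy = xy + d[1], ww = xx + d[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || ww < 0 || ww >= nx)
              continue;
            int k = lin(zz, yy, ww, nz, ny);
            if (in[k] && labels[k] == 0) {
              labels[k] = next;
              stack_.push_back(k);
            }
          }
        }
        sizes.push_back(size);
        face.push_back(touches);
      }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["touches_face"] = LogicalVector(face.begin(), face.end()));
}

namespace {

// 2D 8-connected component areas within one axis-aligned slice.
// axis: 0 = fixed z (plane y-x), 1 = fixed y (plane z-x), 2 = fixed x (plane z-y).
// For slice w along `axis`, writes each in-plane component's area into `out`
// at the voxel's 3D linear index, taking min with the existing value.
void slice_areas(const std::vector<uint8_t>& in, std::vector<int>& out,
                 std::vector<int>& lab2d, int axis, int w,
                 int nz, int ny, int nx) {
  int d1, d2;  // in-plane extents (u, v)
  if (axis == 0) { d1 = ny; d2 = nx; }
  else if (axis == 1) { d1 = nz; d2 = nx; }
  else { d1 = nz; d2 = ny; }
  auto at = [&](int u, int v) {
    if (axis == 0) return lin(w, u, v, nz, ny);
    if (axis == 1) return lin(u, w, v, nz, ny);
    return lin(u, v, w, nz, ny);
  };
  std::fill(lab2d.begin(), lab2d.begin() + (size_t)d1 * d2, 0);
  std::vector<std::pair<int, int>> stack_;
  std::vector<int> members;
  int next = 0;
  for (int v = 0; v < d2; ++v)
    for (int u = 0; u < d1; ++u) {
      int p = u + d1 * v;
      if (!in[at(u, v)] || lab2d[p] != 0) continue;
      ++next;
      lab2d[p] = next;
      stack_.clear();
      members.clear();
      stack_.push_back({u, v});
      while (!stack_.empty()) {
        auto [cu, cv] = stack_.back();
        stack_.pop_back();
        members.push_back(at(cu, cv));
        for (int du = -1; du <= 1; ++du)
          for (int dv = -1; dv <= 1; ++dv) {
            if (du == 0 && dv == 0) continue;
            int uu = cu + du, vv = cv + dv;
            if (uu < 0 || uu >= d1 || vv < 0 || vv >= d2) continue;
            int q = uu + d1 * vv;
            if (in[at(uu, vv)] && lab2d[q] == 0) {
              lab2d[q] = next;
              stack_.push_back({uu, vv});
            }
          }
      }
      int area = (int)members.size();
      for (int m : members)
        if (area < out[m]) out[m] = area;
    }
}

}  // namespace

// Per-voxel minimal cross-section: for each foreground voxel, the area of
// the 8-connected in-plane component containing it, minimized over the
// three axis-aligned planes. Background voxels get 0.
// [[Rcpp::export]]
IntegerVector cpp_min_xsec(LogicalVector vox, IntegerVector dim) {
  check_dim(dim, vox.size());
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<uint8_t> in = to_u8(vox);
  std::vector<int> out(in.size(), INT_MAX);
  size_t maxplane = (size_t)std::max({(long long)ny * nx, (long long)nz * nx,
                                      (long long)nz * ny});
  std::vector<int> lab2d(maxplane);
  for (int w = 0; w < nz; ++w) slice_areas(in, out, lab2d, 0, w, nz, ny, nx);
  for (int w = 0; w < ny; ++w) slice_areas(in, out, lab2d, 1, w, nz, ny, nx);
  for (int w = 0; w < nx; ++w) slice_areas(in, out, lab2d, 2, w, nz, ny, nx);
  IntegerVector res(vox.size());
  for (size_t i = 0; i < in.size(); ++i) res[i] = in[i] ? out[i] : 0;
  res.attr("dim") = dim;
  return res;
}

// Rasterize capsules (cylinders with hemispherical caps) onto a voxel grid.
// p0, p1: n x 3 matrices of segment endpoints in micrometers, columns (z,y,x);
// radius in micrometers. A voxel is foreground when its center lies within
// distance r of the segment. Also returns the per-voxel generating radius
// (max over covering capsules; 0 where background).
// [[Rcpp::export]]
List cpp_rasterize_capsules(NumericMatrix p0, NumericMatrix p1,
                            NumericVector radius, IntegerVector dim,
                            double spacing) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (spacing <= 0) stop("spacing must be positive");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = radius.size();
  if (p0.nrow() != n || p1.nrow() != n) stop("segment arrays disagree");
  LogicalVector vox((R_xlen_t)nz * ny * nx, FALSE);
  NumericVector rmap((R_xlen_t)nz * ny * nx, 0.0);
  for (R_xlen_t s = 0; s < n; ++s) {
    double az = p0(s, 0), ay = p0(s, 1), ax = p0(s, 2);
    double bz = p1(s, 0), by = p1(s, 1), bx = p1(s, 2);
    double r = radius[s];
    if (r <= 0) stop("radius must be positive");
    double lo[3] = {std::min(az, bz) - r, std::min(ay, by) - r,
                    std::min(ax, bx) - r};
    double hi[3] = {std::max(az, bz) + r, std::max(ay, by) + r,
                    std::max(ax, bx) + r};
    int ext[3] = {nz, ny, nx};
    int i0[3], i1[3];
    bool empty = false;
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::floor(lo[k] / spacing - 0.5));
      i1[k] = std::min(ext[k] - 1, (int)std::ceil(hi[k] / spacing - 0.5));
      if (i0[k] > i1[k]) empty = true;
    }
    if (empty) continue;
    double vz = bz - az, vy = by - ay, vx = bx - ax;
    double vv = vz * vz + vy * vy + vx * vx;
    double r2 = r * r;
    for (int x = i0[2]; x <= i1[2]; ++x) {
      double cx = (x + 0.5) * spacing - ax;
      for (int y = i0[1]; y <= i1[1]; ++y) {
        double cy = (y + 0.5) * spacing - ay;
        for (int z = i0[0]; z <= i1[0]; ++z) {
          double cz = (z + 0.5) * spacing - az;
          double t = 0.0;
          if (vv > 0) {
            t = (cz * vz + cy * vy + cx * vx) / vv;
            if (t < 0) t = 0;
            if (t > 1) t = 1;
          }
          double dz = cz - t * vz, dy = cy - t * vy, dx = cx - t * vx;
          if (dz * dz + dy * dy + dx * dx <= r2) {
            R_xlen_t i = lin(z, y, x, nz, ny);
            vox[i] = TRUE;
            if (r > rmap[i]) rmap[i] = r;
          }
        }
      }
    }
  }
  vox.attr("dim") = dim;
  rmap.attr("dim") = dim;
  return List::create(_["voxels"] = vox, _["radius_map"] = rmap);
}
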