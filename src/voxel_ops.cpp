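// Low-level 3D voxel kernels for anisotropic confocal stacks.
// Arrays are R arrays with dim = c(nz, ny, nx); linear index
// idx = z + nz * (y + ny * x), all 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Run a 1D kernel along one axis of the volume. axis: 0=z, 1=y, 2=x.
static void conv1d_axis(const std::vector<double>& in, std::vector<double>& out,
                        int nz, int ny, int nx, int axis,
                        const std::vector<double>& kernel) {
  const int r = ((int)kernel.size() - 1) / 2;
  const int len = (axis == 0) ? nz : (axis == 1 ? ny : nx);
  for (int a = 0; a < (axis == 0 ? ny : nz); ++a) {
    for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0 || j >= len) continue; // zero padding
          R_xlen_t idx;
          if (axis == 0)      idx = lin(j, a, b, nz, ny);
          else if (axis == 1) idx = lin(a, j, b, nz, ny);
          else                idx = lin(a, b, j, nz, ny);
          acc += in[idx] * kernel[k + r];
        }
        R_xlen_t oidx;
        if (axis == 0)      oidx = lin(i, a, b, nz, ny);
        else if (axis == 1) oidx = lin(a, i, b, nz, ny);
        else                oidx = lin(a, b, i, nz, ny);
        out[oidx] = acc;
      }
    }
  }
}

// Separable Gaussian blur, sigma per axis in voxel units; sigma <= 0 skips axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector arr, IntegerVector dim,
                                NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(arr.begin(), arr.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) { kern[k + r] = std::exp(-0.5 * k * k / (s * s)); tot += kern[k + r]; }
    for (double& v : kern) v /= tot;
    conv1d_axis(cur, tmp, nz, ny, nx, axis, kern);
    cur.swap(tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Separable box sum with zero padding; half widths per axis in voxels.
// Divide by cpp_box_sum(ones) in R to obtain an edge-correct box mean.
// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector arr, IntegerVector dim, IntegerVector half) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(arr.begin(), arr.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis) {
    int r = half[axis];
    if (r <= 0) continue;
    std::vector<double> kern(2 * r + 1, 1.0);
    conv1d_axis(cur, tmp, nz, ny, nx, axis, kern);
    cur.swap(tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Separable running max/min filter (rectangular structuring element).
// When pad_background is true, positions outside the volume contribute the
// worst value (-inf for max, +... 0-like for min via -inf comparison
// semantics): for a min filter this makes erosion strip foreground at the
// volume border instead of clamping the window (anti-extensive closing).
// [[Rcpp::export]]
NumericVector cpp_extreme_filter(NumericVector arr, IntegerVector dim,
                                 IntegerVector half, bool take_max,
                                 bool pad_background = false) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(arr.begin(), arr.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis) {
    int r = half[axis];
    if (r <= 0) continue;
    int len = (axis == 0) ? nz : (axis == 1 ? ny : nx);
    for (int a = 0; a < (axis == 0 ? ny : nz); ++a) {
      for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
        for (int i = 0; i < len; ++i) {
          double best = take_max ? -std::numeric_limits<double>::infinity()
                                 :  std::numeric_limits<double>::infinity();
          int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
          if (pad_background && !take_max && (i - r < 0 || i + r > len - 1))
            best = -std::numeric_limits<double>::infinity();
          for (int j = lo; j <= hi; ++j) {
            R_xlen_t idx;
            if (axis == 0)      idx = lin(j, a, b, nz, ny);
            else if (axis == 1) idx = lin(a, j, b, nz, ny);
            else                idx = lin(a, b, j, nz, ny);
            double v = cur[idx];
            if (take_max ? (v > best) : (v < best)) best = v;
          }
          R_xlen_t oidx;
          if (axis == 0)      oidx = lin(i, a, b, nz, ny);
          else if (axis == 1) oidx = lin(a, i, b, nz, ny);
          else                oidx = lin(a, b, i, nz, ny);
          tmp[oidx] = best;
        }
      }
    }
    cur.swap(tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling of a binary mask, 6- or 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  std::vector<int> dzs, dys, dxs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = lin(z, y, x, nz, ny);
        if (!mask[idx] || labels[idx] != 0) continue;
        labels[idx] = ++next;
        std::vector<std::array<int,3> > pos;
        pos.push_back({{z, y, x}});
        while (!pos.empty()) {
          std::array<int,3> p = pos.back(); pos.pop_back();
          for (size_t k = 0; k < dzs.size(); ++k) {
            int zz = p[0] + dzs[k], yy = p[1] + dys[k], xx = p[2] + dxs[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              pos.push_back({{zz, yy, xx}});
            }
          }
        }
      }
  labels.attr("n_labels") = next;
  return labels;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// physical sample spacing s.
static void dt1d(std::vector<double>& f, double s) {
  int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sint <= zb[k]) { --k; } else {
        ++k; v[k] = q; zb[k] = sint; zb[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zb[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  f.swap(d);
}

// Anisotropic Euclidean distance transform: distance (um) from each
// foreground voxel to the nearest background voxel; spacing = (z,y,x) um.
// Volume boundary is not treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> line;
  // z axis
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) line[z] = d[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[0]);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = line[z];
    }
  // y axis
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) line[y] = d[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = line[y];
    }
  // x axis
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = d[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[2]);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = line[x];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dim;
  return out;
}

struct WsNode {
  double prio;
  long long order; // FIFO tie-break for determinism
  R_xlen_t idx;
  int z, y, x, label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on priority
    return a.order > b.order;                     // then first-in first-out
  }
};

// Marker-controlled watershed by priority flooding (6-connectivity):
// seeds grow outward in order of decreasing priority (e.g. the EDT).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (seeds[i] > 0 && mask[i]) {
          labels[i] = seeds[i];
          pq.push({priority[i], counter++, i, z, y, x, seeds[i]});
        }
      }
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    for (int k = 0; k < 6; ++k) {
      int zz = nd.z + dz[k], yy = nd.y + dy[k], xx = nd.x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = lin(zz, yy, xx, nz, ny);
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = nd.label;
      pq.push({priority[j], counter++, j, zz, yy, xx, nd.label});
    }
  }
  return labels;
}

// Additively rasterize solid spheres into a volume. Centers in um
// (z,y,x columns), voxel centers at (i + 0.5) * spacing.
// [[Rcpp::export]]
NumericVector cpp_rasterize_spheres(IntegerVector dim, NumericVector spacing,
                                    NumericMatrix centers_zyx, NumericVector radii,
                                    NumericVector amplitudes) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dim;
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (int c = 0; c < centers_zyx.nrow(); ++c) {
    double cz = centers_zyx(c, 0), cy = centers_zyx(c, 1), cx = centers_zyx(c, 2);
    double r = radii[c], amp = amplitudes[c], r2 = r * r;
    int z0 = std::max(0, (int)std::ceil((cz - r) / sz - 0.5));
    int z1 = std::min(nz - 1, (int)std::floor((cz + r) / sz - 0.5));
    int y0 = std::max(0, (int)std::ceil((cy - r) / sy - 0.5));
    int y1 = std::min(ny - 1, (int)std::floor((cy + r) / sy - 0.5));
    int x0 = std::max(0, (int)std::ceil((cx - r) / sx - 0.5));
    int x1 = std::min(nx - 1, (int)std::floor((cx + r) / sx - 0.5));
    for (int x = x0; x <= x1; ++x) {
      double ddx = (x + 0.5) * sx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (y + 0.5) * sy - cy;
        for (int z = z0; z <= z1; ++z) {
          double ddz = (z + 0.5) * sz - cz;
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r2)
            out[lin(z, y, x, nz, ny)] += amp;
        }
      }
    }
  }
  return out;
}

// Per-label voxel counts, centroids (voxel index space) and per-channel sums.
// labels: integer volume; values: one channel volume; n_labels known.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, NumericVector values,
                     IntegerVector dim, int n_labels) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> cnt(n_labels, 0.0), sz(n_labels, 0.0), sy(n_labels, 0.0),
      sx(n_labels, 0.0), sv(n_labels, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        int l = labels[i];
        if (l <= 0 || l > n_labels) continue;
        cnt[l - 1] += 1.0;
        sz[l - 1] += z; sy[l - 1] += y; sx[l - 1] += x;
        sv[l - 1] += values[i];
      }
  return List::create(_["count"] = NumericVector(cnt.begin(), cnt.end()),
                      _["sum_z"] = NumericVector(sz.begin(), sz.end()),
                      _["sum_y"] = NumericVector(sy.begin(), sy.end()),
                      _["sum_x"] = NumericVector(sx.begin(), sx.end()),
                      _["sum_val"] = NumericVector(sv.begin(), sv.end()));
}

// Count voxels per label that satisfy a boolean volume (marker positivity).
// [[Rcpp::export]]
NumericVector cpp_label_true_counts(IntegerVector labels, LogicalVector flag,
                                    int n_labels) {
  std::vector<double> cnt(n_labels, 0.0);
  for (R_xlen_t i = 0; i < labels.size(); ++i) {
    int l = labels[i];
    if (l > 0 && l <= n_labels && flag[i]) cnt[l - 1] += 1.0;
  }
  return NumericVector(cnt.begin(), cnt.end());
}
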