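// Low-level 3D image operations. Volumes are numeric arrays with dim =
// (z, y, x), column-major as stored by R, so linear index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Box-window rank filters. rank = 0.5 -> median, 0 -> min, 1 -> max.
static NumericVector rank_filter3d(const NumericVector& vol, int nz, int ny,
                                   int nx, int rz, int ry, int rx,
                                   double rank) {
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x) {
    int x0 = clampi(x - rx, 0, nx - 1), x1 = clampi(x + rx, 0, nx - 1);
    for (int y = 0; y < ny; ++y) {
      int y0 = clampi(y - ry, 0, ny - 1), y1 = clampi(y + ry, 0, ny - 1);
      for (int z = 0; z < nz; ++z) {
        int z0 = clampi(z - rz, 0, nz - 1), z1 = clampi(z + rz, 0, nz - 1);
        buf.clear();
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy) {
            const double* col = &vol[0] + (size_t)nz * (yy + (size_t)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) buf.push_back(col[zz]);
          }
        size_t k = (size_t)std::floor(rank * (buf.size() - 1) + 0.5);
        std::nth_element(buf.begin(), buf.begin() + k, buf.end());
        out[z + (size_t)nz * (y + (size_t)ny * x)] = buf[k];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim, int rz,
                           int ry, int rx) {
  return rank_filter3d(vol, dim[0], dim[1], dim[2], rz, ry, rx, 0.5);
}

// [[Rcpp::export]]
NumericVector cpp_min3d(NumericVector vol, IntegerVector dim, int rz, int ry,
                        int rx) {
  return rank_filter3d(vol, dim[0], dim[1], dim[2], rz, ry, rx, 0.0);
}

// Replace a voxel by the median of a 2D disk neighbourhood in its own slice
// when it deviates from that median by more than `threshold`.
// [[Rcpp::export]]
NumericVector cpp_remove_outliers(NumericVector vol, IntegerVector dim,
                                  int radius, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  std::vector<std::pair<int, int> > offs;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) offs.push_back({dy, dx});
  std::vector<double> buf;
  buf.reserve(offs.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (auto& o : offs) {
          int yy = y + o.first, xx = x + o.second;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          buf.push_back(vol[z + (size_t)nz * (yy + (size_t)ny * xx)]);
        }
        size_t k = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + k, buf.end());
        double med = buf[k];
        size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
        if (std::fabs(vol[idx] - med) > threshold) out[idx] = med;
      }
  return out;
}

// Grayscale erosion/dilation of one 2D slice with a non-flat structuring
// element given as height offsets over disk offsets.
static void se_offsets(double radius, bool paraboloid,
                       std::vector<int>& dys, std::vector<int>& dxs,
                       std::vector<double>& hts) {
  int r = (int)std::ceil(radius);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 > radius * radius) continue;
      double h = paraboloid ? d2 / (2.0 * radius)
                            : radius - std::sqrt(radius * radius - d2);
      dys.push_back(dy);
      dxs.push_back(dx);
      hts.push_back(h);
    }
}

// Rolling-ball / sliding-paraboloid background of one slice (ny x nx,
// column-major with y fastest): grayscale opening with the ball SE.
static void rollball_slice(const double* img, double* bg, int ny, int nx,
                           double radius, bool paraboloid) {
  std::vector<int> dys, dxs;
  std::vector<double> hts;
  se_offsets(radius, paraboloid, dys, dxs, hts);
  size_t m = dys.size();
  std::vector<double> ero((size_t)ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = R_PosInf;
      for (size_t i = 0; i < m; ++i) {
        int yy = y + dys[i], xx = x + dxs[i];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double c = img[yy + (size_t)ny * xx] + hts[i];
        if (c < v) v = c;
      }
      ero[y + (size_t)ny * x] = v;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = R_NegInf;
      for (size_t i = 0; i < m; ++i) {
        int yy = y + dys[i], xx = x + dxs[i];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double c = ero[yy + (size_t)ny * xx] - hts[i];
        if (c > v) v = c;
      }
      bg[y + (size_t)ny * x] = v;
    }
}

// Per-slice rolling-ball background subtraction. For radius > 15 the
// background is estimated on a 2x-downsampled slice (mean pooling) and
// bilinearly upsampled, mirroring the standard large-radius strategy.
// [[Rcpp::export]]
NumericVector cpp_rollball_subtract(NumericVector vol, IntegerVector dim,
                                    double radius, bool paraboloid) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  bool shrink = radius > 15.0;
  int sy = shrink ? (ny + 1) / 2 : ny, sx = shrink ? (nx + 1) / 2 : nx;
  double srad = shrink ? radius / 2.0 : radius;
  std::vector<double> slice((size_t)sy * sx), bg((size_t)sy * sx);
  for (int z = 0; z < nz; ++z) {
    if (!shrink) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          slice[y + (size_t)sy * x] =
              vol[z + (size_t)nz * (y + (size_t)ny * x)];
    } else {
      for (int x = 0; x < sx; ++x)
        for (int y = 0; y < sy; ++y) {
          double s = 0;
          int n = 0;
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int yy = 2 * y + dy, xx = 2 * x + dx;
              if (yy >= ny || xx >= nx) continue;
              s += vol[z + (size_t)nz * (yy + (size_t)ny * xx)];
              ++n;
            }
          slice[y + (size_t)sy * x] = s / n;
        }
    }
    rollball_slice(slice.data(), bg.data(), sy, sx, srad, paraboloid);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double b;
        if (!shrink) {
          b = bg[y + (size_t)sy * x];
        } else {
          double fy = std::min(y / 2.0, (double)(sy - 1));
          double fx = std::min(x / 2.0, (double)(sx - 1));
          int y0 = (int)fy, x0 = (int)fx;
          int y1 = std::min(y0 + 1, sy - 1), x1 = std::min(x0 + 1, sx - 1);
          double wy = fy - y0, wx = fx - x0;
          b = (1 - wy) * (1 - wx) * bg[y0 + (size_t)sy * x0] +
              (1 - wy) * wx * bg[y0 + (size_t)sy * x1] +
              wy * (1 - wx) * bg[y1 + (size_t)sy * x0] +
              wy * wx * bg[y1 + (size_t)sy * x1];
        }
        size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
        double v = vol[idx] - b;
        out[idx] = v > 0 ? v : 0;
      }
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, kernel cut at 3 sd.
static void gauss_axis(std::vector<double>& a, int nz, int ny, int nx,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  std::vector<double> out(a.size());
  int dims[3] = {nz, ny, nx};
  size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  int n = dims[axis];
  size_t st = stride[axis];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int pos[3] = {z, y, x};
        size_t base = z + (size_t)nz * (y + (size_t)ny * x);
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int p = clampi(pos[axis] + i, 0, n - 1);
          acc += k[i + r] * a[base + (p - pos[axis]) * (long)st];
        }
        out[base] = acc;
      }
  a.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sz,
                          double sy, double sx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  gauss_axis(a, nz, ny, nx, 0, sz);
  gauss_axis(a, nz, ny, nx, 1, sy);
  gauss_axis(a, nz, ny, nx, 2, sx);
  return NumericVector(a.begin(), a.end());
}

static void neighbor_offsets(int conn, std::vector<std::array<int, 3> >& nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (conn == 6 && m != 1) continue;
        nb.push_back({dz, dy, dx});
      }
}

// Connected-component labelling of a logical mask; conn is 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int conn) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3> > nb;
  neighbor_offsets(conn, nb);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
      for (auto& o : nb) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Local maxima with ellipsoidal exclusion radii (voxels) and a noise floor.
// Returns 1-based linear indices, strongest first, after greedy suppression.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim, int rz,
                               int ry, int rx, double noise) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::pair<double, size_t> > cand;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
        double v = vol[idx];
        if (v < noise) continue;
        bool ismax = true;
        for (int dz = -rz; dz <= rz && ismax; ++dz)
          for (int dy = -ry; dy <= ry && ismax; ++dy)
            for (int dx = -rx; dx <= rx && ismax; ++dx) {
              if (!dz && !dy && !dx) continue;
              double e = (rz ? (double)dz * dz / ((double)rz * rz) : 0) +
                         (ry ? (double)dy * dy / ((double)ry * ry) : 0) +
                         (rx ? (double)dx * dx / ((double)rx * rx) : 0);
              if (e > 1.0) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              double w = vol[zz + (size_t)nz * (yy + (size_t)ny * xx)];
              if (w > v) ismax = false;
              // ties: only the lexicographically first voxel of a plateau wins
              if (w == v &&
                  (zz + (size_t)nz * (yy + (size_t)ny * xx)) < idx)
                ismax = false;
            }
        if (ismax) cand.push_back({v, idx});
      }
  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double, size_t>& a,
               const std::pair<double, size_t>& b) {
              return a.first > b.first ||
                     (a.first == b.first && a.second < b.second);
            });
  std::vector<size_t> kept;
  std::vector<int> kz, ky, kx;
  for (auto& c : cand) {
    int z = c.second % nz, y = (c.second / nz) % ny,
        x = c.second / ((size_t)nz * ny);
    bool ok = true;
    for (size_t i = 0; i < kept.size(); ++i) {
      double e = (rz ? (double)(z - kz[i]) * (z - kz[i]) / ((double)rz * rz)
                     : (z != kz[i] ? 2.0 : 0.0)) +
                 (ry ? (double)(y - ky[i]) * (y - ky[i]) / ((double)ry * ry)
                     : (y != ky[i] ? 2.0 : 0.0)) +
                 (rx ? (double)(x - kx[i]) * (x - kx[i]) / ((double)rx * rx)
                     : (x != kx[i] ? 2.0 : 0.0));
      if (e <= 1.0) {
        ok = false;
        break;
      }
    }
    if (ok) {
      kept.push_back(c.second);
      kz.push_back(z);
      ky.push_back(y);
      kx.push_back(x);
    }
  }
  IntegerVector out(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) out[i] = kept[i] + 1;
  return out;
}

// Seeded watershed by intensity-ordered region growing (6-connected):
// voxels are claimed from the brightest downwards, starting at the seeds;
// voxels below `threshold` stay background (label 0).
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector vol, IntegerVector dim,
                                   IntegerVector seed_idx,
                                   IntegerVector seed_lab, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(vol.size(), 0);
  typedef std::tuple<double, long, size_t> Node;  // (-priority via greater)
  std::priority_queue<Node> pq;
  long tick = 0;
  for (int i = 0; i < seed_idx.size(); ++i) {
    size_t idx = (size_t)seed_idx[i] - 1;
    if (vol[idx] < threshold) continue;
    lab[idx] = seed_lab[i];
    pq.push(Node(vol[idx], -(tick++), idx));
  }
  std::vector<std::array<int, 3> > nb;
  neighbor_offsets(6, nb);
  while (!pq.empty()) {
    size_t cur = std::get<2>(pq.top());
    pq.pop();
    int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
    int l = lab[cur];
    for (auto& o : nb) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
      if (lab[j] || vol[j] < threshold) continue;
      lab[j] = l;
      pq.push(Node(vol[j], -(tick++), j));
    }
  }
  return lab;
}

// Maximum pairwise Euclidean distance over rows of an n x 3 point matrix.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  double best = 0;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dz = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dx = pts(i, 2) - pts(j, 2);
      double d = dz * dz + dy * dy + dx * dx;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Gaussian product-kernel density evaluated at query points.
// [[Rcpp::export]]
NumericVector cpp_kde_eval(NumericMatrix pts, NumericMatrix query,
                           NumericVector h) {
  int n = pts.nrow(), m = query.nrow(), d = pts.ncol();
  double norm = n;
  for (int k = 0; k < d; ++k) norm *= h[k] * std::sqrt(2.0 * M_PI);
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double e = 0;
      for (int k = 0; k < d; ++k) {
        double u = (query(q, k) - pts(i, k)) / h[k];
        e += u * u;
      }
      s += std::exp(-0.5 * e);
    }
    out[q] = s / norm;
  }
  return out;
}
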