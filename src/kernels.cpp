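// Low-level 3D image kernels. Arrays are R arrays dim = c(nx, ny, nz),
// column-major: linear index i + nx*(j + ny*k), 0-based here, 1-based in R.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric boundary (edge sample repeated): ... b a | a b c ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis. boundary: 0 = reflect, 1 = zero.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& kern, int boundary) {
  int r = ((int)kern.size() - 1) / 2;
  int dims[3] = {nx, ny, nz};
  int n = dims[axis];
  long strides[3] = {1, (long)nx, (long)nx * ny};
  long stride = strides[axis];
  // iterate over all lines along `axis`
  int d1 = (axis == 0) ? 1 : 0;
  int d2 = (axis == 2) ? 1 : 2;
  for (int b = 0; b < dims[d2]; ++b) {
    for (int a = 0; a < dims[d1]; ++a) {
      long base = (long)a * strides[d1] + (long)b * strides[d2];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int src = i + t;
          double v;
          if (src < 0 || src >= n) {
            if (boundary == 0) v = in[base + (long)reflect_idx(src, n) * stride];
            else v = 0.0;
          } else v = in[base + (long)src * stride];
          acc += v * kern[t + r];
        }
        out[base + (long)i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".gaussian3d_cpp")]]
NumericVector gaussian3d_cpp(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox, int boundary) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> buf_a(vol.begin(), vol.end());
  std::vector<double> buf_b(buf_a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> kern(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += kern[t + r];
    }
    for (double& k : kern) k /= sum;
    conv_axis(buf_a, buf_b, nx, ny, nz, axis, kern, boundary);
    std::swap(buf_a, buf_b);
  }
  NumericVector out(buf_a.begin(), buf_a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale erosion / dilation with an ellipsoidal (physical ball) SE.
static NumericVector morph_ball(NumericVector vol, IntegerVector dims,
                                NumericVector r_vox, bool erode) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = (int)std::floor(r_vox[0] + 1e-9);
  int ry = (int)std::floor(r_vox[1] + 1e-9);
  int rz = (int)std::floor(r_vox[2] + 1e-9);
  std::vector<int> off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double q = 0.0;
        if (r_vox[0] > 0) q += (double)dx * dx / (r_vox[0] * r_vox[0]);
        else if (dx != 0) q = 2.0;
        if (r_vox[1] > 0) q += (double)dy * dy / (r_vox[1] * r_vox[1]);
        else if (dy != 0) q = 2.0;
        if (r_vox[2] > 0) q += (double)dz * dz / (r_vox[2] * r_vox[2]);
        else if (dz != 0) q = 2.0;
        if (q <= 1.0 + 1e-12) { off.push_back(dx); off.push_back(dy); off.push_back(dz); }
      }
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  size_t m = off.size() / 3;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double best = erode ? std::numeric_limits<double>::infinity()
                            : -std::numeric_limits<double>::infinity();
        for (size_t t = 0; t < m; ++t) {
          int ii = reflect_idx(i + off[3 * t], nx);
          int jj = reflect_idx(j + off[3 * t + 1], ny);
          int kk = reflect_idx(k + off[3 * t + 2], nz);
          double v = vol[ii + (long)nx * (jj + (long)ny * kk)];
          if (erode) { if (v < best) best = v; }
          else { if (v > best) best = v; }
        }
        out[i + (long)nx * (j + (long)ny * k)] = best;
      }
  return out;
}

// [[Rcpp::export(name = ".erode_ball_cpp")]]
NumericVector erode_ball_cpp(NumericVector vol, IntegerVector dims, NumericVector r_vox) {
  return morph_ball(vol, dims, r_vox, true);
}

// [[Rcpp::export(name = ".dilate_ball_cpp")]]
NumericVector dilate_ball_cpp(NumericVector vol, IntegerVector dims, NumericVector r_vox) {
  return morph_ball(vol, dims, r_vox, false);
}

// ---------------------------------------------------------------------------
// Morphological reconstruction by dilation (6-connectivity), hybrid algorithm.
// marker <= mask assumed.
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericVector reconstruct_cpp(NumericVector marker, NumericVector mask,
                              IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<double> J(marker.begin(), marker.end());
  const double* I = &mask[0];
  auto id = [&](int i, int j, int k) { return (long)i + (long)nx * (j + (long)ny * k); };
  // raster and anti-raster sweeps
  bool changed = true;
  int sweeps = 0;
  while (changed && sweeps < 1000) {
    changed = false; ++sweeps;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long p = id(i, j, k);
          double m = J[p];
          if (i > 0 && J[id(i - 1, j, k)] > m) m = J[id(i - 1, j, k)];
          if (j > 0 && J[id(i, j - 1, k)] > m) m = J[id(i, j - 1, k)];
          if (k > 0 && J[id(i, j, k - 1)] > m) m = J[id(i, j, k - 1)];
          if (m > I[p]) m = I[p];
          if (m > J[p]) { J[p] = m; changed = true; }
        }
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j)
        for (int i = nx - 1; i >= 0; --i) {
          long p = id(i, j, k);
          double m = J[p];
          if (i < nx - 1 && J[id(i + 1, j, k)] > m) m = J[id(i + 1, j, k)];
          if (j < ny - 1 && J[id(i, j + 1, k)] > m) m = J[id(i, j + 1, k)];
          if (k < nz - 1 && J[id(i, j, k + 1)] > m) m = J[id(i, j, k + 1)];
          if (m > I[p]) m = I[p];
          if (m > J[p]) { J[p] = m; changed = true; }
        }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Regional maxima (26-connectivity plateaus), labeled 1..n in scan order.
// [[Rcpp::export(name = ".regional_maxima_cpp")]]
IntegerVector regional_maxima_cpp(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<char> visited(n, 0);
  auto id = [&](int i, int j, int k) { return (long)i + (long)nx * (j + (long)ny * k); };
  int next_label = 0;
  std::vector<long> plateau;
  std::vector<long> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long p = id(i, j, k);
        if (visited[p]) continue;
        double v = vol[p];
        plateau.clear(); stack.clear();
        stack.push_back(p);
        visited[p] = 1;
        bool is_max = true;
        bool has_lower = false;  // a plateau must stand above something
        while (!stack.empty()) {
          long q = stack.back(); stack.pop_back();
          plateau.push_back(q);
          int qi = (int)(q % nx), qj = (int)((q / nx) % ny), qk = (int)(q / ((long)nx * ny));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int ii = qi + dx, jj = qj + dy, kk = qk + dz;
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                long r = id(ii, jj, kk);
                double w = vol[r];
                if (w > v) is_max = false;
                else if (w < v) has_lower = true;
                else if (!visited[r]) { visited[r] = 1; stack.push_back(r); }
              }
        }
        if (is_max && has_lower) {
          ++next_label;
          for (long q : plateau) lab[q] = next_label;
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed of -f restricted to mask (f > threshold),
// 6-connectivity, deterministic FIFO tie-break on equal priorities.
struct WsEntry {
  double value; long order; long voxel; int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.value != b.value) return a.value < b.value;  // max-heap on f
    return a.order > b.order;                          // FIFO on ties
  }
};

// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector f, IntegerVector dims,
                            IntegerVector seed_idx0, LogicalVector mask) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long order = 0;
  for (int s = 0; s < seed_idx0.size(); ++s) {
    long p = seed_idx0[s];
    if (p < 0 || p >= n || !mask[p]) continue;  // seed outside mask: dropped upstream
    pq.push({f[p], order++, p, s + 1});
  }
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    if (lab[e.voxel] != 0) continue;
    lab[e.voxel] = e.label;
    int i = (int)(e.voxel % nx), j = (int)((e.voxel / nx) % ny),
        k = (int)(e.voxel / ((long)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      long q = (long)ii + (long)nx * (jj + (long)ny * kk);
      if (!mask[q] || lab[q] != 0) continue;
      pq.push({f[q], order++, q, e.label});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Masked Laplace solve, 6-neighbor stencil, anisotropic spacing, SOR.
// state: 0 = outside (insulating), 1 = free, 2 = Dirichlet (value fixed).
// [[Rcpp::export(name = ".laplace_cpp")]]
List laplace_cpp(IntegerVector state, NumericVector init, IntegerVector dims,
                 NumericVector spacing, double tol, int max_iter, double omega) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<double> phi(init.begin(), init.end());
  double wx = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wz = 1.0 / (spacing[2] * spacing[2]);
  // collect free voxels
  std::vector<long> freev;
  for (long p = 0; p < n; ++p) if (state[p] == 1) freev.push_back(p);
  double resid = NA_REAL;
  int iter = 0;
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  const double W[6] = {wx, wx, wy, wy, wz, wz};
  for (iter = 1; iter <= max_iter; ++iter) {
    resid = 0.0;
    for (long p : freev) {
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((long)nx * ny));
      double num = 0.0, den = 0.0;
      for (int t = 0; t < 6; ++t) {
        int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        long q = (long)ii + (long)nx * (jj + (long)ny * kk);
        if (state[q] == 0) continue;  // insulating: neighbor dropped (zero flux)
        num += W[t] * phi[q];
        den += W[t];
      }
      if (den == 0.0) continue;
      double target = num / den;
      double upd = phi[p] + omega * (target - phi[p]);
      double r = std::fabs(target - phi[p]);
      if (r > resid) resid = r;
      phi[p] = upd;
    }
    if (resid < tol) break;
  }
  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = dims;
  return List::create(_["phi"] = out, _["iterations"] = std::min(iter, max_iter),
                      _["residual"] = resid, _["converged"] = resid < tol);
}

// ---------------------------------------------------------------------------
// Streamline tracing: Euler steps along -grad(phi) until phi < eps.
// Returns per point: path length (um), exit voxel index (0-based linear),
// status 0 = ok, 1 = left mask, 2 = step limit.
static inline double tri(const double* v, int nx, int ny, int nz,
                         double x, double y, double z) {
  // x,y,z are fractional 0-based voxel coordinates
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 < 0) i0 = 0; if (i0 > nx - 2) i0 = std::max(nx - 2, 0);
  if (j0 < 0) j0 = 0; if (j0 > ny - 2) j0 = std::max(ny - 2, 0);
  if (k0 < 0) k0 = 0; if (k0 > nz - 2) k0 = std::max(nz - 2, 0);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  fx = std::min(std::max(fx, 0.0), 1.0);
  fy = std::min(std::max(fy, 0.0), 1.0);
  fz = std::min(std::max(fz, 0.0), 1.0);
  auto at = [&](int a, int b, int c) {
    int ii = std::min(i0 + a, nx - 1), jj = std::min(j0 + b, ny - 1),
        kk = std::min(k0 + c, nz - 1);
    return v[(long)ii + (long)nx * (jj + (long)ny * kk)];
  };
  return (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
                     fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
         fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
               fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)));
}

// [[Rcpp::export(name = ".trace_streamlines_cpp")]]
List trace_streamlines_cpp(NumericVector phi, LogicalVector mask, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix start_xyz, double step_um, double eps,
                           int max_steps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = &phi[0];
  int np = start_xyz.nrow();
  NumericVector length_um(np);
  IntegerVector exit_vox(np);
  IntegerVector status(np);
  for (int c = 0; c < np; ++c) {
    double px = start_xyz(c, 0), py = start_xyz(c, 1), pz = start_xyz(c, 2);
    double len = 0.0;
    int st = 2;
    long exitp = -1;
    for (int it = 0; it < max_steps; ++it) {
      // fractional 0-based index
      double xi = (px - origin[0]) / spacing[0];
      double yi = (py - origin[1]) / spacing[1];
      double zi = (pz - origin[2]) / spacing[2];
      int oi = (int)std::floor(xi + 0.5), oj = (int)std::floor(yi + 0.5),
          ok = (int)std::floor(zi + 0.5);
      if (oi < 0 || oi >= nx || oj < 0 || oj >= ny || ok < 0 || ok >= nz) { st = 1; break; }
      long ovox = (long)oi + (long)nx * (oj + (long)ny * ok);
      if (!mask[ovox]) { st = 1; break; }
      exitp = ovox;
      double ph = tri(v, nx, ny, nz, xi, yi, zi);
      // gradient by central differences at half-voxel offsets (physical)
      double hx = 0.5 * spacing[0], hy = 0.5 * spacing[1], hz = 0.5 * spacing[2];
      double gx = (tri(v, nx, ny, nz, xi + 0.5, yi, zi) - tri(v, nx, ny, nz, xi - 0.5, yi, zi)) / (2 * hx);
      double gy = (tri(v, nx, ny, nz, xi, yi + 0.5, zi) - tri(v, nx, ny, nz, xi, yi - 0.5, zi)) / (2 * hy);
      double gz = (tri(v, nx, ny, nz, xi, yi, zi + 0.5) - tri(v, nx, ny, nz, xi, yi, zi - 0.5)) / (2 * hz);
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (ph < eps) {
        // first-order endpoint correction: remaining distance to phi = 0
        if (gn > 1e-12) len += ph / gn;
        st = 0;
        break;
      }
      if (gn < 1e-12) { st = 2; break; }
      px -= step_um * gx / gn;
      py -= step_um * gy / gn;
      pz -= step_um * gz / gn;
      len += step_um;
    }
    length_um[c] = len;
    exit_vox[c] = (int)exitp;
    status[c] = st;
  }
  return List::create(_["length_um"] = length_um, _["exit_voxel0"] = exit_vox,
                      _["status"] = status);
}

// ---------------------------------------------------------------------------
// Nearest-valid fill: extend phi a few voxels beyond the mask so gradients
// interpolate sensibly at the lateral boundary.
// [[Rcpp::export(name = ".fill_outside_cpp")]]
NumericVector fill_outside_cpp(NumericVector phi, LogicalVector valid,
                               IntegerVector dims, int rounds) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<double> cur(phi.begin(), phi.end());
  std::vector<char> ok(n);
  for (long p = 0; p < n; ++p) ok[p] = valid[p] ? 1 : 0;
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  for (int r = 0; r < rounds; ++r) {
    std::vector<double> nxt = cur;
    std::vector<char> ok2 = ok;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long p = (long)i + (long)nx * (j + (long)ny * k);
          if (ok[p]) continue;
          double s = 0.0; int c = 0;
          for (int t = 0; t < 6; ++t) {
            int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            long q = (long)ii + (long)nx * (jj + (long)ny * kk);
            if (ok[q]) { s += cur[q]; ++c; }
          }
          if (c > 0) { nxt[p] = s / c; ok2[p] = 1; }
        }
    cur.swap(nxt);
    ok.swap(ok2);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
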