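#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Map an out-of-range index into [0, n) by half-sample symmetric
// reflection: (... c b a | a b c ... | c b a ...). Loops because the
// kernel radius can exceed the axis length on small arrays.
static inline int reflect_index(int m, int n) {
  if (n == 1) return 0;
  while (m < 0 || m >= n) {
    if (m < 0) m = -m - 1;
    if (m >= n) m = 2 * n - 1 - m;
  }
  return m;
}

// Correlate a 3D array with a 1D kernel along one axis (1, 2 or 3),
// reflective borders. Kernel has odd length; out(i) = sum_t k[t] * in(i + t - R).
// With zero_dc, the response is computed against the centered line
// (sum_t k[t] * (in - in(i))), which makes derivative kernels return an
// exact 0 on constant input regardless of floating-point kernel sums.
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis, bool zero_dc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size(), R = (klen - 1) / 2;
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  NumericVector out(x.size());

  const int n = dims[axis - 1];
  // strides of the flattened column-major array
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride;
  int n1, n2; R_xlen_t s1, s2;
  if (axis == 1)      { stride = sx; n1 = ny; s1 = sy; n2 = nz; s2 = sz; }
  else if (axis == 2) { stride = sy; n1 = nx; s1 = sx; n2 = nz; s2 = sz; }
  else                { stride = sz; n1 = nx; s1 = sx; n2 = ny; s2 = sy; }

  std::vector<double> line(n);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) line[i] = x[base + i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double c0 = zero_dc ? line[i] : 0.0;
        for (int t = 0; t < klen; ++t) {
          const int m = reflect_index(i + t - R, n);
          acc += kernel[t] * (line[m] - c0);
        }
        out[base + i * stride] = acc;
      }
    }
  }
  return out;
}

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// on a grid with physical step `s`. f holds squared distances; result
// D(p) = min_q f(q) + s^2 (p - q)^2.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double sint;
    while (true) {
      const int p = v[k];
      sint = (f[q] + s2 * q * q - f[p] - s2 * p * p) / (2.0 * s2 * (q - p));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]) * s;
    d[q] = f[v[k]] + dq * dq;
  }
}

// Exact anisotropic squared EDT: squared distance (mm^2) from every voxel
// center to the nearest TRUE voxel center. All-FALSE input -> Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)j * nx + k * sxy;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)i + k * sxy;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; ++k) f[k] = g[base + k * sxy];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + k * sxy] = d[k];
    }
  return g;
}

// Eigenvalues of per-voxel symmetric 3x3 matrices, sorted by increasing
// absolute value. Analytic trigonometric solution for the characteristic
// cubic of the shifted matrix.
// [[Rcpp::export(name = ".eig3_sym_cpp")]]
NumericMatrix eig3_sym_cpp(NumericVector hxx, NumericVector hyy,
                           NumericVector hzz, NumericVector hxy,
                           NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericMatrix out(n, 3);
  const double TWOPI3 = 2.0943951023931953; // 2*pi/3
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = hxx[i], b = hyy[i], c = hzz[i];
    const double d = hxy[i], e = hxz[i], f = hyz[i];
    const double p1 = d * d + e * e + f * f;
    double l1, l2, l3;
    if (p1 == 0.0) {
      l1 = a; l2 = b; l3 = c;
    } else {
      const double q = (a + b + c) / 3.0;
      const double aa = a - q, bb = b - q, cc = c - q;
      const double p2 = aa * aa + bb * bb + cc * cc + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // r = det((A - qI)/p) / 2, clamped into [-1, 1]
      const double det = aa * (bb * cc - f * f) - d * (d * cc - f * e)
                         + e * (d * f - bb * e);
      double r = det / (2.0 * p * p * p);
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * TWOPI3);
      l2 = 3.0 * q - l1 - l3;
    }
    // sort by |lambda| ascending
    double v0 = l1, v1 = l2, v2 = l3, t;
    if (std::fabs(v0) > std::fabs(v1)) { t = v0; v0 = v1; v1 = t; }
    if (std::fabs(v1) > std::fabs(v2)) { t = v1; v1 = v2; v2 = t; }
    if (std::fabs(v0) > std::fabs(v1)) { t = v0; v0 = v1; v1 = t; }
    out(i, 0) = v0; out(i, 1) = v1; out(i, 2) = v2;
  }
  return out;
}

// 26-connected component labelling of a 3D logical array.
// Returns integer labels (0 = background); attribute "n" = component count.
// [[Rcpp::export(name = ".label_cc26_cpp")]]
IntegerVector label_cc26_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (R_xlen_t idx = 0; idx < mask.size(); ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    stack.push_back(idx);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int k = (int)(cur / sxy);
      const int j = (int)((cur - (R_xlen_t)k * sxy) / nx);
      const int i = (int)(cur - (R_xlen_t)k * sxy - (R_xlen_t)j * nx);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * sxy;
            if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("n") = next;
  return lab;
}
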