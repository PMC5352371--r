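#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// finite stand-in for "no source yet": the parabola-intersection arithmetic
// in dt1d needs finite values (INF - INF is NaN), and 1e15 dwarfs any real
// squared distance while keeping the q^2 terms representable
static const double LARGE = 1e15;

// 1D squared-distance transform (lower envelope of parabolas), sample
// locations x_i = i * w so anisotropic spacing enters exactly.
static void dt1d(const double *f, double *d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      // intersection of parabola from q with parabola from p
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (voxel centers, physical units) from every
// voxel to the nearest source voxel. Sources are voxels where mask == 0
// (background). If pad_background, a virtual one-voxel background layer
// surrounds the array, so foreground touching the border is at distance
// `spacing` from the outside.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(IntegerVector mask, IntegerVector dim, NumericVector spacing,
                     bool pad_background) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int px = pad_background ? 1 : 0;
  const int mx = nx + 2 * px, my = ny + 2 * px, mz = nz + 2 * px;
  const R_xlen_t ntot = (R_xlen_t)mx * my * mz;

  std::vector<double> g(ntot);
  // init: 0 at sources, INF elsewhere; pad layer is all source (0)
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t src = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        R_xlen_t dst = (R_xlen_t)(x + px) +
                       (R_xlen_t)mx * ((y + px) + (R_xlen_t)my * (z + px));
        g[dst] = (mask[src] != 0) ? LARGE : 0.0;
      }

  std::vector<double> buf_f(std::max(mx, std::max(my, mz)));
  std::vector<double> buf_d(buf_f.size());

  // pass along x
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y) {
      R_xlen_t base = (R_xlen_t)mx * (y + (R_xlen_t)my * z);
      for (int x = 0; x < mx; ++x) buf_f[x] = g[base + x];
      dt1d(buf_f.data(), buf_d.data(), mx, spacing[0]);
      for (int x = 0; x < mx; ++x) g[base + x] = buf_d[x];
    }
  // pass along y
  for (int z = 0; z < mz; ++z)
    for (int x = 0; x < mx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)mx * my * (R_xlen_t)z;
      for (int y = 0; y < my; ++y) buf_f[y] = g[base + (R_xlen_t)mx * y];
      dt1d(buf_f.data(), buf_d.data(), my, spacing[1]);
      for (int y = 0; y < my; ++y) g[base + (R_xlen_t)mx * y] = buf_d[y];
    }
  // pass along z
  const R_xlen_t zstride = (R_xlen_t)mx * my;
  for (int y = 0; y < my; ++y)
    for (int x = 0; x < mx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)mx * y;
      for (int z = 0; z < mz; ++z) buf_f[z] = g[base + zstride * z];
      dt1d(buf_f.data(), buf_d.data(), mz, spacing[2]);
      for (int z = 0; z < mz; ++z) g[base + zstride * z] = buf_d[z];
    }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t dst = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        R_xlen_t src = (R_xlen_t)(x + px) +
                       (R_xlen_t)mx * ((y + px) + (R_xlen_t)my * (z + px));
        out[dst] = g[src];
      }
  return out;
}

// Number of 6-connected foreground components (iterative flood fill).
// [[Rcpp::export(name = ".label_components")]]
int label_components(IntegerVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int comp = 0;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++comp;
    stack.push_back(start);
    lab[start] = comp;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] != 0 && lab[nb] == 0) {
          lab[nb] = comp;
          stack.push_back(nb);
        }
      }
    }
  }
  return comp;
}

// Smoothed-surface contraction. The binary mask is anti-aliased with a
// Gaussian of sigma = sigma_frac * spacing per axis on a 2x refined
// lattice (each voxel split into 2x2x2 fine samples carrying its binary
// value, fine spacing = spacing/2). The 0.5 level set of the smoothed
// field is the mask interface: for a flat boundary it sits midway through
// the boundary voxels wherever the lattice cuts the surface, which removes
// the half-voxel staircase bias of raw center-to-center distances. A voxel
// survives iff it is foreground and the refined Euclidean distance
// transform at its representative fine sample strictly exceeds depth_mm
// (the outside of the array counts as background). Structures about one
// voxel thin fall below the 0.5 level entirely and contract to nothing,
// as under any anti-aliased surface model.
// [[Rcpp::export(name = ".contract_smooth")]]
LogicalVector contract_smooth(IntegerVector mask, IntegerVector dim,
                              NumericVector spacing, double depth,
                              double sigma_frac) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const int m0 = 2 * n0, m1 = 2 * n1, m2 = 2 * n2;
  const R_xlen_t mtot = (R_xlen_t)m0 * m1 * m2;

  // Gaussian kernel on the fine lattice: sigma_frac voxels = 2*sigma_frac
  // fine samples; truncate at 4 sigma like standard image filters
  const double sig = 2.0 * sigma_frac;
  const int R = (int)std::ceil(4.0 * sig);
  std::vector<double> w(2 * R + 1);
  double wsum = 0;
  for (int j = -R; j <= R; ++j) {
    w[j + R] = std::exp(-(double)j * j / (2.0 * sig * sig));
    wsum += w[j + R];
  }
  for (double &x : w) x /= wsum;

  std::vector<double> a(mtot), b(mtot);
  for (int z = 0; z < m2; ++z)
    for (int y = 0; y < m1; ++y)
      for (int x = 0; x < m0; ++x) {
        R_xlen_t src = (R_xlen_t)(x / 2) +
                       (R_xlen_t)n0 * ((y / 2) + (R_xlen_t)n1 * (z / 2));
        a[(R_xlen_t)x + (R_xlen_t)m0 * (y + (R_xlen_t)m1 * z)] =
            mask[src] != 0 ? 1.0 : 0.0;
      }

  // separable convolution, zero (background) beyond the array
  // pass along x: a -> b
  for (int z = 0; z < m2; ++z)
    for (int y = 0; y < m1; ++y) {
      R_xlen_t base = (R_xlen_t)m0 * (y + (R_xlen_t)m1 * z);
      for (int x = 0; x < m0; ++x) {
        double acc = 0;
        int lo = std::max(-R, -x), hi = std::min(R, m0 - 1 - x);
        for (int j = lo; j <= hi; ++j) acc += w[j + R] * a[base + x + j];
        b[base + x] = acc;
      }
    }
  // pass along y: b -> a
  for (int z = 0; z < m2; ++z)
    for (int x = 0; x < m0; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)m0 * m1 * (R_xlen_t)z;
      for (int y = 0; y < m1; ++y) {
        double acc = 0;
        int lo = std::max(-R, -y), hi = std::min(R, m1 - 1 - y);
        for (int j = lo; j <= hi; ++j)
          acc += w[j + R] * b[base + (R_xlen_t)m0 * (y + j)];
        a[base + (R_xlen_t)m0 * y] = acc;
      }
    }
  // pass along z: a -> binary fine mask
  const R_xlen_t zstride = (R_xlen_t)m0 * m1;
  IntegerVector fine(mtot);
  for (int y = 0; y < m1; ++y)
    for (int x = 0; x < m0; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)m0 * y;
      for (int z = 0; z < m2; ++z) {
        double acc = 0;
        int lo = std::max(-R, -z), hi = std::min(R, m2 - 1 - z);
        for (int j = lo; j <= hi; ++j) acc += w[j + R] * a[base + zstride * (z + j)];
        fine[base + zstride * z] = acc >= 0.5 ? 1 : 0;
      }
    }
  a.clear(); a.shrink_to_fit();
  b.clear(); b.shrink_to_fit();

  IntegerVector mdim = IntegerVector::create(m0, m1, m2);
  NumericVector fsp = NumericVector::create(spacing[0] / 2, spacing[1] / 2,
                                            spacing[2] / 2);
  NumericVector d2 = edt_sq(fine, mdim, fsp, true);

  const double depth2 = depth * depth;
  LogicalVector keep((R_xlen_t)n0 * n1 * n2);
  for (int z = 0; z < n2; ++z)
    for (int y = 0; y < n1; ++y)
      for (int x = 0; x < n0; ++x) {
        R_xlen_t i = (R_xlen_t)x + (R_xlen_t)n0 * (y + (R_xlen_t)n1 * z);
        R_xlen_t fi = (R_xlen_t)(2 * x) +
                      (R_xlen_t)m0 * ((2 * y) + (R_xlen_t)m1 * (2 * z));
        keep[i] = mask[i] != 0 && d2[fi] > depth2;
      }
  return keep;
}
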