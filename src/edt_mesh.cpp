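#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3D,
// anisotropic voxel spacing. Seeds are voxels with seed[i] != 0; the result
// is the physical distance (mm) from every voxel to its nearest seed voxel
// centre. Separable lower-envelope-of-parabolas passes, one per axis.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  // infinite entries are queries, never parabola sources
  int first = 0;
  while (first < n && !std::isfinite(f[first])) ++first;
  if (first == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double qq = q * step;
    double s;
    while (true) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector seed, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = seed[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x (fastest-varying index)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = g[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = g[base + (R_xlen_t)z * nxy]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nxy] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isfinite(g[i]) ? std::sqrt(g[i]) : R_PosInf;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution along one axis with replicate padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector field, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kn = kernel.size();
  const int h = (kn - 1) / 2;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out(field.size());
  out.attr("dim") = dims;

  int n_axis = dims[axis - 1];
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? nx : nxy;

  // iterate over all lines along the chosen axis
  std::vector<double> line(n_axis);
  for (int z = 0; z < (axis == 3 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 2 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 1 ? 1 : nx); ++x) {
        // for axis k, loop the other two dims fully and the axis dim once
        int zmax = (axis == 3) ? nz : z + 1;
        (void)zmax;
        R_xlen_t base = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        for (int i = 0; i < n_axis; ++i) line[i] = field[base + i * stride];
        for (int i = 0; i < n_axis; ++i) {
          double acc = 0.0;
          for (int k = 0; k < kn; ++k) {
            int j = i + k - h;
            if (j < 0) j = 0;
            if (j >= n_axis) j = n_axis - 1;
            acc += line[j] * kernel[k];
          }
          out[base + i * stride] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra with linear interpolation.
// The scalar field f is sampled at voxel centres; the surface is the zero
// level set ("inside" = f > 0). Each cell (2x2x2 voxel block) is split into
// six tetrahedra sharing the main diagonal; crossings are linearly
// interpolated along tetrahedron edges. Physical spacing is honoured.
// ---------------------------------------------------------------------------

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};
// corner v of a cell: offsets ((v&1), (v>>1)&1, (v>>2)&1)

static inline double triArea(const double a[3], const double b[3], const double c[3]) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double w[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

static inline void interp(const double p1[3], const double p2[3],
                          double f1, double f2, double out[3]) {
  double t = (0.0 - f1) / (f2 - f1);
  out[0] = p1[0] + t * (p2[0] - p1[0]);
  out[1] = p1[1] + t * (p2[1] - p1[1]);
  out[2] = p1[2] + t * (p2[2] - p1[2]);
}

// [[Rcpp::export(name = ".mesh_area_cpp")]]
double mesh_area_cpp(NumericVector field, IntegerVector dims,
                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  double total = 0.0;

  double vals[8];
  double pts[8][3];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int npos = 0;
        for (int v = 0; v < 8; ++v) {
          int ox = v & 1, oy = (v >> 1) & 1, oz = (v >> 2) & 1;
          vals[v] = field[(R_xlen_t)(z + oz) * nxy + (R_xlen_t)(y + oy) * nx + (x + ox)];
          if (vals[v] > 0) ++npos;
          pts[v][0] = (x + ox) * sx;
          pts[v][1] = (y + oy) * sy;
          pts[v][2] = (z + oz) * sz;
        }
        if (npos == 0 || npos == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = TET[t];
          double fv[4];
          int inside[4], ins_n = 0;
          for (int i = 0; i < 4; ++i) {
            fv[i] = vals[tv[i]];
            if (fv[i] > 0) inside[ins_n++] = i;
          }
          if (ins_n == 0 || ins_n == 4) continue;
          if (ins_n == 1 || ins_n == 3) {
            int apex = -1;
            if (ins_n == 1) apex = inside[0];
            else { // single outside vertex
              for (int i = 0; i < 4; ++i) if (fv[i] <= 0) { apex = i; break; }
            }
            double m[3][3];
            int k = 0;
            for (int i = 0; i < 4; ++i) {
              if (i == apex) continue;
              interp(pts[tv[apex]], pts[tv[i]], fv[apex], fv[i], m[k]);
              ++k;
            }
            total += triArea(m[0], m[1], m[2]);
          } else { // 2 inside, 2 outside: quad
            int in1 = inside[0], in2 = inside[1], out1 = -1, out2 = -1;
            for (int i = 0; i < 4; ++i)
              if (fv[i] <= 0) { if (out1 < 0) out1 = i; else out2 = i; }
            double m1[3], m2[3], m3[3], m4[3];
            interp(pts[tv[in1]], pts[tv[out1]], fv[in1], fv[out1], m1);
            interp(pts[tv[in1]], pts[tv[out2]], fv[in1], fv[out2], m2);
            interp(pts[tv[in2]], pts[tv[out2]], fv[in2], fv[out2], m3);
            interp(pts[tv[in2]], pts[tv[out1]], fv[in2], fv[out1], m4);
            total += triArea(m1, m2, m3) + triArea(m1, m3, m4);
          }
        }
      }
  return total;
}
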