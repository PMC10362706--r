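#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <algorithm>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p. Ericson's region method.
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  int nx, ny, nz;
  double lo[3], h[3], hmin;
  std::vector<std::vector<int> > cells;

  int idx(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void cell_of(const double *p, int *c) const {
    for (int a = 0; a < 3; ++a) {
      double t = (p[a] - lo[a]) / h[a];
      int i = (int)std::floor(t);
      int n = (a == 0 ? nx : (a == 1 ? ny : nz));
      if (i < 0) i = 0;
      if (i >= n) i = n - 1;
      c[a] = i;
    }
  }
};

static void build_grid(const NumericMatrix &V, const IntegerMatrix &F,
                       TriGrid &g) {
  int nv = V.nrow(), nf = F.nrow();
  double hi[3];
  for (int a = 0; a < 3; ++a) { g.lo[a] = DBL_MAX; hi[a] = -DBL_MAX; }
  for (int i = 0; i < nv; ++i)
    for (int a = 0; a < 3; ++a) {
      double v = V(i, a);
      if (v < g.lo[a]) g.lo[a] = v;
      if (v > hi[a]) hi[a] = v;
    }
  double ext[3];
  for (int a = 0; a < 3; ++a) {
    ext[a] = hi[a] - g.lo[a];
    if (ext[a] <= 0) ext[a] = 1e-9;
  }
  // aim for roughly one triangle per cell, dims capped at 128
  double vol = ext[0] * ext[1] * ext[2];
  double target = std::cbrt(vol / std::max(nf, 1));
  if (target <= 0 || !R_finite(target)) target = std::max(ext[0], std::max(ext[1], ext[2]));
  int dims[3];
  for (int a = 0; a < 3; ++a) {
    int n = (int)std::ceil(ext[a] / target);
    if (n < 1) n = 1;
    if (n > 128) n = 128;
    dims[a] = n;
    g.h[a] = ext[a] / n * (1.0 + 1e-12) + 1e-300;
  }
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.hmin = std::min(g.h[0], std::min(g.h[1], g.h[2]));
  g.cells.assign((size_t)g.nx * g.ny * g.nz, std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    for (int a = 0; a < 3; ++a) { tlo[a] = DBL_MAX; thi[a] = -DBL_MAX; }
    for (int v = 0; v < 3; ++v) {
      int vi = F(f, v);
      for (int a = 0; a < 3; ++a) {
        double x = V(vi, a);
        if (x < tlo[a]) tlo[a] = x;
        if (x > thi[a]) thi[a] = x;
      }
    }
    int c0[3], c1[3];
    g.cell_of(tlo, c0);
    g.cell_of(thi, c1);
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          g.cells[g.idx(i, j, k)].push_back(f);
  }
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nq = Q.nrow();
  TriGrid g;
  build_grid(V, F, g);
  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);

  // flat per-triangle vertex cache (contiguous, avoids accessor overhead)
  int nf = F.nrow();
  std::vector<double> T(9 * (size_t)nf);
  for (int f = 0; f < nf; ++f)
    for (int v = 0; v < 3; ++v)
      for (int s = 0; s < 3; ++s)
        T[9 * (size_t)f + 3 * v + s] = V(F(f, v), s);

  for (int q = 0; q < nq; ++q) {
    double p[3] = { Q(q, 0), Q(q, 1), Q(q, 2) };
    int cq[3];
    g.cell_of(p, cq);
    double best = DBL_MAX, bestp[3] = { 0, 0, 0 };
    int bestf = -1;
    int rmax = std::max(g.nx, std::max(g.ny, g.nz));
    for (int r = 0; r <= rmax; ++r) {
      if (bestf >= 0 && best <= (double)(r - 1) * g.hmin) break;
      int i0 = std::max(0, cq[0] - r), i1 = std::min(g.nx - 1, cq[0] + r);
      int j0 = std::max(0, cq[1] - r), j1 = std::min(g.ny - 1, cq[1] + r);
      int k0 = std::max(0, cq[2] - r), k1 = std::min(g.nz - 1, cq[2] + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // only the shell at Chebyshev radius r
            int dr = std::max(std::abs(i - cq[0]),
                     std::max(std::abs(j - cq[1]), std::abs(k - cq[2])));
            if (dr != r) continue;
            const std::vector<int> &lst = g.cells[g.idx(i, j, k)];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              const double *tri = &T[9 * (size_t)f];
              double cp[3];
              closest_pt_triangle(p, tri, tri + 3, tri + 6, cp);
              double d2 = 0;
              for (int s = 0; s < 3; ++s) {
                double dd = cp[s] - p[s];
                d2 += dd * dd;
              }
              if (d2 < best * best) {
                best = std::sqrt(d2);
                bestf = f;
                bestp[0] = cp[0]; bestp[1] = cp[1]; bestp[2] = cp[2];
              }
            }
          }
    }
    P(q, 0) = bestp[0]; P(q, 1) = bestp[1]; P(q, 2) = bestp[2];
    D[q] = best;
    FI[q] = bestf + 1;  // 1-based for R
  }
  return List::create(_["point"] = P, _["dist"] = D, _["face"] = FI);
}

// Crossing-number point-in-polygon test; points exactly on an edge may land
// on either side (callers keep queries away from edges).
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericMatrix poly, NumericMatrix pts) {
  int n = poly.nrow(), m = pts.nrow();
  LogicalVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = pts(q, 0), y = pts(q, 1);
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1);
      double xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[q] = inside;
  }
  return out;
}

// Trilinear interpolation of a 3D array at continuous 0-based voxel-index
// coordinates; NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dims,
                            NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 &&
          z <= nz - 1)) {
      out[q] = NA_REAL;
      continue;
    }
    int i = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
    int j = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
    int k = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) i = 0;
    if (ny == 1) j = 0;
    if (nz == 1) k = 0;
    double fx = x - i, fy = y - j, fz = z - k;
    int i1 = std::min(i + 1, nx - 1), j1 = std::min(j + 1, ny - 1),
        k1 = std::min(k + 1, nz - 1);
#define AT(I, J, K) arr[(size_t)(K) * nx * ny + (size_t)(J) * nx + (I)]
    double c00 = AT(i, j, k) * (1 - fx) + AT(i1, j, k) * fx;
    double c10 = AT(i, j1, k) * (1 - fx) + AT(i1, j1, k) * fx;
    double c01 = AT(i, j, k1) * (1 - fx) + AT(i1, j, k1) * fx;
    double c11 = AT(i, j1, k1) * (1 - fx) + AT(i1, j1, k1) * fx;
#undef AT
    out[q] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}
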