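// Periodic scattered-data interpolation kernels for the semi-Lagrangian
// transport solver: gather (evaluate), gather-gradient (evaluate the spatial
// derivative of the interpolant) and scatter (the exact transpose of gather).
// order = 1 selects trilinear interpolation, order = 3 cubic Lagrange on the
// sliding 4-point stencil {i-1, i, i+1, i+2}. Coordinates are physical
// (radians on [0, 2pi)); arrays are in R's column-major layout, first index
// fastest. All accesses wrap periodically.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Lagrange cubic weights and their d/dt on local coordinate t in [0,1),
// stencil offsets -1, 0, 1, 2.
static inline void cubic_weights(double t, double* w) {
  w[0] = -t * (t - 1.0) * (t - 2.0) / 6.0;
  w[1] = (t + 1.0) * (t - 1.0) * (t - 2.0) / 2.0;
  w[2] = -(t + 1.0) * t * (t - 2.0) / 2.0;
  w[3] = (t + 1.0) * t * (t - 1.0) / 6.0;
}
static inline void cubic_dweights(double t, double* dw) {
  dw[0] = -(3.0 * t * t - 6.0 * t + 2.0) / 6.0;
  dw[1] = (3.0 * t * t - 4.0 * t - 1.0) / 2.0;
  dw[2] = -(3.0 * t * t - 2.0 * t - 2.0) / 2.0;
  dw[3] = (3.0 * t * t - 1.0) / 6.0;
}
static inline void linear_weights(double t, double* w) {
  w[0] = 1.0 - t;
  w[1] = t;
}
static inline void linear_dweights(double*, double* dw) {
  dw[0] = -1.0;
  dw[1] = 1.0;
}

struct Stencil {
  int base[3];     // lowest stencil index per axis (unwrapped)
  double w[3][4];  // weights per axis
  double dw[3][4]; // d(weight)/dx per axis (physical units)
  int ns;          // stencil size per axis (2 or 4)
};

static inline void make_stencil(const double* x, const int* dims, int order,
                                Stencil& s) {
  s.ns = (order == 3) ? 4 : 2;
  const double twopi = 2.0 * M_PI;
  for (int a = 0; a < 3; ++a) {
    double g = x[a] * dims[a] / twopi; // grid units
    double fl = std::floor(g);
    double t = g - fl;
    int i0 = (int)fl;
    // snap sub-1e-9-voxel offsets so node queries are exact (bitwise
    // identity of zero-velocity transport)
    if (t < 1e-9) {
      t = 0.0;
    } else if (t > 1.0 - 1e-9) {
      t = 0.0;
      i0 += 1;
    }
    double scale = dims[a] / twopi; // d(grid units)/dx
    if (order == 3) {
      s.base[a] = i0 - 1;
      cubic_weights(t, s.w[a]);
      cubic_dweights(t, s.dw[a]);
    } else {
      s.base[a] = i0;
      linear_weights(t, s.w[a]);
      linear_dweights(&t, s.dw[a]);
    }
    for (int k = 0; k < s.ns; ++k) s.dw[a][k] *= scale;
  }
}

// [[Rcpp::export]]
NumericVector ip_gather(NumericVector f, NumericMatrix pts, IntegerVector dims,
                        int order) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int d[3] = {n1, n2, n3};
  const int M = pts.nrow();
  NumericVector out(M);
  const double* fp = f.begin();
  Stencil s;
  for (int m = 0; m < M; ++m) {
    double x[3] = {pts(m, 0), pts(m, 1), pts(m, 2)};
    make_stencil(x, d, order, s);
    double acc = 0.0;
    for (int c = 0; c < s.ns; ++c) {
      int kc = wrap(s.base[2] + c, n3);
      double wc = s.w[2][c];
      for (int b = 0; b < s.ns; ++b) {
        int kb = wrap(s.base[1] + b, n2);
        double wbc = s.w[1][b] * wc;
        long off = ((long)kc * n2 + kb) * n1;
        for (int a = 0; a < s.ns; ++a) {
          int ka = wrap(s.base[0] + a, n1);
          acc += s.w[0][a] * wbc * fp[off + ka];
        }
      }
    }
    out[m] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ip_gather_grad(NumericVector f, NumericMatrix pts,
                             IntegerVector dims, int order) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int d[3] = {n1, n2, n3};
  const int M = pts.nrow();
  NumericMatrix out(M, 3);
  const double* fp = f.begin();
  Stencil s;
  for (int m = 0; m < M; ++m) {
    double x[3] = {pts(m, 0), pts(m, 1), pts(m, 2)};
    make_stencil(x, d, order, s);
    double g1 = 0.0, g2 = 0.0, g3 = 0.0;
    for (int c = 0; c < s.ns; ++c) {
      int kc = wrap(s.base[2] + c, n3);
      for (int b = 0; b < s.ns; ++b) {
        int kb = wrap(s.base[1] + b, n2);
        long off = ((long)kc * n2 + kb) * n1;
        for (int a = 0; a < s.ns; ++a) {
          int ka = wrap(s.base[0] + a, n1);
          double v = fp[off + ka];
          g1 += s.dw[0][a] * s.w[1][b] * s.w[2][c] * v;
          g2 += s.w[0][a] * s.dw[1][b] * s.w[2][c] * v;
          g3 += s.w[0][a] * s.w[1][b] * s.dw[2][c] * v;
        }
      }
    }
    out(m, 0) = g1;
    out(m, 1) = g2;
    out(m, 2) = g3;
  }
  return out;
}

// Exact transpose of ip_gather: out[j] = sum_m w_{m,j} q[m].
// [[Rcpp::export]]
NumericVector ip_scatter(NumericVector q, NumericMatrix pts,
                         IntegerVector dims, int order) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int d[3] = {n1, n2, n3};
  const int M = pts.nrow();
  NumericVector out((long)n1 * n2 * n3);
  double* op = out.begin();
  Stencil s;
  for (int m = 0; m < M; ++m) {
    double x[3] = {pts(m, 0), pts(m, 1), pts(m, 2)};
    double qm = q[m];
    if (qm == 0.0) continue;
    make_stencil(x, d, order, s);
    for (int c = 0; c < s.ns; ++c) {
      int kc = wrap(s.base[2] + c, n3);
      double wc = s.w[2][c] * qm;
      for (int b = 0; b < s.ns; ++b) {
        int kb = wrap(s.base[1] + b, n2);
        double wbc = s.w[1][b] * wc;
        long off = ((long)kc * n2 + kb) * n1;
        for (int a = 0; a < s.ns; ++a) {
          int ka = wrap(s.base[0] + a, n1);
          op[off + ka] += s.w[0][a] * wbc;
        }
      }
    }
  }
  return out;
}
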