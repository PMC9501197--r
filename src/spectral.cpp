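// Spectral regularization operators on the periodic grid, backed by FFTW
// (real-to-complex transforms, half spectrum). The velocity regularizer acts
// per Fourier mode as the symmetric matrix
//   beta_v |k|^2 I + beta_w (1 + |k|^2) k k^T,
// where |k|^2 keeps the Nyquist frequency of an even axis but the
// first-derivative factor k treats it as zero. The zero mode is unpenalized
// (apply -> 0) and passes through the inverse unchanged.
#include <Rcpp.h>
#include <fftw3.h>
#include <cmath>
using namespace Rcpp;

// R arrays are column-major with the first index fastest; FFTW is row-major,
// so we hand it the dimensions reversed and the half-length axis is n1.
struct Plans {
  int n1 = 0, n2 = 0, n3 = 0;
  fftw_plan fwd = nullptr, bwd = nullptr;
  double* real = nullptr;
  fftw_complex* cplx = nullptr;
  void ensure(int a, int b, int c) {
    if (a == n1 && b == n2 && c == n3) return;
    release();
    n1 = a; n2 = b; n3 = c;
    long nr = (long)n1 * n2 * n3;
    long ncplx = (long)(n1 / 2 + 1) * n2 * n3;
    real = fftw_alloc_real(nr);
    cplx = fftw_alloc_complex(ncplx);
    fwd = fftw_plan_dft_r2c_3d(n3, n2, n1, real, cplx, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_c2r_3d(n3, n2, n1, cplx, real, FFTW_ESTIMATE);
  }
  void release() {
    if (fwd) fftw_destroy_plan(fwd);
    if (bwd) fftw_destroy_plan(bwd);
    if (real) fftw_free(real);
    if (cplx) fftw_free(cplx);
    fwd = bwd = nullptr; real = nullptr; cplx = nullptr; n1 = n2 = n3 = 0;
  }
};
static Plans plans;

static inline double freq_full(int i, int n) {
  return (i <= n / 2) ? i : i - n;
}
static inline double freq_deriv(int i, int n) {
  if (n % 2 == 0 && i == n / 2) return 0.0;
  return freq_full(i, n);
}

// mode == 0: apply the regularization gradient; mode == 1: apply its inverse.
static NumericMatrix reg_op(NumericMatrix v, IntegerVector dims, double beta_v,
                            double beta_w, int mode) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long nr = (long)n1 * n2 * n3;
  const int h1 = n1 / 2 + 1;
  plans.ensure(n1, n2, n3);
  std::vector<double> sp(6L * h1 * n2 * n3); // re/im of 3 components
  for (int comp = 0; comp < 3; ++comp) {
    std::copy(&v(0, comp), &v(0, comp) + nr, plans.real);
    fftw_execute(plans.fwd);
    double* dst = sp.data() + 2L * comp * h1 * n2 * n3;
    std::copy((double*)plans.cplx, (double*)plans.cplx + 2L * h1 * n2 * n3, dst);
  }
  const long hstride = (long)h1 * n2 * n3;
  for (int c = 0; c < n3; ++c) {
    double k3 = freq_full(c, n3), kd3 = freq_deriv(c, n3);
    for (int b = 0; b < n2; ++b) {
      double k2 = freq_full(b, n2), kd2 = freq_deriv(b, n2);
      for (int a = 0; a < h1; ++a) {
        double k1 = a, kd1 = freq_deriv(a, n1);
        double ksq = k1 * k1 + k2 * k2 + k3 * k3;
        long idx = 2L * (((long)c * n2 + b) * h1 + a);
        double* u1 = sp.data() + idx;
        double* u2 = sp.data() + 2L * hstride + idx;
        double* u3 = sp.data() + 4L * hstride + idx;
        if (ksq == 0.0) {
          if (mode == 0) { // zero mode unpenalized
            u1[0] = u1[1] = u2[0] = u2[1] = u3[0] = u3[1] = 0.0;
          } // inverse: identity
          continue;
        }
        double av = beta_v * ksq;
        double bw = beta_w * (1.0 + ksq);
        double kdsq = kd1 * kd1 + kd2 * kd2 + kd3 * kd3;
        for (int im = 0; im < 2; ++im) {
          double kdot = kd1 * u1[im] + kd2 * u2[im] + kd3 * u3[im];
          if (mode == 0) {
            double f = bw * kdot;
            u1[im] = av * u1[im] + f * kd1;
            u2[im] = av * u2[im] + f * kd2;
            u3[im] = av * u3[im] + f * kd3;
          } else {
            double f = bw * kdot / (av + bw * kdsq);
            u1[im] = (u1[im] - f * kd1) / av;
            u2[im] = (u2[im] - f * kd2) / av;
            u3[im] = (u3[im] - f * kd3) / av;
          }
        }
      }
    }
  }
  NumericMatrix out(nr, 3);
  const double scale = 1.0 / nr;
  for (int comp = 0; comp < 3; ++comp) {
    double* src = sp.data() + 2L * comp * hstride;
    std::copy(src, src + 2L * hstride, (double*)plans.cplx);
    fftw_execute(plans.bwd);
    double* o = &out(0, comp);
    for (long i = 0; i < nr; ++i) o[i] = plans.real[i] * scale;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix spec_reg_apply(NumericMatrix v, IntegerVector dims,
                             double beta_v, double beta_w) {
  return reg_op(v, dims, beta_v, beta_w, 0);
}

// [[Rcpp::export]]
NumericMatrix spec_reg_invert(NumericMatrix b, IntegerVector dims,
                              double beta_v, double beta_w) {
  return reg_op(b, dims, beta_v, beta_w, 1);
}

// Quadratic forms of the two regularizers (Parseval):
//   S_v = (1/N) sum_k |k|^2 |vhat|^2,
//   S_w = (1/N) sum_k (1 + |k|^2) |k . vhat|^2,
// so that reg_v = (beta_v/2) S_v voxvol and reg_w = (beta_w/2) S_w voxvol.
// [[Rcpp::export]]
NumericVector spec_reg_energies(NumericMatrix v, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long nr = (long)n1 * n2 * n3;
  const int h1 = n1 / 2 + 1;
  plans.ensure(n1, n2, n3);
  std::vector<double> sp(6L * h1 * n2 * n3);
  const long hstride = (long)h1 * n2 * n3;
  for (int comp = 0; comp < 3; ++comp) {
    std::copy(&v(0, comp), &v(0, comp) + nr, plans.real);
    fftw_execute(plans.fwd);
    std::copy((double*)plans.cplx, (double*)plans.cplx + 2L * hstride,
              sp.data() + 2L * comp * hstride);
  }
  double sv = 0.0, sw = 0.0;
  for (int c = 0; c < n3; ++c) {
    double k3 = freq_full(c, n3), kd3 = freq_deriv(c, n3);
    for (int b = 0; b < n2; ++b) {
      double k2 = freq_full(b, n2), kd2 = freq_deriv(b, n2);
      for (int a = 0; a < h1; ++a) {
        double kd1 = freq_deriv(a, n1);
        double ksq = (double)a * a + k2 * k2 + k3 * k3;
        // half-spectrum weight: interior a counts its conjugate too
        double w = (a == 0 || (n1 % 2 == 0 && a == n1 / 2)) ? 1.0 : 2.0;
        long idx = 2L * (((long)c * n2 + b) * h1 + a);
        double* u1 = sp.data() + idx;
        double* u2 = sp.data() + 2L * hstride + idx;
        double* u3 = sp.data() + 4L * hstride + idx;
        double vsq = u1[0] * u1[0] + u1[1] * u1[1] + u2[0] * u2[0] +
                     u2[1] * u2[1] + u3[0] * u3[0] + u3[1] * u3[1];
        double kre = kd1 * u1[0] + kd2 * u2[0] + kd3 * u3[0];
        double kim = kd1 * u1[1] + kd2 * u2[1] + kd3 * u3[1];
        sv += w * ksq * vsq;
        sw += w * (1.0 + ksq) * (kre * kre + kim * kim);
      }
    }
  }
  const double scale = 1.0 / (double)nr; // Parseval, unnormalized forward fft
  return NumericVector::create(sv * scale, sw * scale);
}
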