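// Hot kernels of the 1-D convolution layers: patch extraction (im2col) and
// its adjoint scatter-add (col2im). Layout matches the R engine: batched
// arrays are (n, L, C) column-major; the patch matrix is (n*L) x (k*C) with
// row (i, t) = i + t*n and column (j, c) = j*C + c. "Same" padding with
// pad_left = floor((k - 1) / 2), cross-correlation convention.

#include <Rcpp.h>
#include <dlfcn.h>
using namespace Rcpp;

// Pin the BLAS thread pool if the running BLAS exposes the OpenBLAS
// control symbol. Training consists of many small matrix products; a
// multi-threaded pool oversubscribes a single core and slows them down,
// and single-threaded reductions are bit-reproducible.
// [[Rcpp::export]]
bool set_blas_threads(int n) {
  typedef void (*fn_t)(int);
  fn_t f = (fn_t) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == NULL) return false;
  f(n);
  return true;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int n, int L, int C, int k) {
  const int pl = (k - 1) / 2;
  NumericMatrix out(n * L, k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n * L;
    for (int j = 0; j < k; ++j) {
      double* o = &out(0, j * C + c);
      for (int t = 0; t < L; ++t) {
        const int src = t + j - pl;
        double* od = o + (size_t)t * n;
        if (src < 0 || src >= L) {
          std::fill(od, od + n, 0.0);
        } else {
          const double* xs = xc + (size_t)src * n;
          std::copy(xs, xs + n, od);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, int n, int L, int C, int k) {
  const int pl = (k - 1) / 2;
  NumericVector dx((size_t)n * L * C);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + (size_t)c * n * L;
    for (int j = 0; j < k; ++j) {
      const double* dcj = &dcol(0, j * C + c);
      for (int t = 0; t < L; ++t) {
        const int dst = t + j - pl;
        if (dst < 0 || dst >= L) continue;
        double* dd = dxc + (size_t)dst * n;
        const double* ds = dcj + (size_t)t * n;
        for (int i = 0; i < n; ++i) dd[i] += ds[i];
      }
    }
  }
  dx.attr("dim") = Dimension(n, L, C);
  return dx;
}
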