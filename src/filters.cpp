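#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zero-phase (forward-backward) IIR filtering down each column with
// odd-reflection padding of length pad and steady-state initial
// conditions zi (per unit input).  Works column-at-a-time to avoid
// allocating padded copies of the whole matrix.
// [[Rcpp::export]]
NumericMatrix zerophase_filter_cols(const NumericMatrix& x,
                                    const NumericVector& b,
                                    const NumericVector& a,
                                    const NumericVector& zi, const int pad) {
  const int n = x.nrow(), m = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  if (zi.size() != nz) stop("zi must have max(length(b), length(a)) - 1 states");
  const int p = std::min(pad, n - 1);
  const int N = n + 2 * p;
  NumericMatrix y(n, m);
  std::vector<double> ext(N), z(nz + 1);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int k = 0; k < nb; ++k) bb[k] = b[k];
  for (int k = 0; k < na; ++k) aa[k] = a[k];
  for (int j = 0; j < m; ++j) {
    const double* xj = &x(0, j);
    for (int i = 0; i < p; ++i) ext[i] = 2.0 * xj[0] - xj[p - i];
    for (int i = 0; i < n; ++i) ext[p + i] = xj[i];
    for (int i = 0; i < p; ++i) ext[p + n + i] = 2.0 * xj[n - 1] - xj[n - 2 - i];
    // forward
    for (int k = 0; k < nz; ++k) z[k] = zi[k] * ext[0];
    z[nz] = 0.0;
    for (int i = 0; i < N; ++i) {
      const double xi = ext[i];
      const double yi = bb[0] * xi + z[0];
      for (int k = 0; k < nz; ++k) z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      ext[i] = yi;
    }
    // backward
    for (int k = 0; k < nz; ++k) z[k] = zi[k] * ext[N - 1];
    z[nz] = 0.0;
    for (int i = N - 1; i >= 0; --i) {
      const double xi = ext[i];
      const double yi = bb[0] * xi + z[0];
      for (int k = 0; k < nz; ++k) z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      ext[i] = yi;
    }
    double* yj = &y(0, j);
    for (int i = 0; i < n; ++i) yj[i] = ext[p + i];
  }
  return y;
}

// Causal IIR filter applied down each column (direct form II transposed).
// a must be normalized so a[0] == 1.  zi holds per-unit initial filter
// states; the state is initialized to zi * x(0, j) per column, which gives
// steady-state behaviour for a constant input and suppresses start-up
// transients (pass zeros for classic zero initial conditions).
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(const NumericMatrix& x, const NumericVector& b,
                              const NumericVector& a,
                              const NumericVector& zi) {
  const int n = x.nrow(), m = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  if (zi.size() != nz) stop("zi must have max(length(b), length(a)) - 1 states");
  NumericMatrix y(n, m);
  std::vector<double> z(nz + 1);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int k = 0; k < nb; ++k) bb[k] = b[k];
  for (int k = 0; k < na; ++k) aa[k] = a[k];
  for (int j = 0; j < m; ++j) {
    const double* xj = &x(0, j);
    double* yj = &y(0, j);
    const double x0 = xj[0];
    for (int k = 0; k < nz; ++k) z[k] = zi[k] * x0;
    z[nz] = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = xj[i];
      const double yi = bb[0] * xi + z[0];
      for (int k = 0; k < nz; ++k) {
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      }
      yj[i] = yi;
    }
  }
  return y;
}
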