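#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steady-state initial conditions for a direct-form-II-transposed IIR filter,
// so that filtering a constant input x0 from state zi * x0 produces no
// start-up transient. Solves (I - A) zi = B where A is the transposed
// companion matrix of a and B = b[1:] - a[1:] * b[0].
static std::vector<double> lfilter_zi(const std::vector<double> &b,
                                      const std::vector<double> &a) {
  int n = (int)std::max(a.size(), b.size());
  int m = n - 1;
  std::vector<double> bb(b), aa(a);
  bb.resize(n, 0.0);
  aa.resize(n, 0.0);
  // normalise a[0] = 1
  for (int i = n - 1; i >= 0; --i) {
    bb[i] /= aa[0] == 0 ? 1.0 : aa[0];
  }
  for (int i = n - 1; i >= 0; --i) {
    aa[i] /= aa[0] == 0 ? 1.0 : aa[0];
  }
  // M = I - companion(a)^T ; companion first row = -a[1:], subdiagonal = 1
  std::vector<double> M(m * m, 0.0), rhs(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      double comp_ji = 0.0; // companion(a)[j][i]
      if (j == 0)
        comp_ji = -aa[i + 1];
      else if (j == i + 1)
        comp_ji = 1.0;
      M[i * m + j] = (i == j ? 1.0 : 0.0) - comp_ji;
    }
    rhs[i] = bb[i + 1] - aa[i + 1] * bb[0];
  }
  // Gaussian elimination with partial pivoting (m <= 16)
  for (int k = 0; k < m; ++k) {
    int piv = k;
    for (int r = k + 1; r < m; ++r)
      if (std::fabs(M[r * m + k]) > std::fabs(M[piv * m + k])) piv = r;
    if (piv != k) {
      for (int c = 0; c < m; ++c) std::swap(M[k * m + c], M[piv * m + c]);
      std::swap(rhs[k], rhs[piv]);
    }
    double d = M[k * m + k];
    for (int r = k + 1; r < m; ++r) {
      double f = M[r * m + k] / d;
      for (int c = k; c < m; ++c) M[r * m + c] -= f * M[k * m + c];
      rhs[r] -= f * rhs[k];
    }
  }
  std::vector<double> zi(m);
  for (int k = m - 1; k >= 0; --k) {
    double s = rhs[k];
    for (int c = k + 1; c < m; ++c) s -= M[k * m + c] * zi[c];
    zi[k] = s / M[k * m + k];
  }
  return zi;
}

// One forward pass, direct form II transposed, state z (modified in place).
static void lfilter(const std::vector<double> &b, const std::vector<double> &a,
                    const std::vector<double> &x, std::vector<double> &y,
                    std::vector<double> &z) {
  int n = (int)std::max(a.size(), b.size());
  std::vector<double> bb(b), aa(a);
  bb.resize(n, 0.0);
  aa.resize(n, 0.0);
  int m = n - 1;
  size_t N = x.size();
  y.resize(N);
  for (size_t i = 0; i < N; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (m > 0) z[m - 1] = bb[m] * xi - aa[m] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of each column of x, with odd
// reflection padding of length 3*(order) at both ends and steady-state
// initial conditions, matching the standard filtfilt scheme.
// [[Rcpp::export]]
NumericMatrix zerophase_filter_cpp(NumericVector b, NumericVector a,
                                   NumericMatrix x) {
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  double a0 = av[0];
  for (size_t i = 0; i < bv.size(); ++i) bv[i] /= a0;
  for (size_t i = 0; i < av.size(); ++i) av[i] /= a0;
  int n = (int)std::max(av.size(), bv.size());
  int pad = 3 * (n - 1);
  int N = x.nrow(), C = x.ncol();
  if (N <= pad)
    stop("signal too short for zero-phase filtering (need > %d samples)", pad);
  std::vector<double> zi = lfilter_zi(bv, av);
  int m = n - 1;
  NumericMatrix out(N, C);
  std::vector<double> ext(N + 2 * pad), y, z(m);
  for (int c = 0; c < C; ++c) {
    // odd extension: 2*x[0] - x[pad..1], x, 2*x[N-1] - x[N-2..N-1-pad]
    for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x(0, c) - x(pad - i, c);
    for (int i = 0; i < N; ++i) ext[pad + i] = x(i, c);
    for (int i = 0; i < pad; ++i)
      ext[pad + N + i] = 2.0 * x(N - 1, c) - x(N - 2 - i, c);
    // forward
    for (int k = 0; k < m; ++k) z[k] = zi[k] * ext[0];
    lfilter(bv, av, ext, y, z);
    // backward
    std::reverse(y.begin(), y.end());
    for (int k = 0; k < m; ++k) z[k] = zi[k] * y[0];
    std::vector<double> y2;
    lfilter(bv, av, y, y2, z);
    std::reverse(y2.begin(), y2.end());
    for (int i = 0; i < N; ++i) out(i, c) = y2[pad + i];
  }
  return out;
}
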