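#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Discrete prolate spheroidal (Slepian) sequences via the symmetric
// tridiagonal formulation (Percival & Walden 1993, ch. 8):
//   diag[i]    = ((N - 1 - 2i)/2)^2 * cos(2*pi*W),   i = 0..N-1
//   offdiag[i] = (i+1) * (N - 1 - i) / 2,            i = 0..N-2
// The K most concentrated tapers are the eigenvectors belonging to the K
// largest eigenvalues.  Only those K pairs are needed, so we use Sturm
// bisection for the eigenvalues and inverse iteration for the vectors;
// this stays O(K * N) per taper and handles the long (N ~ 10^4) windows
// used for multi-second LFP epochs without forming a dense matrix.

// Number of eigenvalues of the tridiagonal matrix strictly less than x.
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  const int n = (int)d.size();
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    double denom = q;
    if (denom == 0.0) denom = 1e-300;
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// Solve (T - shift I) x = b for tridiagonal T by Gaussian elimination with
// partial pivoting (robust when the shift is nearly an eigenvalue).
static void tridiag_shift_solve(const std::vector<double>& d,
                                const std::vector<double>& e, double shift,
                                std::vector<double>& b) {
  const int n = (int)d.size();
  std::vector<double> a(n), c0(n - 1), c1(n > 1 ? n - 1 : 0), c2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - shift;
  for (int i = 0; i < n - 1; ++i) { c0[i] = e[i]; c1[i] = e[i]; }
  for (int i = 0; i + 2 < n; ++i) c2[i] = 0.0;
  // forward elimination; c0 = subdiagonal, c1 = superdiag, c2 = 2nd superdiag
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(c0[i]) > std::fabs(a[i])) {
      std::swap(a[i], c0[i]);
      std::swap(c1[i], a[i + 1]);
      if (i + 2 < n) std::swap(c2[i], c1[i + 1]);
      std::swap(b[i], b[i + 1]);
    }
    double piv = a[i];
    if (piv == 0.0) piv = 1e-300;
    double m = c0[i] / piv;
    a[i + 1] -= m * c1[i];
    if (i + 2 < n) c1[i + 1] -= m * c2[i];
    b[i + 1] -= m * b[i];
    c0[i] = m;  // keep multiplier slot occupied (unused afterwards)
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= c1[i] * b[i + 1];
    if (i + 2 < n) s -= c2[i] * b[i + 2];
    double piv = a[i];
    if (piv == 0.0) piv = 1e-300;
    b[i] = s / piv;
  }
}

// [[Rcpp::export(name = ".dpss_tapers_cpp")]]
NumericMatrix dpss_tapers_cpp(int n, double nw, int k) {
  if (n < 2) stop("taper length must be at least 2");
  if (k < 1 || k > n) stop("number of tapers out of range");
  const double w = nw / (double)n;
  if (w <= 0 || w >= 0.5) stop("time-bandwidth product out of range");

  std::vector<double> d(n), e(n - 1);
  const double c = std::cos(2.0 * M_PI * w);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 0; i < n - 1; ++i) e[i] = (i + 1) * (n - 1.0 - i) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < n - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  const double scale = std::max(std::fabs(lo), std::fabs(hi));

  NumericMatrix tapers(n, k);
  std::vector<double> prev;  // previously found vectors for re-orthogonalization
  std::vector<std::vector<double> > found(k);

  for (int j = 0; j < k; ++j) {
    // j-th largest eigenvalue: exactly n-1-j eigenvalues strictly below it
    int target = n - 1 - j;
    double a = lo, b = hi;
    for (int it = 0; it < 200 && (b - a) > 1e-14 * scale; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) > target) b = mid; else a = mid;
    }
    double lambda = 0.5 * (a + b);

    // inverse iteration
    std::vector<double> v(n);
    // deterministic pseudo-random start
    unsigned int st = 12345u + 7919u * (unsigned int)j;
    for (int i = 0; i < n; ++i) {
      st = st * 1103515245u + 12345u;
      v[i] = ((st >> 16) & 0x7fff) / 32767.5 - 1.0;
    }
    for (int iter = 0; iter < 6; ++iter) {
      tridiag_shift_solve(d, e, lambda, v);
      // orthogonalize against previously found eigenvectors
      for (int m = 0; m < j; ++m) {
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += v[i] * found[m][i];
        for (int i = 0; i < n; ++i) v[i] -= dot * found[m][i];
      }
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0.0) { v[0] = 1.0; nrm = 1.0; }
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }

    // polarity convention: symmetric tapers (even j) have positive mean;
    // antisymmetric tapers (odd j) start with a positive lobe
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += v[i];
    bool flip;
    if (j % 2 == 0) {
      flip = mean < 0;
    } else {
      double s = 0.0;
      for (int i = 0; i < n / 2 && s == 0.0; ++i) s = v[i];
      flip = s < 0;
    }
    if (flip) for (int i = 0; i < n; ++i) v[i] = -v[i];

    found[j] = v;
    for (int i = 0; i < n; ++i) tapers(i, j) = v[i];
  }
  return tapers;
}
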