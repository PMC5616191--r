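#include <Rcpp.h>
using namespace Rcpp;

// Drive a vector autoregression with precomputed innovations.
// coeffs: [order x p x p] array, coeffs(k, i, j) multiplies channel j at lag
// (k+1)*lag_step when updating channel i.  innov: [(burn + n) x p].  The
// first `burn` rows are discarded.  Innovations are generated in R so the
// realization is reproducible under R's RNG.

// [[Rcpp::export(name = ".simulate_var_cpp")]]
NumericMatrix simulate_var_cpp(NumericVector coeffs, int order, int p,
                               NumericMatrix innov, int lag_step, int burn) {
  const int total = innov.nrow();
  if (innov.ncol() != p) stop("innovation matrix has wrong width");
  const int maxlag = order * lag_step;
  NumericMatrix x(total, p);
  for (int t = 0; t < total; ++t) {
    for (int i = 0; i < p; ++i) {
      double acc = innov(t, i);
      for (int k = 0; k < order; ++k) {
        int lag = (k + 1) * lag_step;
        if (t - lag < 0) continue;
        for (int j = 0; j < p; ++j) {
          double a = coeffs[k + order * (i + p * j)];
          if (a != 0.0) acc += a * x(t - lag, j);
        }
      }
      x(t, i) = acc;
    }
    (void)maxlag;
  }
  const int n = total - burn;
  NumericMatrix out(n, p);
  for (int t = 0; t < n; ++t)
    for (int i = 0; i < p; ++i) out(t, i) = x(t + burn, i);
  return out;
}
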