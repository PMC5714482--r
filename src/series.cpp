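#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Power-series primitives used by every mutant-count distribution.  All series
// are stored as coefficient vectors c_0..c_N (constant term first) and all
// operations are exact truncations: entry n of the result depends only on
// entries 0..n of the inputs, so extending the order never changes a prefix.
// Hot loops run on raw pointers; these recursions are quadratic in the
// truncation order and dominate the cost of every likelihood evaluation.

// exp of a power series: the compound-Poisson (Ma-Sandri-Sarkar) recursion
// p_0 = exp(c_0), p_n = (1/n) sum_{j=1}^{n} j c_j p_{n-j}.
// [[Rcpp::export]]
NumericVector series_exp_cpp(NumericVector cf) {
  const R_xlen_t N = cf.size() - 1;
  NumericVector out(N + 1);
  double* p = out.begin();
  const double* c = cf.begin();
  std::vector<double> jc(N + 1);
  for (R_xlen_t j = 1; j <= N; ++j) jc[j] = j * c[j];
  p[0] = std::exp(c[0]);
  for (R_xlen_t n = 1; n <= N; ++n) {
    double acc = 0.0;
    const double* a = jc.data() + 1;
    const double* b = p + n - 1;
    for (R_xlen_t j = 0; j < n; ++j) acc += a[j] * b[-j];
    p[n] = acc / n;
  }
  return out;
}

// log of a power series with positive constant term:
// s_0 = log v_0, s_n = v_n/v_0 - (1/(n v_0)) sum_{j=1}^{n-1} j s_j v_{n-j}.
// [[Rcpp::export]]
NumericVector series_log_cpp(NumericVector v) {
  const R_xlen_t N = v.size() - 1;
  if (v[0] <= 0) stop("series log requires a positive constant term");
  NumericVector out(N + 1);
  double* s = out.begin();
  const double* vv = v.begin();
  std::vector<double> js(N + 1, 0.0);
  s[0] = std::log(vv[0]);
  for (R_xlen_t n = 1; n <= N; ++n) {
    double acc = 0.0;
    const double* a = js.data() + 1;
    const double* b = vv + n - 1;
    for (R_xlen_t j = 0; j < n - 1; ++j) acc += a[j] * b[-j];
    s[n] = vv[n] / vv[0] - acc / (n * vv[0]);
    js[n] = n * s[n];
  }
  return out;
}

// truncated quotient a/b (b_0 != 0)
// [[Rcpp::export]]
NumericVector series_div_cpp(NumericVector a, NumericVector b) {
  const R_xlen_t N = a.size() - 1;
  if (b[0] == 0) stop("series division by a series with zero constant term");
  NumericVector out(N + 1);
  double* d = out.begin();
  const double* aa = a.begin();
  const double* bb = b.begin();
  d[0] = aa[0] / bb[0];
  for (R_xlen_t n = 1; n <= N; ++n) {
    double acc = aa[n];
    const double* x = d;
    const double* y = bb + n;
    for (R_xlen_t j = 0; j < n; ++j) acc -= x[j] * y[-j];
    d[n] = acc / bb[0];
  }
  return out;
}

// truncated Cauchy product (same truncation order as the inputs)
// [[Rcpp::export]]
NumericVector series_mul_cpp(NumericVector a, NumericVector b) {
  const R_xlen_t N = a.size() - 1;
  NumericVector out(N + 1);
  double* z = out.begin();
  const double* aa = a.begin();
  const double* bb = b.begin();
  for (R_xlen_t n = 0; n <= N; ++n) {
    double acc = 0.0;
    const double* y = bb + n;
    for (R_xlen_t j = 0; j <= n; ++j) acc += aa[j] * y[-j];
    z[n] = acc;
  }
  return out;
}

// geometric-division recursion for the plating unit series:
// d_0 = b_0, d_k = b_k - xi d_{k-1}  (division by 1 + xi z)
// [[Rcpp::export]]
NumericVector geom_div_cpp(NumericVector b, double xi) {
  const R_xlen_t N = b.size() - 1;
  NumericVector out(N + 1);
  double* d = out.begin();
  const double* bb = b.begin();
  d[0] = bb[0];
  for (R_xlen_t k = 1; k <= N; ++k) d[k] = bb[k] - xi * d[k - 1];
  return out;
}
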