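#include <Rcpp.h>
using namespace Rcpp;

// Central moment sums in one pass with long-double (extended precision)
// accumulation, so results are permutation-invariant at the tested
// tolerance.  Returns c(mean, m2, m3, m4) with m_k the k-th central sample
// moment (divided by n).
// [[Rcpp::export(name = ".central_moments")]]
NumericVector central_moments(NumericVector v) {
  const R_xlen_t n = v.size();
  if (n < 1) stop("empty vector");
  long double s = 0.0L;
  for (R_xlen_t i = 0; i < n; ++i) s += v[i];
  const long double mu = s / n;
  long double s2 = 0.0L, s3 = 0.0L, s4 = 0.0L;
  for (R_xlen_t i = 0; i < n; ++i) {
    const long double d = v[i] - mu;
    const long double d2 = d * d;
    s2 += d2;
    s3 += d2 * d;
    s4 += d2 * d2;
  }
  return NumericVector::create((double)mu, (double)(s2 / n),
                               (double)(s3 / n), (double)(s4 / n));
}
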