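#include <Rcpp.h>
using namespace Rcpp;

// Sliding log-odds sums of a 4 x w score matrix over an integer-coded
// sequence (1..4 = A,C,G,T; 0 = other/N). Windows containing a 0 code
// yield NA. Returns one score per window start (length n - w + 1).
// [[Rcpp::export]]
NumericVector cpp_pwm_scores(IntegerVector codes, NumericMatrix mat) {
  const int n = codes.size();
  const int w = mat.ncol();
  if (n < w) return NumericVector(0);
  const int m = n - w + 1;
  NumericVector out(m);
  double *o = REAL(out);
  const int *cd = INTEGER(codes);
  const double nan = R_NaN;
  // column-major accumulation with a 5-entry lookup (code 0 -> NaN)
  for (int j = 0; j < w; ++j) {
    double sc[5] = {nan, mat(0, j), mat(1, j), mat(2, j), mat(3, j)};
    const int *c = cd + j;
    for (int i = 0; i < m; ++i)
      o[i] += sc[c[i]];
  }
  for (int i = 0; i < m; ++i)
    if (ISNAN(o[i])) o[i] = NA_REAL;
  return out;
}

// Per-query maximum of vals over inclusive 1-based index ranges [lo, hi].
// Empty or out-of-range queries yield NA.
// [[Rcpp::export]]
NumericVector cpp_window_max(NumericVector vals, IntegerVector lo,
                             IntegerVector hi) {
  const int n = vals.size(), q = lo.size();
  NumericVector out(q);
  for (int k = 0; k < q; ++k) {
    int a = lo[k] < 1 ? 1 : lo[k];
    int b = hi[k] > n ? n : hi[k];
    if (a > b) { out[k] = NA_REAL; continue; }
    double m = vals[a - 1];
    for (int i = a; i < b; ++i)
      if (vals[i] > m) m = vals[i];
    out[k] = m;
  }
  return out;
}

// Maximum of sc per group, where grp is sorted ascending (1-based group
// ids) as returned by findOverlaps; out has length ngroups, NA for
// groups with no entries.
// [[Rcpp::export]]
NumericVector cpp_group_max(IntegerVector grp, NumericVector sc,
                            int ngroups) {
  NumericVector out(ngroups, NA_REAL);
  const int n = grp.size();
  for (int i = 0; i < n; ++i) {
    const int g = grp[i] - 1;
    if (ISNAN(out[g]) || sc[i] > out[g]) out[g] = sc[i];
  }
  return out;
}
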