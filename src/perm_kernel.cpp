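#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the mean within-patient rank correlation.
//
// rx, ry: per-patient centered unit-norm midrank vectors of equal length.
// Each iteration independently permutes every patient's ry (permuting the
// covariate series permutes its midranks) and records the mean, over
// patients, of dot(rx, ry[perm]) — i.e. the mean Spearman rho under the
// within-patient exchangeability null. Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericVector perm_mean_rho(List rx, List ry, int n_perm) {
  const int m = rx.size();
  if (ry.size() != m) stop("rank lists differ in length");
  std::vector<NumericVector> X(m), Y(m);
  for (int i = 0; i < m; ++i) {
    X[i] = as<NumericVector>(rx[i]);
    Y[i] = as<NumericVector>(ry[i]);
    if (X[i].size() != Y[i].size()) stop("rank vectors differ in length");
  }
  NumericVector out(n_perm);
  for (int b = 0; b < n_perm; ++b) {
    double tot = 0.0;
    for (int i = 0; i < m; ++i) {
      const int n = X[i].size();
      IntegerVector perm = sample(n, n, false);  // 1-based
      double d = 0.0;
      for (int j = 0; j < n; ++j) d += X[i][j] * Y[i][perm[j] - 1];
      tot += d;
    }
    out[b] = tot / m;
  }
  return out;
}
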