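#include <Rcpp.h>
using namespace Rcpp;

// Greedy 1-D clustering of a sorted m/z vector with a ppm gap criterion.
// A new channel starts whenever the next m/z lies more than tol_ppm away
// from the running intensity-weighted centroid of the current channel.
// Input must be sorted ascending; returns 1-based channel ids.
// [[Rcpp::export]]
IntegerVector greedy_cluster_ppm(NumericVector mz, NumericVector intensity,
                                 double tol_ppm) {
  const R_xlen_t n = mz.size();
  IntegerVector id(n);
  if (n == 0) return id;
  int channel = 1;
  double wsum = intensity[0] > 0 ? intensity[0] : 1e-300;
  double centroid = mz[0];
  id[0] = 1;
  for (R_xlen_t i = 1; i < n; ++i) {
    const double gap = 1e6 * (mz[i] - centroid) / centroid;
    if (gap > tol_ppm) {
      ++channel;
      wsum = intensity[i] > 0 ? intensity[i] : 1e-300;
      centroid = mz[i];
    } else {
      const double w = intensity[i] > 0 ? intensity[i] : 1e-300;
      centroid = (centroid * wsum + mz[i] * w) / (wsum + w);
      wsum += w;
    }
    id[i] = channel;
  }
  return id;
}
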