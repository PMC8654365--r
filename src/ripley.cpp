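#include <Rcpp.h>
using namespace Rcpp;

// Weighted cumulative cross-pair counts for the bivariate Ripley K:
// for each radius r[k], the sum of edge-correction weights e_ij over all
// cross-species pairs with d(x_i, y_j) <= r[k]. Translational correction on
// a rectangular window wx * wy: e_ij = (wx * wy) / ((wx - |dx|) (wy - |dy|)).
// correct = false drops the weights (e_ij = 1).
// [[Rcpp::export]]
NumericVector ripley_crosscount_cpp(NumericVector x1, NumericVector y1,
                                    NumericVector x2, NumericVector y2,
                                    double wx, double wy,
                                    NumericVector r, bool correct = true) {
  int n1 = x1.size(), n2 = x2.size(), nr = r.size();
  std::vector<double> hist(nr, 0.0);
  double rmax = r[nr - 1], rmax2 = rmax * rmax;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      double d = std::sqrt(d2);
      // first grid radius >= d
      int k = int(std::lower_bound(r.begin(), r.end(), d) - r.begin());
      if (k >= nr) continue;
      double w = 1.0;
      if (correct) w = (wx * wy) / ((wx - std::abs(dx)) * (wy - std::abs(dy)));
      hist[k] += w;
    }
  }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) { acc += hist[k]; out[k] = acc; }
  return out;
}
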