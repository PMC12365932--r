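#include <Rcpp.h>
using namespace Rcpp;

// Delta-rule (Rescorla-Wagner) distractor predictions over the
// distractor-present trials of one subject. `loc` holds 0-based distractor
// locations, `segment` the reset-segment id per trial (predictions return
// to `init` when it changes). The value written for trial i is the
// prediction at that trial's distractor location BEFORE trial i's update.
// This recursion is the innermost loop of model fitting, hence C++.
// [[Rcpp::export]]
NumericVector rl_pred_cpp(IntegerVector loc, IntegerVector segment,
                          double alpha, double init, int n_locations) {
  int n = loc.size();
  NumericVector out(n);
  std::vector<double> p(n_locations, init);
  int seg = n > 0 ? segment[0] : 0;
  for (int i = 0; i < n; ++i) {
    if (segment[i] != seg) {
      std::fill(p.begin(), p.end(), init);
      seg = segment[i];
    }
    out[i] = p[loc[i]];
    for (int l = 0; l < n_locations; ++l) {
      double d = (l == loc[i]) ? 1.0 : 0.0;
      p[l] += alpha * (d - p[l]);
    }
  }
  return out;
}
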