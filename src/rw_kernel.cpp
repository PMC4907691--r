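#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial Rescorla-Wagner recursion with optional instructed mixing.
// cue_idx: 1 = cue A, 2 = cue B; us: outcome per trial (0/1);
// swap_after: trial positions after which the two values mix by rho.
// This is the inner kernel of the fitting objective, so it stays minimal.
// [[Rcpp::export(name = ".ev_recursion_cpp")]]
List ev_recursion_cpp(IntegerVector cue_idx, NumericVector us,
                      IntegerVector swap_after, double alpha, double rho,
                      double v0_a, double v0_b, bool instructed) {
  int n = us.size();
  NumericVector v_pres(n), delta(n), v_a(n), v_b(n);
  std::vector<bool> swap(n + 1, false);
  if (instructed) {
    for (int j = 0; j < swap_after.size(); ++j) {
      int k = swap_after[j];
      if (k >= 1 && k <= n) swap[k] = true;
    }
  }
  double va = v0_a, vb = v0_b;
  for (int k = 0; k < n; ++k) {
    double v = (cue_idx[k] == 1) ? va : vb;
    v_pres[k] = v;
    double d = us[k] - v;
    delta[k] = d;
    if (cue_idx[k] == 1) va += alpha * d; else vb += alpha * d;
    if (swap[k + 1]) {
      double na = rho * vb + (1.0 - rho) * va;
      double nb = rho * va + (1.0 - rho) * vb;
      va = na; vb = nb;
    }
    v_a[k] = va;
    v_b[k] = vb;
  }
  return List::create(_["v_presented"] = v_pres, _["delta"] = delta,
                      _["v_a"] = v_a, _["v_b"] = v_b);
}
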