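// ANOSIM permutation loop over a precomputed rank matrix of dissimilarities.
#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

// R statistic for a labelling, given flat upper-triangle ranks.
double anosim_r(const std::vector<double>& rk, const std::vector<int>& grp, int n) {
  double sw = 0.0, sb = 0.0;
  long nw = 0, nb = 0;
  size_t p = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      if (grp[i] == grp[j]) { sw += rk[p]; ++nw; }
      else { sb += rk[p]; ++nb; }
    }
  }
  double mw = nw ? sw / nw : 0.0;
  double mb = nb ? sb / nb : 0.0;
  return (mb - mw) / ((double)n * (n - 1) / 4.0);
}

} // namespace

// ranks: upper triangle (by row, i<j) midranks of the dissimilarities.
// groups: 0-based integer labels. Returns observed R and permuted Rs.
// [[Rcpp::export(name = ".cpp_anosim")]]
List cpp_anosim(NumericVector ranks, IntegerVector groups, int n, int n_perm) {
  RNGScope rng;
  std::vector<double> rk(ranks.begin(), ranks.end());
  std::vector<int> grp(groups.begin(), groups.end());
  double robs = anosim_r(rk, grp, n);
  NumericVector rperm(n_perm);
  std::vector<int> g = grp;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(g[i], g[j]);
    }
    rperm[p] = anosim_r(rk, g, n);
  }
  return List::create(_["r_obs"] = robs, _["r_perm"] = rperm);
}
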