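#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of each IBD-coefficient triple on a grid.
// A0, A1, A2 are the per-site mixture components; K is m x 3.
// [[Rcpp::export]]
NumericVector kin_grid_loglik(NumericVector A0, NumericVector A1,
                              NumericVector A2, NumericMatrix K) {
  const int n = A0.size(), m = K.nrow();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double k0 = K(j, 0), k1 = K(j, 1), k2 = K(j, 2);
    double s = 0.0, prod = 1.0;
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      const double v = k0 * A0[i] + k1 * A1[i] + k2 * A2[i];
      if (v <= 0.0) {
        bad = true;
        break;
      }
      prod *= v;
      // flush the running product to log space before it can underflow
      if (prod < 1e-280 || prod > 1e280) {
        s += std::log(prod);
        prod = 1.0;
      }
    }
    out[j] = bad ? R_NegInf : s + std::log(prod);
  }
  return out;
}

// Inbreeding log-likelihood sum(log(A + F B)) on a grid of F values.
// Non-positive entry likelihoods (model invalid at that F for some site
// frequency) yield -Inf.
// [[Rcpp::export]]
NumericVector f_grid_loglik(NumericVector A, NumericVector B,
                            NumericVector fgrid) {
  const R_xlen_t n = A.size();
  const int m = fgrid.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double f = fgrid[j];
    double s = 0.0, prod = 1.0;
    bool bad = false;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = A[i] + f * B[i];
      if (v <= 0.0) {
        bad = true;
        break;
      }
      prod *= v;
      if (prod < 1e-280 || prod > 1e280) {
        s += std::log(prod);
        prod = 1.0;
      }
    }
    out[j] = bad ? R_NegInf : s + std::log(prod);
  }
  return out;
}

// Same-group pair statistic under random permutations of the group
// labels (Fisher-Yates shuffles driven by R's RNG, so set.seed applies).
// pi, pj are 0-based indices of the pair members.
// [[Rcpp::export]]
IntegerVector perm_same_group_stats(IntegerVector groups, IntegerVector pi,
                                    IntegerVector pj, int nperm) {
  const int n = groups.size(), np = pi.size();
  std::vector<int> g(groups.begin(), groups.end());
  IntegerVector out(nperm);
  GetRNGstate();
  for (int t = 0; t < nperm; ++t) {
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(g[i], g[k]);
    }
    int s = 0;
    for (int c = 0; c < np; ++c) {
      if (g[pi[c]] == g[pj[c]]) ++s;
    }
    out[t] = s;
  }
  PutRNGstate();
  return out;
}
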