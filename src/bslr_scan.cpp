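#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Residual sum of squares of the least-squares fit on the predictor columns
// `idx` (0-based), computed from the precomputed Gram quantities
// G = P'P, gy = P'y, yty = y'y.  Rank-deficient Gram submatrices fall back
// to the minimum-norm (pseudoinverse) solution so that the exhaustive scan
// never fails on collinear subsets.
static double rss_from_gram(const arma::mat& G, const arma::vec& gy,
                            double yty, const arma::uvec& idx, arma::vec& b) {
  arma::mat Gs = G.submat(idx, idx);
  arma::vec gs = gy.elem(idx);
  bool ok = arma::solve(b, Gs, gs,
                        arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
  if (!ok || !b.is_finite()) {
    b = arma::pinv(Gs) * gs;
  }
  double rss = yty - 2.0 * arma::dot(b, gs) + arma::as_scalar(b.t() * Gs * b);
  return rss > 0.0 ? rss : 0.0;
}

// Exhaustive best-subset scan for one target gene: all parent subsets of
// size 0..k drawn from `candidates`, with the `mandatory` columns (self
// term and intercept) always in the model.  Enumeration is by subset size
// and then lexicographic; a subset replaces the incumbent only when its
// RSS is smaller by more than `tol`, so ties go to the smaller /
// lexicographically earlier subset.
// [[Rcpp::export]]
List subset_scan_cpp(const arma::mat& G, const arma::vec& gy, double yty,
                     const arma::uvec& candidates, const arma::uvec& mandatory,
                     int k, double tol) {
  const int m = candidates.n_elem;
  if (k > m) k = m;
  arma::uvec mand = mandatory - 1;

  double best_rss = R_PosInf;
  arma::uvec best_subset;
  arma::vec best_coef;
  long n_eval = 0;

  std::vector<int> comb;
  for (int s = 0; s <= k; ++s) {
    comb.resize(s);
    for (int i = 0; i < s; ++i) comb[i] = i;
    bool more = true;
    while (more) {
      arma::uvec idx(s + mand.n_elem);
      for (int i = 0; i < s; ++i) idx[i] = candidates[comb[i]] - 1;
      for (size_t i = 0; i < mand.n_elem; ++i) idx[s + i] = mand[i];
      arma::vec b;
      double rss = rss_from_gram(G, gy, yty, idx, b);
      ++n_eval;
      if (rss < best_rss - tol) {
        best_rss = rss;
        best_subset.set_size(s);
        for (int i = 0; i < s; ++i) best_subset[i] = candidates[comb[i]];
        best_coef = b;
      }
      // next lexicographic combination of size s
      if (s == 0) break;
      int pos = s - 1;
      while (pos >= 0 && comb[pos] == m - s + pos) --pos;
      if (pos < 0) { more = false; }
      else {
        ++comb[pos];
        for (int i = pos + 1; i < s; ++i) comb[i] = comb[i - 1] + 1;
      }
    }
  }

  return List::create(_["subset"] = IntegerVector(best_subset.begin(), best_subset.end()),
                      _["coef"] = NumericVector(best_coef.begin(), best_coef.end()),
                      _["rss"] = best_rss,
                      _["n_evaluated"] = (double) n_eval);
}
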