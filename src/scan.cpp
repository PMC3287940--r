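#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Permutation engine for the tree scan statistic.
//
// The tree is fixed; every replicate relabels the trait within strata
// (Fisher-Yates per stratum, driven by R's RNG so set.seed() gives
// determinism), re-accumulates node trait sums bottom-up, converts them to
// z scores, applies the score transform f, and reruns the disjoint-node
// dynamic program. Construction guarantees child ids are larger than the
// parent's id, so iterating nodes in decreasing id order is a valid
// post-order.
//
// The observed statistic is evaluated by the same code path (identical
// summation order) so that permutation ties compare exactly; a tiny relative
// slack absorbs float differences caused by accumulating a permuted vector
// in a different order.
//
// fcode: 0 = z^2, 1 = |z|, 2 = max(z, 0)^2.
// [[Rcpp::export]]
List perm_scan_cpp(IntegerVector child0, IntegerVector child1,
                   IntegerVector leaf_of, NumericVector trait,
                   List strata, int k, int fcode, int nreps,
                   bool keep_replicates) {
  const int nn = child0.size();
  const int n = trait.size();
  if (k < 1) stop("k must be >= 1");

  std::vector<int> nmem(nn, 0);
  for (int i = 0; i < n; ++i) nmem[leaf_of[i] - 1]++;
  for (int v = nn - 1; v >= 0; --v)
    if (child0[v] != NA_INTEGER)
      nmem[v] = nmem[child0[v] - 1] + nmem[child1[v] - 1];

  double xbar = 0.0;
  for (int i = 0; i < n; ++i) xbar += trait[i];
  xbar /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (trait[i] - xbar) * (trait[i] - xbar);
  if (n < 2 || ss <= 0.0) stop("degenerate trait: zero variance");
  const double s = std::sqrt(ss / (n - 1));

  const int ns = strata.size();
  std::vector< std::vector<int> > sidx(ns);
  for (int g = 0; g < ns; ++g) {
    IntegerVector v = strata[g];
    sidx[g].resize(v.size());
    for (int i = 0; i < v.size(); ++i) sidx[g][i] = v[i] - 1;
  }

  std::vector<double> x(trait.begin(), trait.end());
  std::vector<double> nodesum(nn), score(nn);
  std::vector<double> best((size_t)nn * (k + 1));

  NumericVector S_obs(k);
  IntegerVector exceed(k);
  NumericMatrix reps_out(keep_replicates ? nreps : 0,
                         keep_replicates ? k : 0);

  std::vector<double> S(k);
  auto eval = [&]() {
    std::fill(nodesum.begin(), nodesum.end(), 0.0);
    for (int i = 0; i < n; ++i) nodesum[leaf_of[i] - 1] += x[i];
    for (int v = nn - 1; v >= 0; --v) {
      if (child0[v] != NA_INTEGER)
        nodesum[v] = nodesum[child0[v] - 1] + nodesum[child1[v] - 1];
      const double ni = nmem[v];
      const double z = nmem[v] == n ? 0.0
        : std::sqrt(ni) * (nodesum[v] / ni - xbar) / s;
      double sc;
      if (fcode == 0) sc = z * z;
      else if (fcode == 1) sc = std::fabs(z);
      else { const double zp = z > 0 ? z : 0.0; sc = zp * zp; }
      score[v] = sc;
    }
    for (int v = nn - 1; v >= 0; --v) {
      double *bv = &best[(size_t)v * (k + 1)];
      bv[0] = 0.0;
      if (child0[v] == NA_INTEGER) {
        const double sc = score[v] > 0 ? score[v] : 0.0;
        for (int m = 1; m <= k; ++m) bv[m] = sc;
      } else {
        const double *b0 = &best[(size_t)(child0[v] - 1) * (k + 1)];
        const double *b1 = &best[(size_t)(child1[v] - 1) * (k + 1)];
        for (int m = 1; m <= k; ++m) {
          double bb = score[v] > 0 ? score[v] : 0.0;
          for (int j = 0; j <= m; ++j) {
            const double val = b0[j] + b1[m - j];
            if (val > bb) bb = val;
          }
          bv[m] = bb;
        }
      }
    }
    for (int m = 0; m < k; ++m) S[m] = best[m + 1];
  };

  eval();
  std::vector<double> tol(k);
  for (int m = 0; m < k; ++m) {
    S_obs[m] = S[m];
    tol[m] = 1e-12 * (1.0 + std::fabs(S[m]));
  }

  for (int r = 0; r < nreps; ++r) {
    for (int g = 0; g < ns; ++g) {
      std::vector<int> &id = sidx[g];
      for (int i = (int)id.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(x[id[i]], x[id[j]]);
      }
    }
    eval();
    for (int m = 0; m < k; ++m) {
      if (S[m] >= S_obs[m] - tol[m]) exceed[m]++;
      if (keep_replicates) reps_out(r, m) = S[m];
    }
  }

  return List::create(_["S_obs"] = S_obs, _["exceed"] = exceed,
                      _["replicates"] = reps_out);
}
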