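#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Presence index lists per sample (taxa with positive weight).
static void presence_lists(const NumericMatrix& F,
                           std::vector< std::vector<int> >& idx) {
  const int n = F.nrow(), S = F.ncol();
  idx.assign(S, std::vector<int>());
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      if (F(i, s) > 0.0) idx[s].push_back(i);
    }
  }
}

// Abundance-weighted betaMNTD for one unordered pair of communities.
// F holds per-community weights (columns sum to 1 over present taxa);
// perm (may be null) maps taxon index -> tip index in D, implementing the
// tip-label shuffle null.
static double bmntd_pair(const NumericMatrix& F, const NumericMatrix& D,
                         const std::vector<int>& a, const std::vector<int>& b,
                         int k, int m, const int* perm) {
  double s1 = 0.0, s2 = 0.0;
  for (size_t u = 0; u < a.size(); ++u) {
    const int i = a[u];
    const int pi = perm ? perm[i] : i;
    double best = R_PosInf;
    for (size_t v = 0; v < b.size(); ++v) {
      const int pj = perm ? perm[b[v]] : b[v];
      const double d = D(pi, pj);
      if (d < best) best = d;
    }
    s1 += F(i, k) * best;
  }
  for (size_t v = 0; v < b.size(); ++v) {
    const int j = b[v];
    const int pj = perm ? perm[j] : j;
    double best = R_PosInf;
    for (size_t u = 0; u < a.size(); ++u) {
      const int pi = perm ? perm[a[u]] : a[u];
      const double d = D(pj, pi);
      if (d < best) best = d;
    }
    s2 += F(j, m) * best;
  }
  return 0.5 * (s1 + s2);
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix F, NumericMatrix D) {
  const int S = F.ncol();
  std::vector< std::vector<int> > idx;
  presence_lists(F, idx);
  NumericMatrix out(S, S);
  for (int k = 0; k < S; ++k) {
    for (int m = k + 1; m < S; ++m) {
      const double v = bmntd_pair(F, D, idx[k], idx[m], k, m, nullptr);
      out(k, m) = v;
      out(m, k) = v;
    }
  }
  return out;
}

// Streaming first/second moments of the null betaMNTD distribution per pair.
// perms: n_taxa x n_null matrix of 1-based permutations of tip indices.
// [[Rcpp::export]]
List cpp_bmntd_null_moments(NumericMatrix F, NumericMatrix D,
                            IntegerMatrix perms) {
  const int S = F.ncol();
  const int n_null = perms.ncol();
  std::vector< std::vector<int> > idx;
  presence_lists(F, idx);
  NumericMatrix sum(S, S), sumsq(S, S);
  std::vector<int> perm(perms.nrow());
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < perms.nrow(); ++i) perm[i] = perms(i, r) - 1;
    for (int k = 0; k < S; ++k) {
      for (int m = k + 1; m < S; ++m) {
        const double v = bmntd_pair(F, D, idx[k], idx[m], k, m, perm.data());
        sum(k, m) += v;
        sumsq(k, m) += v * v;
      }
    }
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(S, S), sd(S, S);
  for (int k = 0; k < S; ++k) {
    for (int m = k + 1; m < S; ++m) {
      const double mu = sum(k, m) / n_null;
      double var = (sumsq(k, m) - n_null * mu * mu) / (n_null - 1.0);
      if (var < 0.0) var = 0.0;
      mean(k, m) = mean(m, k) = mu;
      sd(k, m) = sd(m, k) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
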