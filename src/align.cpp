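#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch style) alignment cost between two integer-coded
// ordinal sequences. Substituting state i for state j costs |i-j|/(K-1);
// inserting a gap costs `gap`. Minimised by dynamic programming.
static double align_cost(const IntegerVector& a, const IntegerVector& b,
                         int K, double gap) {
  const int n = a.size(), m = b.size();
  const double denom = K - 1.0;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double sub = prev[j - 1] + std::abs(ai - b[j - 1]) / denom;
      double del = prev[j] + gap;
      double ins = cur[j - 1] + gap;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".align_distance_cpp")]]
double align_distance_cpp(IntegerVector a, IntegerVector b, int K,
                          double gap) {
  if (a.size() == 0 || b.size() == 0)
    stop("sequences must be non-empty");
  double c = align_cost(a, b, K, gap);
  return c / std::max(a.size(), b.size());
}

// [[Rcpp::export(name = ".distance_matrix_cpp")]]
NumericMatrix distance_matrix_cpp(List seqs, int K, double gap) {
  const int n = seqs.size();
  std::vector<IntegerVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<IntegerVector>(seqs[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double c = align_cost(s[i], s[j], K, gap) /
        std::max(s[i].size(), s[j].size());
      d(i, j) = c;
      d(j, i) = c;
    }
  }
  return d;
}
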