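#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact Levenshtein distance (plain DP, no backtrace).
// [[Rcpp::export]]
int lev_distance_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Levenshtein with one optimal backtrace; tie preference on equal cost:
// substitution/match > deletion > insertion (ops transform a into b).
// Returns c(distance, insertions, deletions, substitutions).
// [[Rcpp::export]]
IntegerVector lev_profile_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int>> dp(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) dp[i][0] = i;
  for (int j = 0; j <= m; ++j) dp[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = dp[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = dp[i - 1][j] + 1;
      int ins = dp[i][j - 1] + 1;
      dp[i][j] = std::min(sub, std::min(del, ins));
    }
  }
  int i = n, j = m, nins = 0, ndel = 0, nsub = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[i][j] == dp[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      if (a[i - 1] != b[j - 1]) ++nsub;
      --i; --j;
    } else if (i > 0 && dp[i][j] == dp[i - 1][j] + 1) {
      ++ndel; --i;
    } else {
      ++nins; --j;
    }
  }
  return IntegerVector::create(dp[n][m], nins, ndel, nsub);
}
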