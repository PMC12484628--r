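#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact max-log-probability Viterbi path over a k-mer HMM.
//
// z: signal samples (pA)
// mu, sigma: per-state emission parameters (states sorted lexicographically,
//            so tie-breaks toward the smaller index prefer the
//            lexicographically smaller k-mer)
// efrom, eto: 1-based non-self transitions (graph edges)
// elogp: log transition probability per edge, log_self: log P(stay)
// Returns the 1-based state path of length M.
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericVector z, NumericVector mu, NumericVector sigma,
                           IntegerVector efrom, IntegerVector eto,
                           NumericVector elogp, double log_self) {
  const int M = z.size();
  const int n = mu.size();
  const int ne = efrom.size();

  // incoming edges grouped by destination, sources ascending
  std::vector<int> head(n + 1, 0);
  for (int e = 0; e < ne; ++e) head[eto[e]]++;
  for (int j = 1; j <= n; ++j) head[j] += head[j - 1];
  // sort edges by (destination, source) so ties resolve to smaller sources
  std::vector<int> in_edge(ne);
  std::vector<std::pair<long long,int>> tmp(ne);
  for (int e = 0; e < ne; ++e) {
    tmp[e] = std::make_pair((long long)(eto[e] - 1) * (n + 1) + (efrom[e] - 1), e);
  }
  std::sort(tmp.begin(), tmp.end());
  for (int e = 0; e < ne; ++e) in_edge[e] = tmp[e].second;
  std::vector<int> start(n + 1, 0);
  {
    int e = 0;
    for (int j = 0; j < n; ++j) {
      start[j] = e;
      while (e < ne && tmp[e].first / (n + 1) == j) ++e;
    }
    start[n] = ne;
  }

  std::vector<double> log_norm(n), inv2s2(n);
  for (int j = 0; j < n; ++j) {
    log_norm[j] = -0.5 * std::log(2.0 * M_PI) - std::log(sigma[j]);
    inv2s2[j] = 1.0 / (2.0 * sigma[j] * sigma[j]);
  }

  // contiguous copies in destination-sorted order (cache-friendly hot loop)
  std::vector<int> from_s(ne);
  std::vector<double> logp_s(ne);
  for (int e = 0; e < ne; ++e) {
    from_s[e] = efrom[in_edge[e]] - 1;
    logp_s[e] = elogp[in_edge[e]];
  }

  std::vector<double> prev(n), cur(n);
  std::vector<int> bp((size_t)M * n, -1);
  const double log_init = -std::log((double)n);

  for (int j = 0; j < n; ++j) {
    double dz = z[0] - mu[j];
    prev[j] = log_init + log_norm[j] - dz * dz * inv2s2[j];
  }
  for (int t = 1; t < M; ++t) {
    size_t off = (size_t)t * n;
    const double zt = z[t];
    for (int j = 0; j < n; ++j) {
      double best = prev[j] + log_self;
      int best_from = j;
      for (int e = start[j]; e < start[j + 1]; ++e) {
        const int i = from_s[e];
        const double v = prev[i] + logp_s[e];
        if (v > best || (v == best && i < best_from)) {
          best = v;
          best_from = i;
        }
      }
      double dz = zt - mu[j];
      cur[j] = best + log_norm[j] - dz * dz * inv2s2[j];
      bp[off + j] = best_from;
    }
    std::swap(prev, cur);
  }

  int best_j = 0;
  for (int j = 1; j < n; ++j) if (prev[j] > prev[best_j]) best_j = j;
  IntegerVector path(M);
  path[M - 1] = best_j + 1;
  for (int t = M - 1; t > 0; --t) {
    best_j = bp[(size_t)t * n + best_j];
    path[t - 1] = best_j + 1;
  }
  return path;
}
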