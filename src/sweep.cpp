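#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding-window scorer for an ungapped position-specific scoring matrix.
//
// prof: 21 x L matrix of per-column log-odds (row 21 is the neutral X row).
// idx:  1-based residue indices into the rows of prof.
//
// If the sequence is at least as long as the profile, only complete
// placements are considered. If it is shorter, any placement (profile
// overhanging either end) is allowed provided it aligns at least
// ceil(L / 2) profile columns to sequence residues; if no placement
// qualifies the result is -Inf.
//
// Loop order is column-outer / shift-inner so each 21-entry profile column
// stays cache-resident while it is streamed across the sequence.

// [[Rcpp::export]]
double sweep_score_cpp(NumericMatrix prof, IntegerVector idx) {
  const int L = prof.ncol();
  const int n = idx.size();
  if (n == 0 || L == 0) return R_NegInf;
  const double* P = REAL(prof); // column-major: entry (r, k) at P[k * 21 + r]
  const int* ix = INTEGER(idx);

  if (n >= L) {
    const int ns = n - L + 1;
    std::vector<double> acc(ns, 0.0);
    for (int k = 0; k < L; ++k) {
      const double* col = P + (std::size_t)k * 21;
      for (int s = 0; s < ns; ++s) acc[s] += col[ix[s + k] - 1];
    }
    double best = acc[0];
    for (int s = 1; s < ns; ++s) if (acc[s] > best) best = acc[s];
    return best;
  }

  // n < L: shifts s in [-(L-1), n-1]; profile column k aligns sequence
  // position k + s; overlap m(s) = min(L-1, n-1-s) - max(0, -s) + 1
  const int min_overlap = (L + 1) / 2;
  const int ns = n + L - 1; // shift s stored at acc[s + L - 1]
  std::vector<double> acc(ns, 0.0);
  for (int k = 0; k < L; ++k) {
    const double* col = P + (std::size_t)k * 21;
    // j = k + s in [0, n-1]  =>  index j - k + L - 1 in [L-1-k, L-1-k+n-1]
    double* a = acc.data() + (L - 1 - k);
    for (int j = 0; j < n; ++j) a[j] += col[ix[j] - 1];
  }
  double best = R_NegInf;
  for (int si = 0; si < ns; ++si) {
    int s = si - (L - 1);
    int m = std::min(L - 1, n - 1 - s) - std::max(0, -s) + 1;
    if (m >= min_overlap && acc[si] > best) best = acc[si];
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sweep_scores_batch_cpp(NumericMatrix prof, List idx_list) {
  const int N = idx_list.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector idx = idx_list[i];
    out[i] = sweep_score_cpp(prof, idx);
  }
  return out;
}
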