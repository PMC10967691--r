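#include <Rcpp.h>
using namespace Rcpp;

// Banded Smith-Waterman local alignment score for nucleotide sequences
// encoded as integers 0..3 (negative = ambiguous, never matches). The band
// is centred on the diagonal shifted by the length difference, which suits
// near-collinear homologous coding sequences.
// [[Rcpp::export(name = ".bandedSW")]]
int bandedSW(IntegerVector a, IntegerVector b, int band,
             int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  const int width = 2 * band + 1;
  // diagonal offset so the band follows j ~ i * m / n
  std::vector<int> prev(width + 2, 0), cur(width + 2, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int centre = (int)((long long)i * m / n);
    int prev_centre = (int)((long long)(i - 1) * m / n);
    int shift = centre - prev_centre; // 0 or 1
    std::fill(cur.begin(), cur.end(), 0);
    for (int k = 0; k < width; ++k) {
      int j = centre + k - band;
      if (j < 1 || j > m) continue;
      // prev row index of (i-1, j-1) and (i-1, j)
      int kd = (j - 1) - prev_centre + band; // diagonal
      int ku = j - prev_centre + band;       // up
      int diag = (kd >= 0 && kd < width) ? prev[kd] : 0;
      int up = (ku >= 0 && ku < width) ? prev[ku] : 0;
      int left = (k - 1 >= 0) ? cur[k - 1] : 0;
      int s = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = diag + s;
      if (up + gap > v) v = up + gap;
      if (left + gap > v) v = left + gap;
      if (v < 0) v = 0;
      cur[k] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
    (void)shift;
  }
  return best;
}
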