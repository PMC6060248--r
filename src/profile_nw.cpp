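#include <Rcpp.h>
using namespace Rcpp;

// Global (end-gap penalised) profile-profile alignment, Gotoh affine gaps.
// colscore[i,j] is the expected substitution score between column i of
// profile A and column j of profile B; a gap of length L costs
// gap_open + gap_ext * L.  Returns 1-based column indices of the merged
// alignment (0 = gap), with a fixed diagonal > up > left tie preference so
// the result is deterministic.
// [[Rcpp::export(name = ".nw_profile_path")]]
List nw_profile_path(NumericMatrix colscore, double gap_open, double gap_ext) {
  const int n = colscore.nrow(), m = colscore.ncol();
  const double NEG = -1e18;
  const double open_cost = gap_open + gap_ext;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; Ix(i, j) = NEG; Iy(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) Ix(i, 0) = -gap_open - gap_ext * i;
  for (int j = 1; j <= m; ++j) Iy(0, j) = -gap_open - gap_ext * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      M(i, j) = prev + colscore(i - 1, j - 1);
      Ix(i, j) = std::max(std::max(M(i - 1, j), Iy(i - 1, j)) - open_cost,
                          Ix(i - 1, j) - gap_ext);
      Iy(i, j) = std::max(std::max(M(i, j - 1), Ix(i, j - 1)) - open_cost,
                          Iy(i, j - 1) - gap_ext);
    }
  }
  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  double best = std::max(M(n, m), std::max(Ix(n, m), Iy(n, m)));
  int state = (best == M(n, m)) ? 0 : (best == Ix(n, m) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ai.push_back(i); bi.push_back(j);
      double prev = M(i, j) - colscore(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(prev - M(i, j)) < 1e-9) state = 0;
      else if (std::abs(prev - Ix(i, j)) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1 || (j == 0 && i > 0)) {
      ai.push_back(i); bi.push_back(0);
      double cur = Ix(i, j);
      --i;
      if (i >= 0 && std::abs(cur - (Ix(i, j) - gap_ext)) < 1e-9) state = 1;
      else if (std::abs(cur - (M(i, j) - open_cost)) < 1e-9) state = 0;
      else state = 2;
      if (i == 0 && j == 0) break;
    } else {
      ai.push_back(0); bi.push_back(j);
      double cur = Iy(i, j);
      --j;
      if (j >= 0 && std::abs(cur - (Iy(i, j) - gap_ext)) < 1e-9) state = 2;
      else if (std::abs(cur - (M(i, j) - open_cost)) < 1e-9) state = 0;
      else state = 1;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
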