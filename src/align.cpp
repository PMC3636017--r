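#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with linear gap penalties.
//
// The band is a corridor in (i, j) space with j - i constrained to
// [min(0, m-n) - band, max(0, m-n) + band], so both endpoints (0,0) and
// (n,m) are always inside the corridor and a connecting path always
// exists.  Scores: +match for a match, -mismatch for a substitution,
// -ins_cost per query base aligned to a gap, -del_cost per subject base
// aligned to a gap.
//
// Returns score, matches and columns (alignment length incl. gap columns)
// of the optimal in-band path.
// [[Rcpp::export]]
List nw_banded_cpp(std::string a, std::string b, int match, int mismatch,
                   int ins_cost, int del_cost, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int W = hi - lo + 1;
  const int NEG = INT_MIN / 4;
  std::vector<int> dp((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0); // 1 diag, 2 up, 3 left
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  dp[idx(0, 0)] = 0;
  for (int i = 0; i <= n; ++i) {
    const int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      int best = NEG;
      unsigned char dir = 0;
      if (i > 0 && j > 0 && j - 1 >= (i - 1) + lo && j - 1 <= (i - 1) + hi) {
        int s = dp[idx(i - 1, j - 1)];
        if (s > NEG) {
          s += (a[i - 1] == b[j - 1]) ? match : -mismatch;
          if (s > best) { best = s; dir = 1; }
        }
      }
      if (i > 0 && j >= (i - 1) + lo && j <= (i - 1) + hi) {
        int s = dp[idx(i - 1, j)];
        if (s > NEG) {
          s -= ins_cost;
          if (s > best) { best = s; dir = 2; }
        }
      }
      if (j > 0 && j - 1 >= i + lo) {
        int s = dp[idx(i, j - 1)];
        if (s > NEG) {
          s -= del_cost;
          if (s > best) { best = s; dir = 3; }
        }
      }
      dp[idx(i, j)] = best;
      tb[idx(i, j)] = dir;
    }
  }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    unsigned char d = tb[idx(i, j)];
    if (d == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (d == 2) { --i; }
    else if (d == 3) { --j; }
    else break;
    ++columns;
  }
  return List::create(_["score"] = dp[idx(n, m)],
                      _["matches"] = matches,
                      _["columns"] = columns);
}

// Banded local (Smith-Waterman) alignment around a seed diagonal.
// `diag` is the 0-based subject offset minus query offset of the seed;
// the corridor is j - i in [diag - band, diag + band].  Coordinates in
// the result are 1-based and inclusive; score 0 means no positive-score
// local alignment inside the band.
// [[Rcpp::export]]
List sw_banded_cpp(std::string a, std::string b, int diag, int match,
                   int mismatch, int ins_cost, int del_cost, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  const int lo = diag - band, hi = diag + band;
  const int W = hi - lo + 1;
  std::vector<int> dp((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);
  auto inband = [&](int i, int j) {
    return i >= 0 && j >= 0 && i <= n && j <= m && j - i >= lo && j - i <= hi;
  };
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= n; ++i) {
    const int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int best = 0;
      unsigned char dir = 0;
      if (inband(i - 1, j - 1)) {
        int s = dp[idx(i - 1, j - 1)] +
                ((a[i - 1] == b[j - 1]) ? match : -mismatch);
        if (s > best) { best = s; dir = 1; }
      }
      if (inband(i - 1, j)) {
        int s = dp[idx(i - 1, j)] - ins_cost;
        if (s > best) { best = s; dir = 2; }
      }
      if (inband(i, j - 1)) {
        int s = dp[idx(i, j - 1)] - del_cost;
        if (s > best) { best = s; dir = 3; }
      }
      dp[idx(i, j)] = best;
      tb[idx(i, j)] = dir;
      if (best > bscore) { bscore = best; bi = i; bj = j; }
    }
  }
  if (bscore == 0)
    return List::create(_["score"] = 0, _["matches"] = 0, _["columns"] = 0,
                        _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0);
  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    unsigned char d = tb[idx(i, j)];
    if (d == 0) break;
    if (d == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (d == 2) { --i; }
    else { --j; }
    ++columns;
  }
  return List::create(_["score"] = bscore, _["matches"] = matches,
                      _["columns"] = columns,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj);
}
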