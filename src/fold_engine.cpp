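#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Pair weights: G-C/C-G = 3, A-U/U-A = 2, G-U/U-G = 1; anything else
// (including IUPAC ambiguity codes) is unpairable.  A +1 stacking bonus is
// added for every pair (i,j) whose inner neighbour (i+1,j-1) is also paired.
static inline int pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return -1;
}

namespace {

struct FoldDP {
  int n;
  int minloop;
  const std::string &s;
  std::vector<int> M;   // best score on [i..j]
  std::vector<int> P;   // best score on [i..j] with (i,j) paired; -1 if invalid
  std::vector<int> pair_of;

  FoldDP(const std::string &seq, int ml)
      : n((int)seq.size()), minloop(ml), s(seq),
        M((size_t)n * n, 0), P((size_t)n * n, -1),
        pair_of(n, -1) {}

  inline int m(int i, int j) const {
    if (i > j || i < 0 || j >= n) return 0;
    return M[(size_t)i * n + j];
  }
  inline int p(int i, int j) const { return P[(size_t)i * n + j]; }

  void fill() {
    for (int span = minloop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // P[i][j]: (i,j) paired
        int w = pair_w(s[i], s[j]);
        if (w > 0) {
          int inner = m(i + 2, j - 1);  // i+1 unpaired
          if (j - i - 3 >= minloop && pair_w(s[i + 1], s[j - 1]) > 0) {
            int st = p(i + 1, j - 1);
            if (st >= 0 && st + 1 > inner) inner = st + 1;  // stacked
          }
          for (int k = i + 1 + minloop + 1; k <= j - 2; ++k) {
            int pk = p(i + 1, k);
            if (pk >= 0) {
              int v = pk + m(k + 1, j - 1);
              if (v > inner) inner = v;
            }
          }
          P[(size_t)i * n + j] = w + inner;
        }
        // M[i][j]
        int best = m(i + 1, j);  // i unpaired
        for (int k = i + minloop + 1; k <= j; ++k) {
          int pk = p(i, k);
          if (pk >= 0) {
            int v = pk + m(k + 1, j);
            if (v > best) best = v;
          }
        }
        M[(size_t)i * n + j] = best;
      }
    }
  }

  // Deterministic traceback: the leftmost base of an interval is paired
  // whenever an optimal structure allows it, with the smallest admissible
  // partner; otherwise it is left unpaired.
  void traceM(int i, int j) {
    while (i <= j) {
      int best = m(i, j);
      int chosen = -1;
      for (int k = i + minloop + 1; k <= j; ++k) {
        int pk = p(i, k);
        if (pk >= 0 && pk + m(k + 1, j) == best) { chosen = k; break; }
      }
      if (chosen < 0) { ++i; continue; }
      traceP(i, chosen);
      i = chosen + 1;
    }
  }

  void traceP(int i, int j) {
    pair_of[i] = j;
    pair_of[j] = i;
    int inner = p(i, j) - pair_w(s[i], s[j]);
    int chosen = -1;
    for (int k = i + 1 + minloop + 1; k <= j - 1; ++k) {
      int pk = p(i + 1, k);
      if (pk < 0) continue;
      int v = (k == j - 1) ? pk + 1 : pk + m(k + 1, j - 1);
      if (v == inner) { chosen = k; break; }
    }
    if (chosen >= 0) {
      traceP(i + 1, chosen);
      if (chosen < j - 1) traceM(chosen + 1, j - 1);
    } else {
      traceM(i + 2, j - 1);
    }
  }
};

}  // namespace

//' @useDynLib its2cbc, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq, int min_loop) {
  int n = (int)seq.size();
  FoldDP dp(seq, min_loop);
  int score = 0;
  if (n > min_loop + 1) {
    dp.fill();
    score = dp.m(0, n - 1);
    dp.traceM(0, n - 1);
  }
  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (dp.pair_of[i] > i) { db[i] = '('; db[dp.pair_of[i]] = ')'; ++npairs; }
  }
  IntegerMatrix pr(npairs, 2);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (dp.pair_of[i] > i) { pr(r, 0) = i + 1; pr(r, 1) = dp.pair_of[i] + 1; ++r; }
  }
  return List::create(_["structure"] = db, _["score"] = score,
                      _["pairs"] = pr);
}
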