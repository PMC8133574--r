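#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Anchor chaining by layered dynamic programming.
//
// States are (anchor, total skipped genes g, saturating chain length l).
// A chain extends from anchor j to anchor i when 0 < da <= max_gap+1 and
// 0 < orient*db <= max_gap+1; the transition adds match_score plus
// gap_penalty per skipped gene (da-1 + |db|-1). Chains qualify as blocks
// once the saturating length layer reaches min_anchors and g stays within
// max_gaps_total. Greedy extraction: repeatedly take the best-scoring
// chain (ties: smaller first a-ordinal, then +1 orientation), remove its
// anchors, and re-run the DP on the remainder.

struct Chain {
  std::vector<int> idx;  // indices into the original anchor arrays
  int orient;
  double score;
  int gaps;
};

static bool best_chain_orient(const IntegerVector& pa, const IntegerVector& pb,
                              const std::vector<int>& act, int orient,
                              int min_anchors, int max_gap,
                              int max_gaps_total, double match_score,
                              double gap_penalty, Chain& out) {
  const int n = (int)act.size();
  if (n < min_anchors) return false;
  const int G = max_gaps_total + 1;
  const int L = std::max(min_anchors, 1);
  const double NEG = -1e18;
  std::vector<double> f((size_t)n * G * L, NEG);
  std::vector<long long> par((size_t)n * G * L, -1);
  for (int i = 0; i < n; ++i) f[((size_t)i * G + 0) * L + 0] = match_score;
  for (int i = 0; i < n; ++i) {
    const int ai = pa[act[i]], bi = pb[act[i]];
    for (int j = i - 1; j >= 0; --j) {
      const int da = ai - pa[act[j]];
      if (da > max_gap + 1) break;  // act sorted by (pa, pb)
      if (da <= 0) continue;
      const int db = orient * (bi - pb[act[j]]);
      if (db <= 0 || db > max_gap + 1) continue;
      const int s = (da - 1) + (db - 1);
      const double add = match_score + gap_penalty * s;
      for (int g = 0; g + s < G; ++g) {
        for (int l = 0; l < L; ++l) {
          const double prev = f[((size_t)j * G + g) * L + l];
          if (prev <= NEG / 2) continue;
          const int nl = std::min(l + 1, L - 1);
          const size_t st = ((size_t)i * G + g + s) * L + nl;
          const double cand = prev + add;
          if (cand > f[st] + 1e-12) {
            f[st] = cand;
            par[st] = ((long long)j * G + g) * L + l;
          }
        }
      }
    }
  }
  double best = NEG;
  size_t bst = 0;
  bool found = false;
  int best_start = INT_MAX;
  for (int i = 0; i < n; ++i) {
    for (int g = 0; g < G; ++g) {
      const size_t st = ((size_t)i * G + g) * L + (L - 1);
      if (f[st] <= NEG / 2) continue;
      // backtrack to find the chain start for tie-breaking
      if (f[st] > best + 1e-9 ||
          (std::abs(f[st] - best) <= 1e-9 && found)) {
        long long cur = (long long)st;
        int start_i = i;
        while (par[cur] >= 0) {
          cur = par[cur];
          start_i = (int)(cur / ((long long)G * L));
        }
        const int start_pa = pa[act[start_i]];
        if (f[st] > best + 1e-9 || start_pa < best_start) {
          best = f[st];
          bst = st;
          best_start = start_pa;
          found = true;
        }
      }
    }
  }
  if (!found) return false;
  std::vector<int> chain;
  long long cur = (long long)bst;
  int gaps = (int)((bst / L) % G);
  while (cur >= 0) {
    chain.push_back(act[(int)(cur / ((long long)G * L))]);
    cur = par[cur];
  }
  std::reverse(chain.begin(), chain.end());
  if ((int)chain.size() < min_anchors) return false;
  out.idx = chain;
  out.orient = orient;
  out.score = best;
  out.gaps = gaps;
  return true;
}

// [[Rcpp::export]]
List chain_anchors_cpp(IntegerVector pos_a, IntegerVector pos_b,
                       int min_anchors, int max_gap, int max_gaps_total,
                       double match_score, double gap_penalty) {
  const int n = pos_a.size();
  std::vector<int> act(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (pos_a[a] != pos_a[b]) return pos_a[a] < pos_a[b];
    return pos_b[a] < pos_b[b];
  });
  act = ord;
  List blocks;
  while ((int)act.size() >= min_anchors) {
    Chain plus, minus;
    const bool hp = best_chain_orient(pos_a, pos_b, act, +1, min_anchors,
                                      max_gap, max_gaps_total, match_score,
                                      gap_penalty, plus);
    const bool hm = best_chain_orient(pos_a, pos_b, act, -1, min_anchors,
                                      max_gap, max_gaps_total, match_score,
                                      gap_penalty, minus);
    if (!hp && !hm) break;
    Chain* pick;
    if (hp && hm) {
      if (plus.score > minus.score + 1e-9) pick = &plus;
      else if (minus.score > plus.score + 1e-9) pick = &minus;
      else pick = (pos_a[plus.idx[0]] <= pos_a[minus.idx[0]]) ? &plus
                                                              : &minus;
    } else {
      pick = hp ? &plus : &minus;
    }
    blocks.push_back(List::create(
        Named("idx") = IntegerVector(pick->idx.begin(), pick->idx.end()),
        Named("orientation") = pick->orient,
        Named("score") = pick->score,
        Named("gaps") = pick->gaps));
    std::vector<int> remain;
    remain.reserve(act.size());
    std::vector<bool> used(n, false);
    for (int v : pick->idx) used[v] = true;
    for (int v : act)
      if (!used[v]) remain.push_back(v);
    act.swap(remain);
  }
  return blocks;
}
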