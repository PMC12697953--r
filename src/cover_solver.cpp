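#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>

using namespace Rcpp;

// Exact-cover selection of frame-to-frame assignment candidates by
// depth-first branch and bound.
//
// Encoding (0-based, -1 = absent):
//   src < 0, t1 >= 0            appearance of target t1
//   src >= 0, t1 < 0            disappearance of source src
//   src >= 0, t1 >= 0, t2 < 0   migration src -> t1
//   src >= 0, t1 >= 0, t2 >= 0  division src -> (t1, t2)
//
// Constraints: every source and every target is covered by exactly one
// selected candidate; objective: maximise the summed log-scores. Ties are
// broken toward fewer appear+disappear assignments, then toward the
// lexicographically smallest candidate index set (determinism).
//
// Dominance: a migrate/divide candidate scoring strictly worse than covering
// the same cells with disappear + appear(s) cannot occur in any optimal
// cover (swapping it out stays feasible and strictly improves), so such
// candidates are skipped. Equal scores are kept so tie-breaking is exact.
//
// `forbidden` is a list of previously returned solutions (sorted 1-based
// candidate index vectors) that must not be returned again; this implements
// the exclusion constraints of the k-best enumeration. Only solutions free
// of dominated candidates are enumerable, which is also the sensible
// hypothesis set for particle sampling.
//
// `max_nodes` caps the number of search-tree expansions (0 = unlimited); the
// cap keeps worst-case flat-score instances bounded while remaining fully
// deterministic. The returned vector carries attribute `complete` = FALSE
// when the cap was hit.

namespace {

struct Incumbent {
  bool found = false;
  double score = 0.0;
  int unary = 0;
  std::vector<int> set;  // sorted 0-based candidate indices
};

const double EPS = 1e-9;

bool lex_less(const std::vector<int> &a, const std::vector<int> &b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

}  // namespace

// [[Rcpp::export(name = ".solve_cover_cpp")]]
IntegerVector solve_cover_cpp(int n_sources, int n_targets,
                              IntegerVector src, IntegerVector t1,
                              IntegerVector t2, NumericVector score,
                              List forbidden, double max_nodes = 0) {
  const int m = src.size();
  std::vector<int> appear_of(n_targets, -1);
  std::vector<int> disappear_of(n_sources, -1);
  for (int i = 0; i < m; ++i) {
    if (src[i] < 0) appear_of[t1[i]] = i;
    else if (t1[i] < 0) disappear_of[src[i]] = i;
  }
  for (int t = 0; t < n_targets; ++t) {
    if (appear_of[t] < 0) stop("every target needs an appearance candidate");
  }
  for (int s = 0; s < n_sources; ++s) {
    if (disappear_of[s] < 0) stop("every source needs a disappearance candidate");
  }
  std::vector<std::vector<int>> by_source(n_sources);
  for (int i = 0; i < m; ++i) {
    if (src[i] < 0) continue;
    if (t1[i] >= 0) {
      // dominance filter against the unary replacement
      double unary_alt = score[disappear_of[src[i]]] + score[appear_of[t1[i]]];
      if (t2[i] >= 0) unary_alt += score[appear_of[t2[i]]];
      if (score[i] < unary_alt - EPS) continue;
    }
    by_source[src[i]].push_back(i);
  }
  // high-score candidates first: good incumbents early, stronger pruning
  for (auto &v : by_source) {
    std::sort(v.begin(), v.end(), [&](int a, int b) {
      if (score[a] != score[b]) return score[a] > score[b];
      return a < b;
    });
  }
  // admissible bound parts: per-source best candidate (suffix sums) and, per
  // still-uncovered target, max(appear score, 0) (0 when a later source
  // covers it)
  std::vector<double> tail(n_sources + 1, 0.0);
  for (int s = n_sources - 1; s >= 0; --s) {
    tail[s] = tail[s + 1] + score[by_source[s].front()];
  }
  std::vector<double> tgt_bound(n_targets);
  double avail_bound = 0.0;
  for (int t = 0; t < n_targets; ++t) {
    tgt_bound[t] = std::max(score[appear_of[t]], 0.0);
    avail_bound += tgt_bound[t];
  }

  std::vector<std::vector<int>> forb;
  for (int i = 0; i < forbidden.size(); ++i) {
    IntegerVector f = forbidden[i];
    std::vector<int> v(f.begin(), f.end());
    for (auto &x : v) x -= 1;  // to 0-based
    std::sort(v.begin(), v.end());
    forb.push_back(v);
  }

  std::vector<bool> taken(n_targets, false);
  std::vector<int> chosen;
  chosen.reserve(n_sources);
  Incumbent best;
  double nodes = 0;
  bool complete = true;

  std::function<void(int, double, int)> dfs = [&](int s, double cur,
                                                  int unary) {
    if (max_nodes > 0 && nodes >= max_nodes) {
      complete = false;
      return;
    }
    nodes += 1;
    if (best.found && cur + tail[s] + avail_bound < best.score - EPS) return;
    if (s == n_sources) {
      double total = cur;
      int un = unary;
      std::vector<int> sol(chosen);
      for (int t = 0; t < n_targets; ++t) {
        if (!taken[t]) {
          total += score[appear_of[t]];
          sol.push_back(appear_of[t]);
          ++un;
        }
      }
      std::sort(sol.begin(), sol.end());
      for (const auto &f : forb) {
        if (f == sol) return;
      }
      bool better = false;
      if (!best.found || total > best.score + EPS) {
        better = true;
      } else if (total >= best.score - EPS) {
        if (un < best.unary) better = true;
        else if (un == best.unary && lex_less(sol, best.set)) better = true;
      }
      if (better) {
        best.found = true;
        best.score = total;
        best.unary = un;
        best.set = std::move(sol);
      }
      return;
    }
    for (int c : by_source[s]) {
      bool is_dis = t1[c] < 0;
      bool is_div = t2[c] >= 0;
      if (!is_dis) {
        if (taken[t1[c]]) continue;
        if (is_div && taken[t2[c]]) continue;
      }
      double delta_avail = 0.0;
      if (!is_dis) {
        taken[t1[c]] = true;
        delta_avail += tgt_bound[t1[c]];
        if (is_div) {
          taken[t2[c]] = true;
          delta_avail += tgt_bound[t2[c]];
        }
      }
      avail_bound -= delta_avail;
      chosen.push_back(c);
      dfs(s + 1, cur + score[c], unary + (is_dis ? 1 : 0));
      chosen.pop_back();
      avail_bound += delta_avail;
      if (!is_dis) {
        taken[t1[c]] = false;
        if (is_div) taken[t2[c]] = false;
      }
    }
  };
  dfs(0, 0.0, 0);

  IntegerVector out;
  if (best.found) {
    out = IntegerVector(best.set.size());
    for (size_t i = 0; i < best.set.size(); ++i) out[i] = best.set[i] + 1;
  } else {
    out = IntegerVector(0);
  }
  out.attr("complete") = complete;
  return out;
}
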