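// Extremely randomized trees over flattened patch vectors.
//
// Node tests are the two pixel-level families:
//   SIMPLETHRES (kind 0): x[attr] < threshold
//   DIFFNEIGHBOR (kind 1): x[attr] - x[attr2] < threshold, attr2 one of the
//     8-neighbors of attr inside the same channel plane of the patch grid.
// At each node K candidate tests are drawn (attribute uniform, threshold
// uniform in the open node-local (min, max) of the tested quantity) and the
// best by normalized Shannon information gain is kept.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

namespace {

struct TestDraw {
  int attr;    // 0-based; -1 when no valid test exists
  int attr2;   // 0-based; -1 for SIMPLETHRES
  double thr;
};

inline double quantity(const double* X, int nrow, int i, int a, int a2) {
  double v = X[i + (size_t)nrow * a];
  if (a2 >= 0) v -= X[i + (size_t)nrow * a2];
  return v;
}

// in-grid 8-neighbors of `attr` within its channel plane (edge x edge)
int neighbors_of(int attr, int edge, int* out) {
  const int plane = edge * edge;
  const int ch = attr / plane, p = attr % plane, r = p / edge, c = p % edge;
  int n = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      const int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= edge || cc < 0 || cc >= edge) continue;
      out[n++] = ch * plane + rr * edge + cc;
    }
  return n;
}

bool minmax_quantity(const double* X, int nrow, const std::vector<int>& idx,
                     int a, int a2, double* qmin, double* qmax) {
  double lo = quantity(X, nrow, idx[0], a, a2), hi = lo;
  for (size_t k = 1; k < idx.size(); ++k) {
    const double q = quantity(X, nrow, idx[k], a, a2);
    if (q < lo) lo = q;
    if (q > hi) hi = q;
  }
  *qmin = lo;
  *qmax = hi;
  return hi > lo;
}

// Draw one candidate test: attribute (and neighbor) uniform at random,
// rejecting node-constant quantities; threshold uniform in (min, max).
// Falls back to a deterministic scan when rejection takes too long; returns
// attr = -1 when no non-constant quantity exists at the node.
TestDraw draw_test(const double* X, int nrow, const std::vector<int>& idx,
                   int nattr, int edge, int kind, ZsRng& rng) {
  TestDraw t{-1, -1, 0.0};
  int nb[8];
  double qmin, qmax;
  const int max_attempts = 8 * nattr;
  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    const int a = rng.randint(nattr);
    int a2 = -1;
    if (kind == 1) {
      const int nn = neighbors_of(a, edge, nb);
      a2 = nb[rng.randint(nn)];
    }
    if (minmax_quantity(X, nrow, idx, a, a2, &qmin, &qmax)) {
      t.attr = a;
      t.attr2 = a2;
      t.thr = qmin + rng.unif_open() * (qmax - qmin);
      return t;
    }
  }
  // exhaustive fallback (degenerate node): first valid attribute in order
  for (int a = 0; a < nattr; ++a) {
    if (kind == 0) {
      if (minmax_quantity(X, nrow, idx, a, -1, &qmin, &qmax)) {
        t.attr = a;
        t.thr = qmin + rng.unif_open() * (qmax - qmin);
        return t;
      }
    } else {
      const int nn = neighbors_of(a, edge, nb);
      for (int j = 0; j < nn; ++j) {
        if (minmax_quantity(X, nrow, idx, a, nb[j], &qmin, &qmax)) {
          t.attr = a;
          t.attr2 = nb[j];
          t.thr = qmin + rng.unif_open() * (qmax - qmin);
          return t;
        }
      }
    }
  }
  return t;  // no valid test
}

double entropy(const std::vector<int>& cnt, int n) {
  double h = 0.0;
  for (int c : cnt)
    if (c > 0) {
      const double p = (double)c / n;
      h -= p * std::log(p);
    }
  return h;
}

// normalized Shannon information gain: 2 I(split; class) / (Hc + Hs)
double score_counts(const std::vector<int>& lc, int nl,
                    const std::vector<int>& rc, int nr) {
  const int n = nl + nr;
  const size_t ncl = lc.size();
  std::vector<int> pc(ncl);
  for (size_t c = 0; c < ncl; ++c) pc[c] = lc[c] + rc[c];
  const double hc = entropy(pc, n);
  const double hl = entropy(lc, nl), hr = entropy(rc, nr);
  double hs = 0.0;
  const double pl = (double)nl / n, pr = (double)nr / n;
  if (pl > 0) hs -= pl * std::log(pl);
  if (pr > 0) hs -= pr * std::log(pr);
  const double gain = hc - pl * hl - pr * hr;
  const double denom = hc + hs;
  if (denom <= 0) return 0.0;
  const double s = 2.0 * gain / denom;
  return s > 0 ? s : 0.0;
}

struct TreeBuf {
  std::vector<int> attr, attr2, left, right, leaf_id;
  std::vector<double> thr;
  std::vector<std::vector<int>> counts;  // leaf class counts; empty internal

  int new_node(int n_classes) {
    attr.push_back(-1);
    attr2.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    leaf_id.push_back(-1);
    thr.push_back(NA_REAL);
    counts.push_back(std::vector<int>());
    return (int)attr.size() - 1;
  }
};

struct StackItem {
  int slot;
  std::vector<int> idx;
};

void build_tree(const double* X, int nrow, const int* y, int n_classes,
                int n_tests, int n_min, int kind, int edge, int nattr,
                ZsRng& rng, TreeBuf& tb) {
  std::vector<StackItem> stack;
  std::vector<int> all(nrow);
  for (int i = 0; i < nrow; ++i) all[i] = i;
  int root = tb.new_node(n_classes);
  stack.push_back({root, std::move(all)});

  while (!stack.empty()) {
    StackItem it = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = it.idx;
    const int n = (int)idx.size();

    std::vector<int> cnt(n_classes, 0);
    for (int i : idx) cnt[y[i]]++;
    int present = 0;
    for (int c : cnt)
      if (c > 0) present++;

    bool make_leaf = (n < n_min) || (present <= 1);
    TestDraw best{-1, -1, 0.0};
    if (!make_leaf) {
      double best_score = -1.0;
      for (int k = 0; k < n_tests; ++k) {
        TestDraw t = draw_test(X, nrow, idx, nattr, edge, kind, rng);
        if (t.attr < 0) break;  // node fully constant: no test will be valid
        std::vector<int> lc(n_classes, 0), rc(n_classes, 0);
        int nl = 0, nr = 0;
        for (int i : idx) {
          if (quantity(X, nrow, i, t.attr, t.attr2) < t.thr) {
            lc[y[i]]++;
            nl++;
          } else {
            rc[y[i]]++;
            nr++;
          }
        }
        const double s = score_counts(lc, nl, rc, nr);
        if (s > best_score) {  // strict: ties keep the first-drawn test
          best_score = s;
          best = t;
        }
      }
      if (best.attr < 0) make_leaf = true;
    }

    if (make_leaf) {
      tb.counts[it.slot] = cnt;
      continue;
    }

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {  // stable partition: preserves sample order
      if (quantity(X, nrow, i, best.attr, best.attr2) < best.thr)
        lidx.push_back(i);
      else
        ridx.push_back(i);
    }
    tb.attr[it.slot] = best.attr;
    tb.attr2[it.slot] = best.attr2;
    tb.thr[it.slot] = best.thr;
    const int ls = tb.new_node(n_classes);
    const int rs = tb.new_node(n_classes);
    tb.left[it.slot] = ls;
    tb.right[it.slot] = rs;
    // LIFO: push right first so the left child is grown first (preorder)
    stack.push_back({rs, std::move(ridx)});
    stack.push_back({ls, std::move(lidx)});
  }
}

List tree_to_list(const TreeBuf& tb, int n_classes, int* leaf_counter) {
  const int nn = (int)tb.attr.size();
  IntegerVector attr(nn), attr2(nn), left(nn), right(nn), leaf_id(nn);
  NumericVector thr(nn);
  NumericMatrix counts(nn, n_classes);
  int n_leaves = 0;
  for (int i = 0; i < nn; ++i) {
    const bool leaf = tb.left[i] < 0;
    attr[i] = leaf ? NA_INTEGER : tb.attr[i] + 1;
    attr2[i] = (leaf || tb.attr2[i] < 0) ? NA_INTEGER : tb.attr2[i] + 1;
    thr[i] = leaf ? NA_REAL : tb.thr[i];
    left[i] = leaf ? NA_INTEGER : tb.left[i] + 1;
    right[i] = leaf ? NA_INTEGER : tb.right[i] + 1;
    if (leaf) {
      leaf_id[i] = ++(*leaf_counter);
      n_leaves++;
      for (int c = 0; c < n_classes; ++c) counts(i, c) = tb.counts[i][c];
    } else {
      leaf_id[i] = NA_INTEGER;
    }
  }
  return List::create(_["attr"] = attr, _["attr2"] = attr2,
                      _["threshold"] = thr, _["left"] = left,
                      _["right"] = right, _["leaf_id"] = leaf_id,
                      _["counts"] = counts, _["n_nodes"] = nn,
                      _["n_leaves"] = n_leaves);
}

}  // namespace

// [[Rcpp::export]]
List cpp_build_ensemble(NumericMatrix X, IntegerVector y, int n_classes,
                        int n_trees, int n_tests, int n_min, int kind,
                        int edge, double seed) {
  const int nrow = X.nrow(), nattr = X.ncol();
  std::vector<int> yy(nrow);
  for (int i = 0; i < nrow; ++i) yy[i] = y[i];
  List trees(n_trees);
  int leaf_counter = 0;
  for (int t = 0; t < n_trees; ++t) {
    // independent substream per tree
    const uint64_t s =
        (uint64_t)(int64_t)seed * 0x9E3779B97F4A7C15ULL + (uint64_t)(t + 1);
    ZsRng rng(s);
    TreeBuf tb;
    build_tree(&X[0], nrow, yy.data(), n_classes, n_tests, n_min, kind, edge,
               nattr, rng, tb);
    trees[t] = tree_to_list(tb, n_classes, &leaf_counter);
  }
  return trees;
}

// [[Rcpp::export]]
IntegerVector cpp_propagate(NumericMatrix X, IntegerVector attr,
                            IntegerVector attr2, NumericVector thr,
                            IntegerVector left, IntegerVector right) {
  const int nrow = X.nrow();
  IntegerVector out(nrow);
  for (int i = 0; i < nrow; ++i) {
    int node = 0;
    while (left[node] != NA_INTEGER) {
      double q = X(i, attr[node] - 1);
      if (attr2[node] != NA_INTEGER) q -= X(i, attr2[node] - 1);
      node = (q < thr[node]) ? left[node] - 1 : right[node] - 1;
    }
    out[i] = node + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_draw_random_test(NumericMatrix Xnode, int kind, int edge,
                          double seed) {
  const int nrow = Xnode.nrow(), nattr = Xnode.ncol();
  std::vector<int> idx(nrow);
  for (int i = 0; i < nrow; ++i) idx[i] = i;
  ZsRng rng((uint64_t)(int64_t)seed);
  TestDraw t = draw_test(&Xnode[0], nrow, idx, nattr, edge, kind, rng);
  return List::create(
      _["kind"] = kind, _["attr"] = t.attr < 0 ? NA_INTEGER : t.attr + 1,
      _["attr2"] = t.attr2 < 0 ? NA_INTEGER : t.attr2 + 1,
      _["threshold"] = t.attr < 0 ? NA_REAL : t.thr,
      _["valid"] = t.attr >= 0);
}

// [[Rcpp::export]]
double cpp_split_score(IntegerVector left_y, IntegerVector right_y,
                       int n_classes) {
  std::vector<int> lc(n_classes, 0), rc(n_classes, 0);
  for (int v : left_y) lc[v]++;
  for (int v : right_y) rc[v]++;
  return score_counts(lc, (int)left_y.size(), rc, (int)right_y.size());
}
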