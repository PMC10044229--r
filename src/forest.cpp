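// Classification random forest: bagged CART trees with per-split feature
// subsampling (mtry), grown to purity, Gini splits. Out-of-bag class votes
// and Gini (impurity-decrease) importances are accumulated over trees.
// Uses R's RNG so set.seed() makes runs reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

inline double gini_impurity(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / n;
    s += p * p;
  }
  return 1.0 - s;
}

inline int rand_int(int n) {            // uniform on [0, n)
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;               // 0-based classes
  int n_classes, mtry;
  std::vector<Node> nodes;
  std::vector<double>& importance;      // accumulated Gini decrease

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K, int mtry_,
              std::vector<double>& imp)
      : X(X_), y(y_), n_classes(K), mtry(mtry_), importance(imp) {}

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> counts(n_classes, 0);
    for (int i = lo; i < hi; ++i) counts[y[idx[i]]]++;
    int node_id = static_cast<int>(nodes.size());
    nodes.emplace_back();
    int best_class = 0;
    for (int c = 1; c < n_classes; ++c)
      if (counts[c] > counts[best_class]) best_class = c;
    nodes[node_id].pred = best_class;

    double g_parent = gini_impurity(counts, n);
    if (n < 2 || g_parent <= 0.0) return node_id;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    // partial Fisher-Yates draw of mtry features
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + rand_int(p - j)]);

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> left_counts(n_classes);

    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i)
        vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
      std::sort(vals.begin(), vals.end());
      std::fill(left_counts.begin(), left_counts.end(), 0);
      for (int i = 0; i < n - 1; ++i) {
        left_counts[vals[i].second]++;
        if (vals[i + 1].first <= vals[i].first) continue;  // tied values
        int nl = i + 1, nr = n - nl;
        double gl = gini_impurity(left_counts, nl);
        std::vector<int> rc(n_classes);
        for (int c = 0; c < n_classes; ++c) rc[c] = counts[c] - left_counts[c];
        double gr = gini_impurity(rc, nr);
        double gain = g_parent * n - gl * nl - gr * nr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return node_id;   // no informative split available

    importance[best_feat] += best_gain;
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return node_id;  // numeric degeneracy guard

    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }

  int predict(int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
                ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

}  // namespace

// [[Rcpp::export(name = ".forest_oob")]]
List forest_oob(NumericMatrix X, IntegerVector y, int n_classes,
                int n_trees, int mtry) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  IntegerMatrix votes(n, n_classes);
  std::vector<char> in_bag(n);
  std::vector<int> idx;
  idx.reserve(n);

  GetRNGstate();
  for (int t = 0; t < n_trees; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    idx.resize(n);
    for (int i = 0; i < n; ++i) {
      int s = rand_int(n);
      idx[i] = s;
      in_bag[s] = 1;
    }
    TreeBuilder tb(X, y, n_classes, mtry, importance);
    tb.nodes.reserve(2 * n);
    tb.build(idx, 0, n);
    for (int i = 0; i < n; ++i)
      if (!in_bag[i]) votes(i, tb.predict(i))++;
  }
  PutRNGstate();

  IntegerVector oob_pred(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes(i, c) > votes(i, best)) best = c;
    oob_pred[i] = best;
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;
  return List::create(_["oob_pred"] = oob_pred, _["votes"] = votes,
                      _["importance"] = imp);
}
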