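// Forest of binary classification trees with a selectable impurity
// criterion (gini or entropy), best-split or random-split (extremely
// randomized) search, optional bootstrap resampling, and mean-decrease-in-
// impurity feature importances. Single-threaded, deterministic per seed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() { s ^= s << 13; s ^= s >> 7; s ^= s << 17; return s; }
  uint64_t next_below(uint64_t n) { return next() % n; }
  double next_unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double impurity(double n1, double n, bool entropy) {
  if (n <= 0.0) return 0.0;
  const double p1 = n1 / n, p0 = 1.0 - p1;
  if (entropy) {
    double h = 0.0;
    if (p0 > 0.0) h -= p0 * std::log2(p0);
    if (p1 > 0.0) h -= p1 * std::log2(p1);
    return h;
  }
  return 1.0 - p0 * p0 - p1 * p1;
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // class-1 fraction at node
};

struct Builder {
  const double* X;   // column-major, n_rows x n_features
  const int* y;
  int n_rows, n_features, mtry, min_split, max_depth;
  bool entropy_crit, random_split;
  double n_total;
  XorShift& rng;
  std::vector<double>& importance;
  Tree tree;
  std::vector<int> feat_order;  // scratch for mtry sampling
  std::vector<double> val_buf;  // contiguous gather of one feature's values
  std::vector<int> y_buf;

  Builder(const double* X_, const int* y_, int n_rows_, int n_features_,
          int mtry_, int min_split_, int max_depth_, bool entropy_,
          bool random_, double n_total_, XorShift& rng_,
          std::vector<double>& imp_)
      : X(X_), y(y_), n_rows(n_rows_), n_features(n_features_), mtry(mtry_),
        min_split(min_split_), max_depth(max_depth_), entropy_crit(entropy_),
        random_split(random_), n_total(n_total_), rng(rng_),
        importance(imp_) {
    feat_order.resize(n_features);
    for (int j = 0; j < n_features; ++j) feat_order[j] = j;
    val_buf.resize(n_rows);
    y_buf.resize(n_rows);
  }

  int new_node(double p1) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(p1);
    return static_cast<int>(tree.feature.size()) - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    const int n = static_cast<int>(idx.size());
    double n1 = 0.0;
    for (int i : idx) n1 += y[i];
    const int node = new_node(n1 / n);
    const double imp_parent = impurity(n1, n, entropy_crit);
    if (n < min_split || imp_parent <= 0.0 || depth >= max_depth) return node;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) {
      int k = j + static_cast<int>(rng.next_below(n_features - j));
      std::swap(feat_order[j], feat_order[k]);
    }

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    for (int j = 0; j < mtry; ++j) {
      const int f = feat_order[j];
      const double* col = X + static_cast<size_t>(f) * n_rows;
      // single gather into a contiguous scratch buffer
      double lo = col[idx[0]], hi = lo;
      for (int i = 0; i < n; ++i) {
        const double v = col[idx[i]];
        val_buf[i] = v;
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi <= lo) continue;
      if (random_split) {
        const double thr = lo + rng.next_unif() * (hi - lo);
        double nl = 0.0, nl1 = 0.0;
        for (int i = 0; i < n; ++i) {
          if (val_buf[i] <= thr) { nl += 1.0; nl1 += y[idx[i]]; }
        }
        const double nr = n - nl, nr1 = n1 - nl1;
        if (nl == 0.0 || nr == 0.0) continue;
        const double gain = imp_parent -
            (nl / n) * impurity(nl1, nl, entropy_crit) -
            (nr / n) * impurity(nr1, nr, entropy_crit);
        if (gain > best_gain) { best_gain = gain; best_feat = f; best_thr = thr; }
      } else {
        // exhaustive scan over sorted values
        std::vector<std::pair<double, int>> vals(n);
        for (int i = 0; i < n; ++i) vals[i] = {val_buf[i], y[idx[i]]};
        std::sort(vals.begin(), vals.end());
        double nl = 0.0, nl1 = 0.0;
        for (int i = 0; i + 1 < n; ++i) {
          nl += 1.0; nl1 += vals[i].second;
          if (vals[i].first == vals[i + 1].first) continue;
          const double nr = n - nl, nr1 = n1 - nl1;
          const double gain = imp_parent -
              (nl / n) * impurity(nl1, nl, entropy_crit) -
              (nr / n) * impurity(nr1, nr, entropy_crit);
          if (gain > best_gain) {
            best_gain = gain; best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }
    if (best_feat < 0) return node;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(n);
    right_idx.reserve(n);
    const double* bcol = X + static_cast<size_t>(best_feat) * n_rows;
    for (int i : idx) {
      if (bcol[i] <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return node;

    importance[best_feat] += (n / n_total) * best_gain;
    tree.feature[node] = best_feat;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(left_idx, depth + 1);
    tree.right[node] = build(right_idx, depth + 1);
    return node;
  }
};

} // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_split, int max_depth, bool entropy, bool random_split,
                bool bootstrap, int seed) {
  const int n = X.nrow();
  if (n == 0) stop("empty training set");
  XorShift rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  std::vector<double> importance(X.ncol(), 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = static_cast<int>(rng.next_below(n));
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Builder b(REAL(X), INTEGER(y), n, X.ncol(), mtry, min_split, max_depth,
              entropy, random_split, static_cast<double>(n) * n_trees, rng,
              importance);
    b.build(idx, 0);
    trees[t] = List::create(
        _["feature"] = wrap(b.tree.feature),
        _["threshold"] = wrap(b.tree.threshold),
        _["left"] = wrap(b.tree.left),
        _["right"] = wrap(b.tree.right),
        _["value"] = wrap(b.tree.value));
  }
  return List::create(_["trees"] = trees, _["importance"] = wrap(importance));
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= n_trees;
  return out;
}
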