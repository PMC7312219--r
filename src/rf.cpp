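// Random forest for binary classification: gini splits, bootstrap
// resampling, mtry random features per node, depth-limited trees,
// majority-vote prediction with deterministic tie-breaking (tie -> class 0).
// Implemented in C++ because the wrapper search evaluates thousands of
// channel subsets, each requiring folds x depths forests.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift64* : deterministic across platforms, independent of R's RNG
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int unif_int(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

struct Node {
  int feature = -1;   // -1 marks a leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

struct Tree {
  std::vector<Node> nodes;
};

double gini_after_split(int n1_left, int n_left, int n1_right, int n_right) {
  auto gini = [](int n1, int n) {
    if (n == 0) return 0.0;
    double p = (double)n1 / n;
    return 2.0 * p * (1.0 - p);
  };
  int n = n_left + n_right;
  return ((double)n_left / n) * gini(n1_left, n_left) +
         ((double)n_right / n) * gini(n1_right, n_right);
}

int build_node(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo, int hi, int depth,
               int max_depth, int mtry, XRng& rng, Tree& tree) {
  int node_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int majority = (2 * n1 > n) ? 1 : 0;  // tie -> class 0
  tree.nodes[node_id].pred = majority;
  if (n1 == 0 || n1 == n || depth >= max_depth || n < 2) return node_id;

  int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + rng.unif_int(p - j);
    std::swap(feats[j], feats[k]);
  }

  double parent_gini = gini_after_split(n1, n, 0, 0);
  double best_gini = parent_gini;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      vals[i] = {X(r, f), y[r]};
    }
    std::sort(vals.begin(), vals.end());
    int left1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      left1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      double g = gini_after_split(left1, i + 1, n1 - left1, n - i - 1);
      if (g < best_gini - 1e-12) {
        best_gini = g;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node_id;  // no impurity-reducing split found

  // partition idx[lo..hi) in place, preserving relative order (stable)
  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) left_idx.push_back(idx[i]);
    else right_idx.push_back(idx[i]);
  }
  if (left_idx.empty() || right_idx.empty()) return node_id;
  std::copy(left_idx.begin(), left_idx.end(), idx.begin() + lo);
  std::copy(right_idx.begin(), right_idx.end(),
            idx.begin() + lo + (int)left_idx.size());
  int mid = lo + (int)left_idx.size();

  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].thr = best_thr;
  int l = build_node(X, y, idx, lo, mid, depth + 1, max_depth, mtry, rng,
                     tree);
  int r = build_node(X, y, idx, mid, hi, depth + 1, max_depth, mtry, rng,
                     tree);
  tree.nodes[node_id].left = l;
  tree.nodes[node_id].right = r;
  return node_id;
}

int predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].thr)
              ? tree.nodes[cur].left
              : tree.nodes[cur].right;
  }
  return tree.nodes[cur].pred;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector rf_fit_predict(NumericMatrix X_train, IntegerVector y_train,
                             NumericMatrix X_test, int n_trees,
                             int max_depth, int mtry, double seed) {
  int n = X_train.nrow();
  int n_test = X_test.nrow();
  if (n != y_train.size()) {
    stop("X_train rows and y_train length differ");
  }
  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> votes(n_test, 0);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);  // bootstrap
    Tree tree;
    build_node(X_train, y_train, idx, 0, n, 0, max_depth, mtry, rng, tree);
    for (int i = 0; i < n_test; ++i) votes[i] += predict_tree(tree, X_test, i);
  }
  IntegerVector out(n_test);
  for (int i = 0; i < n_test; ++i) {
    out[i] = (2 * votes[i] > n_trees) ? 1 : 0;  // tie -> class 0
  }
  return out;
}
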