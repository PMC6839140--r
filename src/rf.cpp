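// Bagged classification trees with per-split feature subsampling and a
// best-first leaf cap, plus out-of-bag error. Self-contained deterministic
// RNG (splitmix64/xorshift) so a given seed reproduces the forest exactly,
// independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    // splitmix64
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = -1.0;
};

struct Node {
  std::vector<int> samples;  // row indices into X
  int node_id = -1;          // index in the flat tree arrays
  Split best;
};

inline double gini(int c1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(c1) / n;
  return 2.0 * p * (1.0 - p);
}

// Best split over `mtry` features sampled without replacement.
Split best_split(const NumericMatrix& X, const IntegerVector& y,
                 const std::vector<int>& samples, int mtry, Rng& rng) {
  int p = X.ncol();
  int n = static_cast<int>(samples.size());
  Split best;
  int c1 = 0;
  for (int i : samples) c1 += y[i];
  if (c1 == 0 || c1 == n) return best;  // pure node
  double g_parent = gini(c1, n);

  // partial Fisher-Yates over feature indices
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + rng.unif_int(p - j);
    std::swap(feats[j], feats[k]);
  }

  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(samples[i], f), y[samples[i]]};
    std::sort(vals.begin(), vals.end());
    int left_n = 0, left_c1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      left_n++;
      left_c1 += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue;  // tie on value
      int right_n = n - left_n, right_c1 = c1 - left_c1;
      double g = g_parent -
                 (left_n * gini(left_c1, left_n) +
                  right_n * gini(right_c1, right_n)) / n;
      if (g > best.gain + 1e-15) {
        best.gain = g;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best.gain <= 1e-12) best.feature = -1;
  return best;
}

struct Tree {
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
  int add_node() {
    feature.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    threshold.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

void set_leaf_pred(Tree& tree, int node, const IntegerVector& y,
                   const std::vector<int>& samples) {
  int c1 = 0;
  for (int i : samples) c1 += y[i];
  int c0 = static_cast<int>(samples.size()) - c1;
  tree.pred[node] = (c1 > c0) ? 1 : 0;  // ties -> class 0
}

// Grow one tree best-first until `max_leaves` leaves or no positive-gain
// split remains.
Tree grow_tree(const NumericMatrix& X, const IntegerVector& y,
               const std::vector<int>& boot, int max_leaves, int mtry,
               Rng& rng) {
  Tree tree;
  std::vector<Node> frontier;
  Node root;
  root.samples = boot;
  root.node_id = tree.add_node();
  set_leaf_pred(tree, root.node_id, y, root.samples);
  root.best = best_split(X, y, root.samples, mtry, rng);
  frontier.push_back(std::move(root));
  int leaves = 1;

  while (leaves < max_leaves) {
    int pick = -1;
    double best_gain = 0.0;
    for (size_t i = 0; i < frontier.size(); ++i) {
      if (frontier[i].best.feature >= 0 && frontier[i].best.gain > best_gain) {
        best_gain = frontier[i].best.gain;
        pick = static_cast<int>(i);
      }
    }
    if (pick < 0) break;
    Node node = std::move(frontier[pick]);
    frontier.erase(frontier.begin() + pick);

    Node lchild, rchild;
    for (int i : node.samples) {
      if (X(i, node.best.feature) <= node.best.threshold)
        lchild.samples.push_back(i);
      else
        rchild.samples.push_back(i);
    }
    tree.feature[node.node_id] = node.best.feature;
    tree.threshold[node.node_id] = node.best.threshold;
    lchild.node_id = tree.add_node();
    rchild.node_id = tree.add_node();
    tree.left[node.node_id] = lchild.node_id;
    tree.right[node.node_id] = rchild.node_id;
    set_leaf_pred(tree, lchild.node_id, y, lchild.samples);
    set_leaf_pred(tree, rchild.node_id, y, rchild.samples);
    lchild.best = best_split(X, y, lchild.samples, mtry, rng);
    rchild.best = best_split(X, y, rchild.samples, mtry, rng);
    frontier.push_back(std::move(lchild));
    frontier.push_back(std::move(rchild));
    ++leaves;
  }
  return tree;
}

int predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
               ? tree.left[node]
               : tree.right[node];
  }
  return tree.pred[node];
}

NumericMatrix pack_tree(const Tree& t) {
  int n = static_cast<int>(t.feature.size());
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.pred[i];
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "pred");
  return m;
}

Tree unpack_tree(const NumericMatrix& m) {
  Tree t;
  int n = m.nrow();
  t.feature.resize(n);
  t.threshold.resize(n);
  t.left.resize(n);
  t.right.resize(n);
  t.pred.resize(n);
  for (int i = 0; i < n; ++i) {
    t.feature[i] = static_cast<int>(m(i, 0));
    t.threshold[i] = m(i, 1);
    t.left[i] = static_cast<int>(m(i, 2));
    t.right[i] = static_cast<int>(m(i, 3));
    t.pred[i] = static_cast<int>(m(i, 4));
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int max_leaves,
                int mtry, double seed) {
  int n = X.nrow();
  Rng rng(static_cast<uint64_t>(seed));
  List trees(ntree);
  std::vector<int> oob0(n, 0), oob1(n, 0);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; ++i) {
      boot[i] = rng.unif_int(n);
      inbag[boot[i]] = true;
    }
    Tree tree = grow_tree(X, y, boot, max_leaves, mtry, rng);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        if (predict_one(tree, X, i) == 1)
          ++oob1[i];
        else
          ++oob0[i];
      }
    }
    trees[t] = pack_tree(tree);
  }

  int n_oob = 0, n_err = 0;
  NumericVector oob_score(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    int tot = oob0[i] + oob1[i];
    if (tot == 0) continue;
    ++n_oob;
    oob_score[i] = static_cast<double>(oob1[i]) / tot;
    int pred = (oob1[i] > oob0[i]) ? 1 : 0;
    if (pred != y[i]) ++n_err;
  }
  double oob_err = (n_oob > 0) ? static_cast<double>(n_err) / n_oob : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_error"] = oob_err,
                      _["oob_score"] = oob_score);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  int ntree = trees.size();
  NumericVector votes(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    Tree tree = unpack_tree(as<NumericMatrix>(trees[t]));
    for (int i = 0; i < n; ++i) votes[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) votes[i] /= ntree;
  return votes;
}
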