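// Compact CART random forest for two-class problems: bootstrap sampling,
// gini splits over mtry randomly drawn features, majority-vote leaves.
// Scores are case-vote fractions over trees, mirroring the vote-fraction
// output of classic random-forest implementations.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;      // -1 marks a leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

struct Tree {
  std::vector<Node> nodes;

  int predict(const double* row) const {
    int i = 0;
    while (nodes[i].feat >= 0) {
      i = (row[nodes[i].feat] <= nodes[i].thr) ? nodes[i].left : nodes[i].right;
    }
    return nodes[i].pred;
  }
};

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int mtry,
          int min_node, std::mt19937& rng)
      : X_(X), y_(y), p_(X.ncol()), mtry_(mtry), min_node_(min_node), rng_(rng) {}

  Tree build(std::vector<int>& idx) {
    tree_.nodes.clear();
    grow(idx, 0, static_cast<int>(idx.size()));
    return tree_;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int p_, mtry_, min_node_;
  std::mt19937& rng_;
  Tree tree_;
  std::vector<int> feat_pool_;

  int leaf(int n1, int n) {
    Node nd;
    int n0 = n - n1;
    if (n1 > n0) nd.pred = 1;
    else if (n1 < n0) nd.pred = 0;
    else nd.pred = static_cast<int>(rng_() & 1u);  // tie broken at random
    tree_.nodes.push_back(nd);
    return static_cast<int>(tree_.nodes.size()) - 1;
  }

  // Grow on idx[lo, hi); returns node index.
  int grow(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y_[idx[i]];
    if (n1 == 0 || n1 == n || n < 2 * min_node_) return leaf(n1, n);

    // sample mtry features without replacement
    if (static_cast<int>(feat_pool_.size()) != p_) {
      feat_pool_.resize(p_);
      for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
    }
    for (int j = 0; j < mtry_; ++j) {
      std::uniform_int_distribution<int> pick(j, p_ - 1);
      std::swap(feat_pool_[j], feat_pool_[pick(rng_)]);
    }

    int best_feat = -1;
    double best_thr = 0.0, best_score = -1.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry_; ++j) {
      int f = feat_pool_[j];
      for (int i = 0; i < n; ++i) {
        vals[i] = {X_(idx[lo + i], f), y_[idx[lo + i]]};
      }
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl, r1 = n1 - l1;
        // decrease in gini impurity up to constants: maximize sum of
        // per-child (count of class 1)^2/n + (count of class 0)^2/n
        double score =
            (static_cast<double>(l1) * l1 + static_cast<double>(nl - l1) * (nl - l1)) / nl +
            (static_cast<double>(r1) * r1 + static_cast<double>(nr - r1) * (nr - r1)) / nr;
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_feat < 0) return leaf(n1, n);  // all sampled features constant

    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X_(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) return leaf(n1, n);

    Node nd;
    nd.feat = best_feat;
    nd.thr = best_thr;
    int self = static_cast<int>(tree_.nodes.size());
    tree_.nodes.push_back(nd);
    int left = grow(idx, lo, mid);
    int right = grow(idx, mid, hi);
    tree_.nodes[self].left = left;
    tree_.nodes[self].right = right;
    return self;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_vote", rng = false)]]
NumericVector rf_vote(NumericMatrix X_train, IntegerVector y_train,
                      NumericMatrix X_test, int n_trees, int mtry,
                      int min_node, int seed) {
  const int n = X_train.nrow(), m = X_test.nrow(), p = X_train.ncol();
  if (y_train.size() != n) stop("y_train length must match X_train rows");
  if (X_test.ncol() != p) stop("X_test must have the same features as X_train");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng(static_cast<unsigned>(seed));

  // balanced bootstrap: each tree draws min(n1, n0) samples with replacement
  // from each class, so vote fractions are not biased by class imbalance
  // (important for leave-one-out folds, where classes differ by one).
  std::vector<int> class1, class0;
  for (int i = 0; i < n; ++i) (y_train[i] == 1 ? class1 : class0).push_back(i);
  if (class1.empty() || class0.empty()) stop("both classes required in training data");
  const int k = static_cast<int>(std::min(class1.size(), class0.size()));
  std::uniform_int_distribution<int> boot1(0, static_cast<int>(class1.size()) - 1);
  std::uniform_int_distribution<int> boot0(0, static_cast<int>(class0.size()) - 1);

  NumericVector votes(m, 0.0);
  std::vector<int> idx(2 * k);
  std::vector<double> row(p);
  Builder builder(X_train, y_train, mtry, min_node, rng);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < k; ++i) {
      idx[i] = class1[boot1(rng)];
      idx[k + i] = class0[boot0(rng)];
    }
    Tree tree = builder.build(idx);
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < p; ++j) row[j] = X_test(i, j);
      votes[i] += tree.predict(row.data());
    }
  }
  for (int i = 0; i < m; ++i) votes[i] /= n_trees;
  return votes;
}
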