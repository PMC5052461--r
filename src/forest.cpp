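#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Self-contained RNG (splitmix64 seeded xorshift128+) so forests are
// reproducible from an integer seed and independent of R's RNG state.
namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 to spread a small seed over both words
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t; else s1 = t;
    }
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform integer in [0, n)
  int randint(int n) { return (int)(next() % (uint64_t)n); }
};

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= thr
  std::vector<int> left, right;
  std::vector<double> probs;     // K entries per node (only leaves used)
};

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y; // 0..K-1
  int K, mtry, min_node, max_depth, p;
  Rng &rng;
  TreeBuf &tree;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix &X_, const IntegerVector &y_, int K_, int mtry_,
         int min_node_, int max_depth_, Rng &rng_, TreeBuf &t_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), p(X_.ncol()), rng(rng_), tree(t_) {
    feat_pool.resize(p);
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
  }

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    for (int k = 0; k < K; ++k) tree.probs.push_back(0.0);
    return (int)tree.feature.size() - 1;
  }

  void make_leaf(int node, const std::vector<int> &counts, int n) {
    for (int k = 0; k < K; ++k)
      tree.probs[(size_t)node * K + k] = (double)counts[k] / (double)n;
  }

  // gini impurity of counts summing to n, times n (so it is additive)
  static double gini_n(const std::vector<int> &counts, int n) {
    if (n == 0) return 0.0;
    double s = 0.0;
    for (size_t k = 0; k < counts.size(); ++k)
      s += (double)counts[k] * (double)counts[k];
    return (double)n - s / (double)n;
  }

  int grow(std::vector<int> &idx, int depth) {
    int node = new_node();
    int n = (int)idx.size();
    std::vector<int> counts(K, 0);
    for (int i = 0; i < n; ++i) counts[y[idx[i]]]++;
    int n_classes = 0;
    for (int k = 0; k < K; ++k) if (counts[k] > 0) n_classes++;
    if (n_classes <= 1 || n < 2 * min_node || depth >= max_depth) {
      make_leaf(node, counts, n);
      return node;
    }

    double parent_imp = gini_n(counts, n);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int> > vals(n);
    std::vector<int> lc(K);
    // sample mtry distinct candidate features (partial Fisher-Yates)
    for (int m = 0; m < mtry; ++m) {
      int j = m + rng.randint(p - m);
      std::swap(feat_pool[m], feat_pool[j]);
      int f = feat_pool[m];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++;
        nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node || n - nl < min_node) continue;
        // children impurity (additive form)
        double sl = 0.0, sr = 0.0;
        for (int k = 0; k < K; ++k) {
          sl += (double)lc[k] * lc[k];
          sr += (double)(counts[k] - lc[k]) * (counts[k] - lc[k]);
        }
        double child_imp =
            ((double)nl - sl / nl) + ((double)(n - nl) - sr / (n - nl));
        double gain = parent_imp - child_imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }

    if (best_feat < 0) {
      make_leaf(node, counts, n);
      return node;
    }

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_feat) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    if (li.empty() || ri.empty()) { // numeric edge case
      make_leaf(node, counts, n);
      return node;
    }
    tree.feature[node] = best_feat;
    tree.threshold[node] = best_thr;
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, IntegerVector y, int K, int n_trees, int mtry,
             int min_node, int max_depth, int seed) {
  int n = X.nrow();
  if (y.size() != n) stop("X and y disagree on n");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");
  List trees(n_trees);
  Rng rng((uint64_t)seed * 0x5DEECE66DULL + 11ULL);
  for (int t = 0; t < n_trees; ++t) {
    // bootstrap sample
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.randint(n);
    TreeBuf tb;
    Grower g(X, y, K, mtry, min_node, max_depth, rng, tb);
    g.grow(idx, 0);
    trees[t] = List::create(
        Named("feature") = IntegerVector(tb.feature.begin(), tb.feature.end()),
        Named("threshold") =
            NumericVector(tb.threshold.begin(), tb.threshold.end()),
        Named("left") = IntegerVector(tb.left.begin(), tb.left.end()),
        Named("right") = IntegerVector(tb.right.begin(), tb.right.end()),
        Named("probs") = NumericVector(tb.probs.begin(), tb.probs.end()));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericMatrix rf_predict(List forest, NumericMatrix X, int K) {
  int n = X.nrow(), T = forest.size();
  NumericMatrix out(n, K);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector probs = tr["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      for (int k = 0; k < K; ++k) out(i, k) += probs[node * K + k];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) out(i, k) /= (double)T;
  return out;
}
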