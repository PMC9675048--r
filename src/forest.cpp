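// Minimal deterministic CART / bagging random forest.
//
// Regression trees with variance-reduction splits, per-split feature
// subsampling (mtry), bootstrap resampling, per-variable split counts and
// impurity (SSE-reduction) importance. Binary outcomes are handled as
// regression on {0,1}; leaf means are probabilities.
//
// Kept self-contained (no armadillo): the package needs access to split
// variables per tree for importance tallies, which CRAN forests don't expose
// uniformly.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int var;        // -1 for leaf
  double split;   // go left if x <= split
  int left, right;
  double pred;
};

struct TreeGrower {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double>& imp;     // SSE reduction per variable (accumulated)
  std::vector<int>& splits;     // split count per variable (accumulated)

  TreeGrower(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
             int min_node_, int max_depth_, std::mt19937& rng_,
             std::vector<double>& imp_, std::vector<int>& splits_)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
      rng(rng_), imp(imp_), splits(splits_) {}

  int grow(std::vector<int>& idx, int lo, int hi, int depth) {
    const int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; sum2 += y[idx[i]] * y[idx[i]]; }
    const double mean = sum / n;
    const double sse = sum2 - sum * sum / n;

    Node node; node.var = -1; node.split = 0.0; node.left = node.right = -1;
    node.pred = mean;
    const int me = (int)nodes.size();
    nodes.push_back(node);

    if (n < 2 * min_node || depth >= max_depth || sse <= 1e-12) return me;

    // candidate features: mtry sampled without replacement
    const int d = X.ncol();
    std::vector<int> feats(d);
    for (int j = 0; j < d; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < d; ++j) {
      std::uniform_int_distribution<int> pick(j, d - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }

    double best_gain = 1e-10;  // require strictly positive gain
    int best_var = -1; double best_split = 0.0;

    std::vector<std::pair<double, double> > xy(n);
    for (int t = 0; t < mtry && t < d; ++t) {
      const int j = feats[t];
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(idx[lo + i], j), y[idx[lo + i]]);
      std::sort(xy.begin(), xy.end());
      if (xy[0].first == xy[n - 1].first) continue;
      double sl = 0.0; int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second; ++nl;
        if (xy[i].first == xy[i + 1].first) continue;
        const int nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = j;
          best_split = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_var < 0) return me;

    // partition idx[lo,hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_var) <= best_split) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return me;  // numerical guard

    imp[best_var] += best_gain;
    splits[best_var] += 1;
    nodes[me].var = best_var;
    nodes[me].split = best_split;
    nodes[me].left = grow(idx, lo, mid, depth + 1);
    nodes[me].right = grow(idx, mid, hi, depth + 1);
    return me;
  }
};

double predict_one(const IntegerVector& var, const NumericVector& split,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericVector& pred, const NumericMatrix& X, int row) {
  int node = 0;
  while (var[node] >= 0)
    node = (X(row, var[node]) <= split[node]) ? left[node] : right[node];
  return pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth, double sample_frac, bool replace,
                int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> imp(d, 0.0);
  std::vector<int> split_counts(d, 0);
  List trees(ntree);
  const int nsamp = std::max(2, (int)std::lround(sample_frac * n));

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    idx.reserve(nsamp);
    if (replace) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int i = 0; i < nsamp; ++i) idx.push_back(pick(rng));
    } else {
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      for (int i = 0; i < nsamp; ++i) {
        std::uniform_int_distribution<int> pick(i, n - 1);
        std::swap(all[i], all[pick(rng)]);
      }
      idx.assign(all.begin(), all.begin() + nsamp);
    }
    TreeGrower g(X, y, mtry, min_node, max_depth, rng, imp, split_counts);
    g.grow(idx, 0, (int)idx.size(), 0);
    const int m = (int)g.nodes.size();
    IntegerVector var(m), left(m), right(m);
    NumericVector split(m), pred(m);
    for (int i = 0; i < m; ++i) {
      var[i] = g.nodes[i].var; split[i] = g.nodes[i].split;
      left[i] = g.nodes[i].left; right[i] = g.nodes[i].right;
      pred[i] = g.nodes[i].pred;
    }
    trees[t] = List::create(_["var"] = var, _["split"] = split,
                            _["left"] = left, _["right"] = right,
                            _["pred"] = pred);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(imp.begin(), imp.end()),
                      _["split_counts"] = IntegerVector(split_counts.begin(),
                                                        split_counts.end()));
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector split = tr["split"], pred = tr["pred"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_one(var, split, left, right, pred, X, i);
  }
  return out / (double)ntree;
}
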