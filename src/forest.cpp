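#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted bagged-CART probability forest for a binary outcome.
//
// Each tree is grown on a bootstrap resample of the rows, splitting on the
// weighted Gini criterion with axis-aligned cuts at midpoints between
// consecutive distinct feature values. Case weights enter both the split
// criterion and the leaf class-1 probability (weighted fraction of events),
// which is what makes the forest minimize a weighted empirical loss: a
// record with weight rho contributes like rho duplicated records.
//
// All randomness (bootstrap rows, feature subsampling) is drawn from R's
// RNG, so behaviour is fully determined by set.seed() on the R side.

struct TreeNode {
  int feature;    // -1 for leaf
  double thr;     // go left iff x[feature] < thr
  int left, right;
  double pred;    // weighted P(y = 1) in node
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int mtry, max_depth, min_node;
  std::vector<TreeNode> nodes;

  Builder(const NumericMatrix& X_, const IntegerVector& y_,
          const NumericVector& w_, int mtry_, int max_depth_, int min_node_)
    : X(X_), y(y_), w(w_), mtry(mtry_), max_depth(max_depth_),
      min_node(min_node_) {}

  int build(std::vector<int>& idx, int depth) {
    double W = 0.0, P = 0.0;
    for (int i : idx) { W += w[i]; P += w[i] * y[i]; }
    double pred = (W > 0.0) ? P / W : 0.0;

    int self = (int)nodes.size();
    nodes.push_back(TreeNode{-1, 0.0, -1, -1, pred});

    int nIdx = (int)idx.size();
    if (depth >= max_depth || nIdx < 2 * min_node || P <= 0.0 || P >= W)
      return self;

    // candidate features: sample mtry without replacement via R RNG
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int nf = std::min(mtry, p);
    for (int j = 0; j < nf; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double bestScore = P * P / W + (W - P) * (W - P) / W;  // no-split score
    int bestF = -1;
    double bestThr = 0.0;
    std::vector<std::pair<double, int> > vals(nIdx);

    for (int fj = 0; fj < nf; ++fj) {
      int f = feats[fj];
      for (int a = 0; a < nIdx; ++a) vals[a] = std::make_pair(X(idx[a], f), idx[a]);
      std::sort(vals.begin(), vals.end());
      double WL = 0.0, PL = 0.0;
      for (int a = 0; a < nIdx - 1; ++a) {
        int i = vals[a].second;
        WL += w[i]; PL += w[i] * y[i];
        if (vals[a + 1].first <= vals[a].first) continue;   // no cut here
        int nL = a + 1, nR = nIdx - nL;
        if (nL < min_node || nR < min_node) continue;
        double WR = W - WL, PR = P - PL;
        if (WL <= 0.0 || WR <= 0.0) continue;
        double score = PL * PL / WL + (WL - PL) * (WL - PL) / WL +
                       PR * PR / WR + (WR - PR) * (WR - PR) / WR;
        if (score > bestScore + 1e-12) {
          bestScore = score;
          bestF = f;
          bestThr = 0.5 * (vals[a].first + vals[a + 1].first);
        }
      }
    }
    if (bestF < 0) return self;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, bestF) < bestThr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return self;

    nodes[self].feature = bestF;
    nodes[self].thr = bestThr;
    int l = build(li, depth + 1);
    nodes[self].left = l;
    int r = build(ri, depth + 1);
    nodes[self].right = r;
    return self;
  }
};

static List tree_to_list(const std::vector<TreeNode>& nodes) {
  int k = (int)nodes.size();
  IntegerVector feature(k), left(k), right(k);
  NumericVector thr(k), pred(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = nodes[i].feature;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["thr"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["pred"] = pred);
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, NumericVector w,
                    int ntree, int mtry, int max_depth, int min_node) {
  int n = X.nrow();
  if (n == 0) stop("cpp_forest_fit: empty training set");
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Builder b(X, y, w, mtry, max_depth, min_node);
    b.nodes.reserve(64);
    std::vector<int> root_idx = idx;
    b.build(root_idx, 0);
    forest[t] = tree_to_list(b.nodes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) < thr[node]) ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
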