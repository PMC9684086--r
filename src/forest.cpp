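#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

// Regression random forest: CART trees grown on bootstrap resamples with a
// random feature subset (mtry) scanned at every node. Conventions follow the
// classic randomForest regression defaults: ntree = 500, mtry = floor(p/3),
// nodesize = 5 (nodes at or below this size become leaves). Importance is the
// total within-tree decrease in node sum-of-squares attributed to each
// feature, averaged over trees ("IncNodePurity" style).
//
// The forest is fit and applied in one call (fit on Xtr/ytr, predict Xte);
// trees are not serialized across the R boundary, which keeps the hot loops
// in C++ for the cross-validation and permutation-test callers.

namespace {

// xorshift64* PRNG: deterministic across platforms, cheap, seedable per tree.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  double value;     // leaf prediction (node mean)
  int left, right;  // child node ids
};

struct Tree {
  std::vector<Node> nodes;
};

struct Builder {
  const Rcpp::NumericMatrix& X;
  const std::vector<double>& y;
  int p, mtry, nodesize;
  Rng& rng;
  std::vector<int> idx;        // sample indices, partitioned in place
  std::vector<int> feat_pool;  // feature ids for mtry draws
  std::vector<std::pair<double, double>> buf; // (x, y) sort buffer
  std::vector<double>& importance;            // accumulated SSE decrease per feature
  Tree tree;

  Builder(const Rcpp::NumericMatrix& X_, const std::vector<double>& y_, int mtry_,
          int nodesize_, Rng& rng_, std::vector<double>& imp)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), nodesize(nodesize_), rng(rng_),
        feat_pool(p), importance(imp) {
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
  }

  int build(int lo, int hi) {
    int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      double v = y[idx[i]];
      sum += v;
      sum2 += v * v;
    }
    double mean = sum / n;
    double sse = sum2 - sum * sum / n;

    int id = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back({-1, 0.0, mean, -1, -1});
    if (n <= nodesize || sse <= 1e-12) return id;

    // draw mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) {
      int k = j + rng.below(p - j);
      std::swap(feat_pool[j], feat_pool[k]);
    }

    int best_f = -1;
    double best_dec = 1e-12, best_thr = 0.0;
    for (int j = 0; j < mtry; ++j) {
      int f = feat_pool[j];
      buf.clear();
      for (int i = lo; i < hi; ++i)
        buf.emplace_back(X(idx[i], f), y[idx[i]]);
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      double lsum = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        lsum += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double rsum = sum - lsum;
        double dec = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = (buf[i].first + buf[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return id;

    importance[best_f] += best_dec;
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[mid++], idx[i]);
    // guard against degenerate partitions from float midpoints
    if (mid == lo || mid == hi) return id;

    tree.nodes[id].feature = best_f;
    tree.nodes[id].threshold = best_thr;
    int l = build(lo, mid);
    tree.nodes[id].left = l;
    int r = build(mid, hi);
    tree.nodes[id].right = r;
    return id;
  }
};

double predict_one(const Tree& t, const Rcpp::NumericMatrix& X, int row) {
  int id = 0;
  while (t.nodes[id].feature >= 0)
    id = (X(row, t.nodes[id].feature) <= t.nodes[id].threshold) ? t.nodes[id].left
                                                                : t.nodes[id].right;
  return t.nodes[id].value;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
Rcpp::List rf_fit_predict(Rcpp::NumericMatrix Xtr, Rcpp::NumericVector ytr,
                          Rcpp::NumericMatrix Xte, int ntree, int mtry,
                          int nodesize, double seed) {
  int n = Xtr.nrow(), p = Xtr.ncol();
  if (ytr.size() != n) Rcpp::stop("length(y) must match nrow(X)");
  if (Xte.ncol() != p) Rcpp::stop("train/test feature count mismatch");
  if (n < 2) Rcpp::stop("need at least 2 training samples");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (nodesize < 1) nodesize = 1;

  std::vector<double> y(ytr.begin(), ytr.end());
  std::vector<double> imp(p, 0.0);
  Rcpp::NumericVector pred(Xte.nrow());
  Rng master(static_cast<uint64_t>(seed) + 0x5DEECE66DULL);

  for (int t = 0; t < ntree; ++t) {
    Rng rng(master.next());
    std::vector<double> tree_imp(p, 0.0);
    Builder b(Xtr, y, mtry, nodesize, rng, tree_imp);
    b.idx.resize(n);
    for (int i = 0; i < n; ++i) b.idx[i] = rng.below(n); // bootstrap resample
    b.build(0, n);
    for (int j = 0; j < p; ++j) imp[j] += tree_imp[j];
    for (int i = 0; i < Xte.nrow(); ++i) pred[i] += predict_one(b.tree, Xte, i);
  }
  for (int i = 0; i < Xte.nrow(); ++i) pred[i] /= ntree;
  Rcpp::NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  return Rcpp::List::create(Rcpp::Named("predictions") = pred,
                            Rcpp::Named("importance") = importance);
}
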