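// Random forest for binary pixel classification.
//
// Classification trees use histogram (quantile-binned) split search with
// Gini impurity, bootstrap resampling and per-node random feature
// subsampling. Binned search keeps the cost of a fit at O(n * mtry) per
// node level, which is what makes wrapper feature selection with per-
// candidate 10-fold cross-validation tractable on a single CPU. For
// external use thresholds are stored as real bin-edge values, so
// prediction runs on raw features; the cross-validation entry point bins
// its input once and trains/predicts on bin indices directly.
//
// A self-contained splitmix64 RNG keeps fits bit-reproducible for a given
// seed across platforms, independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {  // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature;      // -1 for leaf
  int bin;          // split bin: go left if bin(x) <= bin
  double threshold; // raw-value equivalent: go left if x <= threshold
  int left, right;
  double pred;      // positive-class fraction at the leaf
};

struct Binned {
  int n, d;
  std::vector<uint8_t> bin;               // n x d, column-major
  std::vector<std::vector<double>> edges; // per feature: upper edges
};

Binned bin_data(const NumericMatrix& X, int nbins) {
  Binned B;
  B.n = X.nrow();
  B.d = X.ncol();
  B.bin.resize(static_cast<size_t>(B.n) * B.d);
  B.edges.resize(B.d);
  std::vector<double> col(B.n), sorted(B.n);
  for (int j = 0; j < B.d; ++j) {
    for (int i = 0; i < B.n; ++i) col[i] = X(i, j);
    sorted = col;
    std::sort(sorted.begin(), sorted.end());
    std::vector<double>& ed = B.edges[j];
    for (int b = 1; b < nbins; ++b) {
      size_t q = static_cast<size_t>(
          std::floor(static_cast<double>(b) / nbins * (B.n - 1)));
      double e = sorted[q];
      if (ed.empty() || e > ed.back()) ed.push_back(e);
    }
    for (int i = 0; i < B.n; ++i) {
      B.bin[static_cast<size_t>(j) * B.n + i] = static_cast<uint8_t>(
          std::lower_bound(ed.begin(), ed.end(), col[i]) - ed.begin());
    }
  }
  return B;
}

struct TreeBuilder {
  const Binned& B;
  const int* y;
  int mtry, max_depth, min_node;
  Rng& rng;
  std::vector<Node> nodes;
  std::vector<int> feat_pool;

  TreeBuilder(const Binned& B_, const int* y_, int mtry_, int max_depth_,
              int min_node_, Rng& rng_)
      : B(B_), y(y_), mtry(mtry_), max_depth(max_depth_), min_node(min_node_),
        rng(rng_), feat_pool(B_.d) {
    for (int j = 0; j < B.d; ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    int n = hi - lo, pos = 0;
    for (int i = lo; i < hi; ++i) pos += y[idx[i]];
    int id = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0, 0.0, -1, -1, static_cast<double>(pos) / n});
    if (pos == 0 || pos == n || n < 2 * min_node ||
        (max_depth > 0 && depth >= max_depth))
      return id;

    for (int k = 0; k < mtry; ++k)  // partial Fisher-Yates
      std::swap(feat_pool[k], feat_pool[k + rng.below(B.d - k)]);

    double best_gain = 1e-12;
    int best_f = -1, best_bin = -1;
    int cnt[256], cpos[256];
    for (int k = 0; k < mtry; ++k) {
      int j = feat_pool[k];
      int nb = static_cast<int>(B.edges[j].size()) + 1;
      if (nb < 2) continue;
      std::fill(cnt, cnt + nb, 0);
      std::fill(cpos, cpos + nb, 0);
      const uint8_t* bj = &B.bin[static_cast<size_t>(j) * B.n];
      for (int i = lo; i < hi; ++i) {
        int b = bj[idx[i]];
        ++cnt[b];
        cpos[b] += y[idx[i]];
      }
      double parent = static_cast<double>(pos) * (n - pos) / n;
      int ln = 0, lp = 0;
      for (int b = 0; b < nb - 1; ++b) {
        ln += cnt[b];
        lp += cpos[b];
        if (ln < min_node || n - ln < min_node) continue;
        if (ln == 0 || ln == n) continue;
        double gl = static_cast<double>(lp) * (ln - lp) / ln;
        int rn = n - ln, rp = pos - lp;
        double gr = static_cast<double>(rp) * (rn - rp) / rn;
        double gain = parent - gl - gr;  // Gini decrease * n/2
        if (gain > best_gain) {
          best_gain = gain;
          best_f = j;
          best_bin = b;
        }
      }
    }
    if (best_f < 0) return id;

    const uint8_t* bf = &B.bin[static_cast<size_t>(best_f) * B.n];
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (bf[idx[i]] <= best_bin) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return id;

    nodes[id].feature = best_f;
    nodes[id].bin = best_bin;
    nodes[id].threshold = B.edges[best_f][best_bin];
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

typedef std::vector<std::vector<Node>> Forest;

// grow a forest from (a subset of) pre-binned rows
Forest grow(const Binned& B, const int* y, const std::vector<int>& rows,
            int ntree, int mtry, int max_depth, int min_node, uint64_t seed) {
  Forest forest(ntree);
  int n = static_cast<int>(rows.size());
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    Rng rng(seed * 0x100000001B3ULL + t + 1);
    for (int i = 0; i < n; ++i) idx[i] = rows[rng.below(n)];  // bootstrap
    TreeBuilder tb(B, y, mtry, max_depth, min_node, rng);
    tb.nodes.reserve(64);
    tb.build(idx, 0, n, 0);
    forest[t] = std::move(tb.nodes);
  }
  return forest;
}

// majority-vote fraction for pre-binned row i
double vote_binned(const Forest& forest, const Binned& B, int i) {
  int votes = 0;
  for (size_t t = 0; t < forest.size(); ++t) {
    const std::vector<Node>& tree = forest[t];
    int node = 0;
    while (tree[node].feature >= 0) {
      const uint8_t b = B.bin[static_cast<size_t>(tree[node].feature) * B.n + i];
      node = b <= tree[node].bin ? tree[node].left : tree[node].right;
    }
    if (tree[node].pred >= 0.5) ++votes;
  }
  return static_cast<double>(votes) / forest.size();
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int max_depth, int min_node, int nbins, double seed) {
  Binned B = bin_data(X, nbins);
  std::vector<int> yy(y.begin(), y.end());
  std::vector<int> rows(B.n);
  for (int i = 0; i < B.n; ++i) rows[i] = i;
  Forest forest = grow(B, yy.data(), rows, ntree, mtry, max_depth, min_node,
                       static_cast<uint64_t>(seed));
  List out(ntree);
  for (int t = 0; t < ntree; ++t) {
    const std::vector<Node>& nodes = forest[t];
    NumericMatrix m(static_cast<int>(nodes.size()), 5);
    for (size_t i = 0; i < nodes.size(); ++i) {
      m(i, 0) = nodes[i].feature;
      m(i, 1) = nodes[i].threshold;
      m(i, 2) = nodes[i].left;
      m(i, 3) = nodes[i].right;
      m(i, 4) = nodes[i].pred;
    }
    out[t] = m;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_vote_cpp")]]
NumericVector rf_vote_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tree(node, 0) >= 0) {
        int f = static_cast<int>(tree(node, 0));
        node = static_cast<int>(X(i, f) <= tree(node, 1) ? tree(node, 2)
                                                         : tree(node, 3));
      }
      if (tree(node, 4) >= 0.5) out[i] += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Cross-validated skin-class F-score and error rate: the input is binned
// once (quantile edges from the whole fitness subsample; edges carry no
// label information), then one forest is trained per fold on the
// complement and scores held-out pixels at vote threshold 0.5.
// `fold` holds 1-based fold assignments.
// [[Rcpp::export(name = ".rf_cv_cpp")]]
NumericVector rf_cv_cpp(NumericMatrix X, IntegerVector y, IntegerVector fold,
                        int ntree, int mtry, int max_depth, int min_node,
                        int nbins, double seed) {
  int n = X.nrow();
  Binned B = bin_data(X, nbins);
  std::vector<int> yy(y.begin(), y.end());
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i]);
  double f_sum = 0.0, e_sum = 0.0;
  int used = 0;
  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    if (tr.empty() || te.empty()) continue;
    Forest forest = grow(B, yy.data(), tr, ntree, mtry, max_depth, min_node,
                         static_cast<uint64_t>(seed) + f);
    long tp = 0, fp = 0, fn = 0, err = 0;
    for (size_t i = 0; i < te.size(); ++i) {
      int pred = vote_binned(forest, B, te[i]) >= 0.5 ? 1 : 0;
      int truth = yy[te[i]];
      if (pred != truth) ++err;
      if (pred == 1 && truth == 1) ++tp;
      else if (pred == 1) ++fp;
      else if (truth == 1) ++fn;
    }
    double denom = 2.0 * tp + fp + fn;
    f_sum += denom > 0 ? 2.0 * tp / denom : 0.0;
    e_sum += static_cast<double>(err) / te.size();
    ++used;
  }
  if (used == 0) stop("no usable folds");
  return NumericVector::create(f_sum / used, e_sum / used);
}
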