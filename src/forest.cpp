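#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Binary-classification random forest with out-of-bag (OOB) estimation and
// Breiman-style permutation importance measured as the mean increase in the
// misclassification probability over trees, each tree evaluated on its own
// OOB rows. Implemented here because the method requires per-tree OOB
// bookkeeping that must stay under the package's control (reproducible
// R-RNG streams, deterministic tie-breaks).
//
// Class labels are 0/1; label 0 is the reference ("positive") class.
// All randomness draws from R's RNG so set.seed() on the R side fixes
// the forest bit-for-bit.

struct Node {
  int feat;      // split feature, -1 for leaf
  double thr;    // go left if x <= thr
  int left, right;
  int pred;      // leaf prediction (majority class; tie -> class 0)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> oob;        // row indices out of the bootstrap sample
  std::vector<char> used;      // length p, 1 if feature appears in a split
};

struct Forest {
  int n, p, ntree;
  std::vector<Tree> trees;
};

static int rand_int(int n) {
  // uniform integer in [0, n); rejection not needed at these sizes
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// weighted Gini impurity of a two-way split given class counts
static inline double gini_impurity(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return n * (1.0 - p0 * p0 - p1 * p1);
}

static int grow_node(Tree& tree, const NumericMatrix& x, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi,
                     int mtry, int min_node,
                     std::vector<int>& feat_pool,
                     std::vector<std::pair<double,int>>& buf) {
  int n = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
  int c0 = n - c1;

  int self = (int)tree.nodes.size();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, (c1 > c0) ? 1 : 0});

  if (c0 == 0 || c1 == 0 || n < std::max(2, min_node)) return self;

  int p = x.ncol();
  // sample mtry distinct features (partial Fisher-Yates on the pool)
  for (int i = 0; i < p; ++i) feat_pool[i] = i;
  int best_feat = -1;
  double best_thr = 0.0, best_score = R_PosInf;
  double parent_score = gini_impurity((double)c0, (double)c1);

  for (int m = 0; m < mtry; ++m) {
    int j = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[j]);
    int f = feat_pool[m];

    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(x(idx[i], f), idx[i]));
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue; // constant in node

    double l0 = 0.0, l1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      if (y[buf[i].second] == 1) l1 += 1.0; else l0 += 1.0;
      if (buf[i].first == buf[i + 1].first) continue;
      double score = gini_impurity(l0, l1) +
                     gini_impurity((double)c0 - l0, (double)c1 - l1);
      if (score < best_score) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }

  if (best_feat < 0 || best_score >= parent_score) return self;

  // partition idx[lo..hi) in place around the split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (x(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return self; // numerically degenerate

  tree.nodes[self].feat = best_feat;
  tree.nodes[self].thr = best_thr;
  tree.used[best_feat] = 1;
  int l = grow_node(tree, x, y, idx, lo, mid, mtry, min_node, feat_pool, buf);
  tree.nodes[self].left = l;
  int r = grow_node(tree, x, y, idx, mid, hi, mtry, min_node, feat_pool, buf);
  tree.nodes[self].right = r;
  return self;
}

static int predict_row(const Tree& tree, const NumericMatrix& x, int row,
                       int perm_feat = -1, double perm_val = 0.0) {
  int node = 0;
  for (;;) {
    const Node& nd = tree.nodes[node];
    if (nd.feat < 0) return nd.pred;
    double v = (nd.feat == perm_feat) ? perm_val : x(row, nd.feat);
    node = (v <= nd.thr) ? nd.left : nd.right;
  }
}

// [[Rcpp::export]]
SEXP rf_fit(NumericMatrix x, IntegerVector y, int ntree, int mtry, int min_node) {
  int n = x.nrow(), p = x.ncol();
  RNGScope scope;
  Forest* forest = new Forest();
  forest->n = n; forest->p = p; forest->ntree = ntree;
  forest->trees.resize(ntree);

  std::vector<int> idx;
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double,int>> buf;
  std::vector<char> inbag(n);

  for (int t = 0; t < ntree; ++t) {
    Tree& tree = forest->trees[t];
    tree.used.assign(p, 0);
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int k = rand_int(n);
      inbag[k] = 1;
      idx.push_back(k);
    }
    for (int i = 0; i < n; ++i) if (!inbag[i]) tree.oob.push_back(i);
    grow_node(tree, x, y, idx, 0, (int)idx.size(), mtry, min_node,
              feat_pool, buf);
  }

  XPtr<Forest> ptr(forest, true);
  return ptr;
}

// votes[i, c]: number of trees with row i OOB predicting class c
// [[Rcpp::export]]
IntegerMatrix rf_oob_votes(SEXP handle, NumericMatrix x) {
  XPtr<Forest> forest(handle);
  IntegerMatrix votes(forest->n, 2);
  for (int t = 0; t < forest->ntree; ++t) {
    const Tree& tree = forest->trees[t];
    for (size_t k = 0; k < tree.oob.size(); ++k) {
      int row = tree.oob[k];
      votes(row, predict_row(tree, x, row)) += 1;
    }
  }
  return votes;
}

// [[Rcpp::export]]
IntegerVector rf_predict(SEXP handle, NumericMatrix x) {
  XPtr<Forest> forest(handle);
  int n = x.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int v1 = 0;
    for (int t = 0; t < forest->ntree; ++t)
      v1 += predict_row(forest->trees[t], x, i);
    out[i] = (2 * v1 > forest->ntree) ? 1 : 0;
  }
  return out;
}

// Breiman permutation importance: for each tree, error on its OOB rows
// before and after permuting one feature's OOB values; the importance of a
// feature is the mean error increase over all trees (trees not using the
// feature contribute zero).
// [[Rcpp::export]]
NumericVector rf_perm_importance(SEXP handle, NumericMatrix x, IntegerVector y) {
  XPtr<Forest> forest(handle);
  int p = forest->p;
  RNGScope scope;
  NumericVector imp(p);

  std::vector<int> perm;
  for (int t = 0; t < forest->ntree; ++t) {
    const Tree& tree = forest->trees[t];
    int m = (int)tree.oob.size();
    if (m == 0) continue;

    int wrong0 = 0;
    for (int k = 0; k < m; ++k) {
      int row = tree.oob[k];
      if (predict_row(tree, x, row) != y[row]) ++wrong0;
    }
    double err0 = (double)wrong0 / m;

    perm.resize(m);
    for (int j = 0; j < p; ++j) {
      if (!tree.used[j]) continue;
      for (int k = 0; k < m; ++k) perm[k] = k;
      for (int k = m - 1; k > 0; --k)
        std::swap(perm[k], perm[rand_int(k + 1)]);
      int wrong = 0;
      for (int k = 0; k < m; ++k) {
        int row = tree.oob[k];
        double v = x(tree.oob[perm[k]], j);
        if (predict_row(tree, x, row, j, v) != y[row]) ++wrong;
      }
      imp[j] += (double)wrong / m - err0;
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= forest->ntree;
  return imp;
}

// number of trees in which each feature is used at least once
// [[Rcpp::export]]
IntegerVector rf_feature_use(SEXP handle) {
  XPtr<Forest> forest(handle);
  IntegerVector use(forest->p);
  for (int t = 0; t < forest->ntree; ++t)
    for (int j = 0; j < forest->p; ++j)
      if (forest->trees[t].used[j]) use[j] += 1;
  return use;
}
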