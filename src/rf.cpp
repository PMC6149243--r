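// Random forest for binary (0/1) feature matrices.
//
// Standard Breiman forest specialised to binary predictors: bootstrap per
// tree, mtry features drawn without replacement at each node, split on
// bit == 0 vs bit == 1 by Gini impurity decrease, grown to purity.  Each
// tree casts a class vote; the forest score is the fraction of trees
// voting the active class.  All randomness comes from R's RNG so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // flat node arrays; feature == -1 marks a leaf whose vote is in pred
  std::vector<int> feature, left, right, pred;
};

int r_unif_index(int n) {  // uniform in 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k == n ? n - 1 : k;
}

double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n == 0.0) return 0.0;
  double p1 = n1 / n;
  return 2.0 * p1 * (1.0 - p1);
}

void grow_node(const IntegerMatrix& X, const IntegerVector& y,
               std::vector<int>& rows, int lo, int hi, int mtry,
               std::vector<int>& feat_buf, Tree& t, int node) {
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[rows[i]];
  int n = hi - lo, n0 = n - n1;
  // majority vote; exact tie goes to the active class
  t.pred[node] = (2 * n1 >= n) ? 1 : 0;
  if (n0 == 0 || n1 == 0 || n < 2) return;  // pure or singleton

  int p = X.ncol();
  // draw mtry distinct features (partial Fisher-Yates on feat_buf)
  for (int j = 0; j < p; ++j) feat_buf[j] = j;
  double parent = gini(n0, n1);
  double best_gain = 1e-12;  // require a strictly positive decrease
  int best_f = -1;
  for (int d = 0; d < mtry; ++d) {
    int pick = d + r_unif_index(p - d);
    std::swap(feat_buf[d], feat_buf[pick]);
    int f = feat_buf[d];
    int l1 = 0, ln = 0;  // bit == 0 child counts
    for (int i = lo; i < hi; ++i) {
      if (X(rows[i], f) == 0) { ++ln; l1 += y[rows[i]]; }
    }
    if (ln == 0 || ln == n) continue;  // no split
    int rn = n - ln;
    int r1 = n1 - l1;
    double child = (ln * gini(ln - l1, l1) + rn * gini(rn - r1, r1)) / n;
    double gain = parent - child;
    if (gain > best_gain) { best_gain = gain; best_f = f; }
  }
  if (best_f < 0) return;  // leaf: no impurity-reducing split found

  // partition rows: bit == 0 first
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(rows[i], best_f) == 0) std::swap(rows[i], rows[mid++]);
  }
  t.feature[node] = best_f;
  int l = (int)t.feature.size(), r = l + 1;
  t.left[node] = l;
  t.right[node] = r;
  for (int c = 0; c < 2; ++c) {
    t.feature.push_back(-1);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.pred.push_back(0);
  }
  grow_node(X, y, rows, lo, mid, mtry, feat_buf, t, l);
  grow_node(X, y, rows, mid, hi, mtry, feat_buf, t, r);
}

IntegerMatrix pack(const Tree& t) {
  int m = (int)t.feature.size();
  IntegerMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = t.feature[i];
    out(i, 1) = t.left[i];
    out(i, 2) = t.right[i];
    out(i, 3) = t.pred[i];
  }
  return out;
}

int tree_vote(const IntegerMatrix& t, const IntegerMatrix& X, int row) {
  int node = 0;
  while (t(node, 0) >= 0) {
    node = (X(row, t(node, 0)) == 0) ? t(node, 1) : t(node, 2);
  }
  return t(node, 3);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(IntegerMatrix X, IntegerVector y, int ntree, int mtry) {
  int n = X.nrow();
  RNGScope scope;
  List forest(ntree);
  std::vector<int> rows(n);
  std::vector<int> feat_buf(X.ncol());
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) rows[i] = r_unif_index(n);  // bootstrap
    Tree t;
    t.feature.assign(1, -1);
    t.left.assign(1, -1);
    t.right.assign(1, -1);
    t.pred.assign(1, 0);
    grow_node(X, y, rows, 0, n, mtry, feat_buf, t, 0);
    forest[b] = pack(t);
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, IntegerMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector score(n);
  for (int b = 0; b < ntree; ++b) {
    IntegerMatrix t = forest[b];
    for (int i = 0; i < n; ++i) score[i] += tree_vote(t, X, i);
  }
  for (int i = 0; i < n; ++i) score[i] /= ntree;
  return score;
}
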