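#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-column value dictionary: SNP dosage columns hold very few distinct
// values, so splits can be scored by value histogram instead of sorting the
// node. Columns with more than MAX_LEVELS distinct values use a sort path.
static const int MAX_LEVELS = 64;

struct ColumnInfo {
  std::vector<std::vector<double> > levels; // sorted distinct values or empty
};

static ColumnInfo make_column_info(const NumericMatrix &X) {
  ColumnInfo ci;
  ci.levels.resize(X.ncol());
  std::vector<double> v(X.nrow());
  for (int j = 0; j < X.ncol(); ++j) {
    for (int i = 0; i < X.nrow(); ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    if ((int)v.size() <= MAX_LEVELS) ci.levels[j] = v;
    v.assign(X.nrow(), 0.0);
    v.resize(X.nrow());
  }
  return ci;
}

// Exhaustive RSS split search over the candidate features of one node.
// Rows are indices (0-based) into X/y. Split points are midpoints between
// consecutive distinct sorted values; regions are {x < s} and {x >= s}.
// Ties are broken by lowest feature index, then smallest split value
// (guaranteed by scanning features ascending and values ascending with a
// strict improvement test). Returns true if a gainful split was found.
static bool node_best_split(const NumericMatrix &X, const NumericVector &y,
                            const ColumnInfo &ci,
                            const std::vector<int> &rows,
                            const std::vector<int> &features,
                            int &best_j, double &best_s, double &best_rss) {
  const int n = rows.size();
  if (n < 2) return false;
  double sy = 0.0, syy = 0.0;
  for (int r : rows) { sy += y[r]; syy += y[r] * y[r]; }
  const double node_rss = syy - sy * sy / n;
  bool found = false;
  best_rss = R_PosInf;
  std::vector<std::pair<double,double> > xv; // (x, y), sort path
  double cnt[MAX_LEVELS], bsum[MAX_LEVELS], bsq[MAX_LEVELS];
  for (int j : features) {
    const std::vector<double> &lev = ci.levels[j];
    const int k_lev = lev.size();
    if (k_lev >= 2 && k_lev <= MAX_LEVELS) {
      for (int b = 0; b < k_lev; ++b) cnt[b] = bsum[b] = bsq[b] = 0.0;
      for (int r : rows) {
        const double x = X(r, j);
        const int b = std::lower_bound(lev.begin(), lev.end(), x) -
          lev.begin();
        cnt[b] += 1.0;
        bsum[b] += y[r];
        bsq[b] += y[r] * y[r];
      }
      double nl = 0.0, sl = 0.0, sll = 0.0;
      for (int b = 0; b < k_lev - 1; ++b) {
        nl += cnt[b]; sl += bsum[b]; sll += bsq[b];
        if (nl < 0.5 || n - nl < 0.5) continue;
        // skip boundaries where the upper side has no occupied bin yet
        bool upper = false;
        for (int b2 = b + 1; b2 < k_lev; ++b2)
          if (cnt[b2] > 0.5) { upper = true; break; }
        if (!upper) break;
        const double nr = n - nl, sr = sy - sl, srr = syy - sll;
        const double rss = (sll - sl * sl / nl) + (srr - sr * sr / nr);
        if (rss < best_rss - 1e-12) {
          // midpoint between the highest occupied value <= b and the
          // lowest occupied value > b, matching the sort path exactly
          int lo = b; while (lo >= 0 && cnt[lo] < 0.5) --lo;
          int hi = b + 1; while (cnt[hi] < 0.5) ++hi;
          if (lo < 0) continue;
          const double s = 0.5 * (lev[lo] + lev[hi]);
          if (!(s > lev[lo])) continue; // midpoint rounded onto the value
          best_rss = rss;
          best_j = j;
          best_s = s;
          found = true;
        }
      }
    } else {
      xv.resize(n);
      for (int k = 0; k < n; ++k)
        xv[k] = std::make_pair(X(rows[k], j), y[rows[k]]);
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue; // constant feature
      double sl = 0.0, sll = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        sl += xv[k].second;
        sll += xv[k].second * xv[k].second;
        if (xv[k].first == xv[k + 1].first) continue;
        const int nl = k + 1, nr = n - nl;
        const double sr = sy - sl, srr = syy - sll;
        const double rss = (sll - sl * sl / nl) + (srr - sr * sr / nr);
        if (rss < best_rss - 1e-12) {
          const double s = 0.5 * (xv[k].first + xv[k + 1].first);
          if (!(s > xv[k].first)) continue; // midpoint rounded onto value
          best_rss = rss;
          best_j = j;
          best_s = s;
          found = true;
        }
      }
    }
  }
  if (!found) return false;
  // require a strict RSS improvement over the unsplit node
  if (!(node_rss - best_rss > 1e-12 * (1.0 + std::abs(node_rss))))
    return false;
  return true;
}

// [[Rcpp::export(name = ".cpp_best_split")]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector features) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<int> feats(features.size());
  for (int k = 0; k < features.size(); ++k) feats[k] = features[k] - 1;
  std::sort(feats.begin(), feats.end());
  ColumnInfo ci = make_column_info(X);
  int j = -1; double s = NA_REAL, rss = NA_REAL;
  bool ok = node_best_split(X, y, ci, rows, feats, j, s, rss);
  return List::create(_["found"] = ok, _["feature"] = j + 1,
                      _["split"] = s, _["rss"] = rss);
}

struct FlatTree {
  std::vector<int> feature, left, right, leaf_start, leaf_end;
  std::vector<double> split, value;
  std::vector<int> rows; // bootstrap row ids (0-based) grouped by leaf
};

// Grow one unpruned regression tree on the given bootstrap rows. mtry
// candidate features are redrawn at every node with the tree's own RNG.
static FlatTree grow_one_tree(const NumericMatrix &X, const NumericVector &y,
                              const ColumnInfo &ci,
                              std::vector<int> rows, int mtry, int min_node,
                              unsigned int seed) {
  const int p = X.ncol();
  std::mt19937 rng(seed);
  FlatTree t;
  t.rows = rows;
  std::vector<int> pool(p);
  struct Item { int node, start, end; };
  std::vector<Item> stack;

  auto new_node = [&]() {
    t.feature.push_back(-1); t.split.push_back(NA_REAL);
    t.left.push_back(-1); t.right.push_back(-1);
    t.value.push_back(NA_REAL);
    t.leaf_start.push_back(-1); t.leaf_end.push_back(-1);
    return (int)t.feature.size() - 1;
  };
  int root = new_node();
  stack.push_back({root, 0, (int)t.rows.size()});

  std::vector<int> feats;
  while (!stack.empty()) {
    Item it = stack.back(); stack.pop_back();
    const int n_node = it.end - it.start;
    bool make_leaf = n_node < 2 * min_node;
    int bj = -1; double bs = NA_REAL, brss = NA_REAL;
    if (!make_leaf) {
      // sample mtry distinct features (partial Fisher-Yates)
      for (int i = 0; i < p; ++i) pool[i] = i;
      int k = std::min(mtry, p);
      feats.clear();
      for (int i = 0; i < k; ++i) {
        int r = i + (int)(rng() % (unsigned)(p - i));
        std::swap(pool[i], pool[r]);
        feats.push_back(pool[i]);
      }
      std::sort(feats.begin(), feats.end());
      std::vector<int> rws(t.rows.begin() + it.start, t.rows.begin() + it.end);
      if (!node_best_split(X, y, ci, rws, feats, bj, bs, brss))
        make_leaf = true;
    }
    if (make_leaf) {
      double m = 0.0;
      for (int k = it.start; k < it.end; ++k) m += y[t.rows[k]];
      t.value[it.node] = m / n_node;
      t.leaf_start[it.node] = it.start;
      t.leaf_end[it.node] = it.end;
      continue;
    }
    // partition rows in place: {x < s} first
    int lo = it.start, hi = it.end - 1;
    while (lo <= hi) {
      if (X(t.rows[lo], bj) < bs) ++lo;
      else { std::swap(t.rows[lo], t.rows[hi]); --hi; }
    }
    const int mid = lo;
    if (mid == it.start || mid == it.end) { // numerically unsplittable
      double m = 0.0;
      for (int k = it.start; k < it.end; ++k) m += y[t.rows[k]];
      t.value[it.node] = m / n_node;
      t.leaf_start[it.node] = it.start;
      t.leaf_end[it.node] = it.end;
      continue;
    }
    t.feature[it.node] = bj;
    t.split[it.node] = bs;
    int l = new_node(), r = new_node();
    t.left[it.node] = l;
    t.right[it.node] = r;
    stack.push_back({l, it.start, mid});
    stack.push_back({r, mid, it.end});
  }
  return t;
}

static List tree_to_list(const FlatTree &t) {
  return List::create(
    _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
    _["split"] = NumericVector(t.split.begin(), t.split.end()),
    _["left"] = IntegerVector(t.left.begin(), t.left.end()),
    _["right"] = IntegerVector(t.right.begin(), t.right.end()),
    _["value"] = NumericVector(t.value.begin(), t.value.end()),
    _["leaf_start"] = IntegerVector(t.leaf_start.begin(), t.leaf_start.end()),
    _["leaf_end"] = IntegerVector(t.leaf_end.begin(), t.leaf_end.end()),
    _["rows"] = IntegerVector(t.rows.begin(), t.rows.end()));
}

// boot: n x T matrix of 1-based bootstrap row indices (drawn in R so that
// the forest is reproducible from the R RNG); seeds: per-tree feature RNG.
// [[Rcpp::export(name = ".cpp_fit_forest")]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, IntegerMatrix boot,
                    int mtry, int min_node, IntegerVector seeds) {
  const int T = boot.ncol();
  if (seeds.size() != T) stop("seeds length must equal the number of trees");
  ColumnInfo ci = make_column_info(X);
  List trees(T);
  for (int t = 0; t < T; ++t) {
    std::vector<int> rows(boot.nrow());
    for (int i = 0; i < boot.nrow(); ++i) rows[i] = boot(i, t) - 1;
    trees[t] = tree_to_list(grow_one_tree(X, y, ci, rows, mtry, min_node,
                                          (unsigned)seeds[t]));
  }
  return trees;
}

static int drop_to_leaf(const List &tree, const NumericMatrix &Xn, int row) {
  IntegerVector feature = tree["feature"], left = tree["left"],
    right = tree["right"];
  NumericVector split = tree["split"];
  int node = 0;
  while (feature[node] >= 0)
    node = (Xn(row, feature[node]) < split[node]) ? left[node] : right[node];
  return node;
}

// Mean-mode forest prediction: average over trees of leaf means.
// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix Xnew) {
  const int n = Xnew.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    NumericVector value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += value[drop_to_leaf(tree, Xnew, i)];
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Conditional-distribution weights over the n_train original training
// observations: per tree, each bootstrap occurrence in the query's leaf
// contributes 1 / (leaf size * T) to its originating observation.
// [[Rcpp::export(name = ".cpp_forest_weights")]]
NumericMatrix cpp_forest_weights(List trees, NumericMatrix Xnew, int n_train) {
  const int n = Xnew.nrow(), T = trees.size();
  NumericMatrix Wt(n, n_train);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector leaf_start = tree["leaf_start"], leaf_end = tree["leaf_end"],
      rows = tree["rows"];
    for (int i = 0; i < n; ++i) {
      int leaf = drop_to_leaf(tree, Xnew, i);
      const int a = leaf_start[leaf], b = leaf_end[leaf];
      const double w = 1.0 / ((double)(b - a) * T);
      for (int k = a; k < b; ++k)
        Wt(i, rows[k]) += w;
    }
  }
  return Wt;
}
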