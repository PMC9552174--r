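#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gradient-boosted trees with a logistic objective over *binary* features,
// in the second-order (gradient/hessian) split-gain formulation used by
// xgboost.  Because every feature is 0/1 there is exactly one candidate
// split per feature, so exact greedy search is cheap and fully
// deterministic: ties in gain are broken by the lowest column index, which
// upstream code arranges to be the gene-symbol order.
//
// Feature matrices are accessed through raw column-major pointers: these
// loops dominate panel selection's run time.

struct Node {
  int feature;     // -1 for a leaf
  double value;    // leaf weight (already scaled by eta)
  int left, right; // child indices within the tree's node vector
};

static inline double score_part(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// Greedy depth-limited tree growth over the row set `rows`.
static void grow_node(const int *X, int nrow, int ncol,
                      const std::vector<double> &g,
                      const std::vector<double> &h,
                      std::vector<int> &rows,
                      int depth, int max_depth,
                      double lambda, double eta,
                      double min_child_weight,
                      std::vector<Node> &nodes, int node_idx,
                      std::vector<double> &gain_acc) {
  const int n = (int)rows.size();

  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[rows[i]]; H += h[rows[i]]; }

  double best_gain = 0.0, best_g1 = 0.0, best_h1 = 0.0;
  int best_feature = -1, best_n1 = 0;

  if (depth < max_depth && n >= 2) {
    double parent_score = score_part(G, H, lambda);
    for (int f = 0; f < ncol; ++f) {
      const int *col = X + (size_t)f * nrow;
      double g1 = 0.0, h1 = 0.0;
      int n1 = 0;
      for (int i = 0; i < n; ++i) {
        int r = rows[i];
        if (col[r]) { g1 += g[r]; h1 += h[r]; ++n1; }
      }
      if (n1 == 0 || n1 == n) continue;
      double g0 = G - g1, h0 = H - h1;
      if (h1 < min_child_weight || h0 < min_child_weight) continue;
      double gain = 0.5 * (score_part(g0, h0, lambda) +
                           score_part(g1, h1, lambda) - parent_score);
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feature = f;
        best_g1 = g1; best_h1 = h1; best_n1 = n1;
      }
    }
  }

  if (best_feature < 0) {
    nodes[node_idx].feature = -1;
    nodes[node_idx].value = eta * (-G / (H + lambda));
    nodes[node_idx].left = nodes[node_idx].right = -1;
    return;
  }

  gain_acc[best_feature] += best_gain;

  std::vector<int> rows0, rows1;
  rows0.reserve(n - best_n1);
  rows1.reserve(best_n1);
  const int *bcol = X + (size_t)best_feature * nrow;
  for (int i = 0; i < n; ++i) {
    int r = rows[i];
    if (bcol[r]) rows1.push_back(r); else rows0.push_back(r);
  }
  rows.clear(); rows.shrink_to_fit();

  int li = (int)nodes.size(); nodes.push_back(Node());
  int ri = (int)nodes.size(); nodes.push_back(Node());
  nodes[node_idx].feature = best_feature;
  nodes[node_idx].left = li;
  nodes[node_idx].right = ri;
  nodes[node_idx].value = 0.0;

  grow_node(X, nrow, ncol, g, h, rows0, depth + 1, max_depth, lambda, eta,
            min_child_weight, nodes, li, gain_acc);
  grow_node(X, nrow, ncol, g, h, rows1, depth + 1, max_depth, lambda, eta,
            min_child_weight, nodes, ri, gain_acc);
}

static inline double tree_predict_row(const std::vector<Node> &nodes,
                                      const int *X, int nrow, int row) {
  int idx = 0;
  while (nodes[idx].feature >= 0) {
    const int *col = X + (size_t)nodes[idx].feature * nrow;
    idx = col[row] ? nodes[idx].right : nodes[idx].left;
  }
  return nodes[idx].value;
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(IntegerMatrix X, NumericVector y,
                 int nrounds, int max_depth, double eta,
                 double lambda, double min_child_weight,
                 double base_margin) {
  const int n = X.nrow(), p = X.ncol();
  const int *Xp = INTEGER(X);
  std::vector<double> margin(n, base_margin), g(n), h(n);
  std::vector<double> gain_acc(p, 0.0);
  std::vector<std::vector<Node> > forest;
  forest.reserve(nrounds);

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = pr * (1.0 - pr);
    }
    std::vector<Node> nodes;
    nodes.reserve(2 * (1 << max_depth));
    nodes.push_back(Node());
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    grow_node(Xp, n, p, g, h, rows, 0, max_depth, lambda, eta,
              min_child_weight, nodes, 0, gain_acc);
    if (nodes.size() == 1 && nodes[0].feature < 0 &&
        std::fabs(nodes[0].value) < 1e-15) {
      break; // pure leaf with ~zero update: nothing left to learn
    }
    for (int i = 0; i < n; ++i)
      margin[i] += tree_predict_row(nodes, Xp, n, i);
    forest.push_back(nodes);
  }

  // flatten forest into parallel vectors
  int total = 0;
  for (size_t t = 0; t < forest.size(); ++t) total += (int)forest[t].size();
  IntegerVector feature(total), left(total), right(total);
  NumericVector value(total);
  IntegerVector tree_offset((int)forest.size() + 1);
  int pos = 0;
  tree_offset[0] = 0;
  for (size_t t = 0; t < forest.size(); ++t) {
    for (size_t k = 0; k < forest[t].size(); ++k, ++pos) {
      feature[pos] = forest[t][k].feature;
      value[pos] = forest[t][k].value;
      left[pos] = forest[t][k].left;
      right[pos] = forest[t][k].right;
    }
    tree_offset[(int)t + 1] = pos;
  }

  return List::create(
    _["feature"] = feature, _["value"] = value,
    _["left"] = left, _["right"] = right,
    _["tree_offset"] = tree_offset,
    _["gain"] = NumericVector(gain_acc.begin(), gain_acc.end()),
    _["base_margin"] = base_margin,
    _["ntrees"] = (int)forest.size());
}

static inline double flat_tree_predict(const int *feature, const double *value,
                                       const int *left, const int *right,
                                       int off, const int *X, int nrow,
                                       int row, int perm_col, int perm_row) {
  int idx = 0;
  while (feature[off + idx] >= 0) {
    int f = feature[off + idx];
    int r = (f == perm_col) ? perm_row : row;
    const int *col = X + (size_t)f * nrow;
    idx = col[r] ? right[off + idx] : left[off + idx];
  }
  return value[off + idx];
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, IntegerMatrix X) {
  IntegerVector feature = model["feature"], left = model["left"],
                right = model["right"], tree_offset = model["tree_offset"];
  NumericVector value = model["value"];
  double base_margin = model["base_margin"];
  const int n = X.nrow();
  const int *Xp = INTEGER(X);
  const int *fp = INTEGER(feature), *lp = INTEGER(left), *rp = INTEGER(right);
  const double *vp = REAL(value);
  const int ntrees = tree_offset.size() - 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double m = base_margin;
    for (int t = 0; t < ntrees; ++t)
      m += flat_tree_predict(fp, vp, lp, rp, tree_offset[t], Xp, n, i, -1, -1);
    out[i] = m;
  }
  return out;
}

// Mann-Whitney AUC with mid-rank tie handling.
static double auc_stat(const std::vector<double> &score,
                       const NumericVector &y) {
  const int n = (int)score.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  double rank_sum_pos = 0.0;
  int n1 = 0, n0 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) ++j;
    double midrank = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) {
      if (y[ord[k]] == 1.0) { rank_sum_pos += midrank; ++n1; }
      else ++n0;
    }
    i = j + 1;
  }
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rank_sum_pos - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}

// Held-out permutation importance: mean decrease in validation AUC when a
// feature column is read through random row permutations.  Only trees that
// split on the shuffled feature change their output, so each (feature,
// shuffle) pass re-traverses just those trees on top of cached per-tree
// base predictions.
// `perms` is n x n_shuffles of 1-based row indices; `used` is 1-based
// feature indices with at least one split.
// [[Rcpp::export(name = ".gbt_perm_importance_cpp")]]
List gbt_perm_importance_cpp(List model, IntegerMatrix X, NumericVector y,
                             IntegerMatrix perms, IntegerVector used) {
  IntegerVector feature = model["feature"], left = model["left"],
                right = model["right"], tree_offset = model["tree_offset"];
  NumericVector value = model["value"];
  double base_margin = model["base_margin"];
  const int n = X.nrow(), p = X.ncol();
  const int *Xp = INTEGER(X);
  const int *fp = INTEGER(feature), *lp = INTEGER(left), *rp = INTEGER(right);
  const double *vp = REAL(value);
  const int ntrees = tree_offset.size() - 1;
  const int n_shuffles = perms.ncol();

  // cache per-tree unpermuted predictions and full margins
  std::vector<double> tree_pred((size_t)ntrees * n);
  std::vector<double> base(n, base_margin);
  for (int t = 0; t < ntrees; ++t) {
    double *tp = &tree_pred[(size_t)t * n];
    for (int i = 0; i < n; ++i) {
      tp[i] = flat_tree_predict(fp, vp, lp, rp, tree_offset[t], Xp, n, i,
                                -1, -1);
      base[i] += tp[i];
    }
  }
  double base_auc = auc_stat(base, y);

  // trees touching each feature
  std::vector<std::vector<int> > trees_with(p);
  for (int t = 0; t < ntrees; ++t) {
    for (int k = tree_offset[t]; k < tree_offset[t + 1]; ++k) {
      int f = fp[k];
      if (f >= 0 && (trees_with[f].empty() || trees_with[f].back() != t))
        trees_with[f].push_back(t);
    }
  }

  NumericVector imp(p);
  std::vector<double> margin(n);
  for (int u = 0; u < used.size(); ++u) {
    int f = used[u] - 1;
    const std::vector<int> &tw = trees_with[f];
    if (tw.empty()) continue;
    double drop = 0.0;
    for (int s = 0; s < n_shuffles; ++s) {
      for (int i = 0; i < n; ++i) {
        double m = base[i];
        int pr = perms(i, s) - 1;
        for (size_t k = 0; k < tw.size(); ++k) {
          int t = tw[k];
          m -= tree_pred[(size_t)t * n + i];
          m += flat_tree_predict(fp, vp, lp, rp, tree_offset[t], Xp, n, i,
                                 f, pr);
        }
        margin[i] = m;
      }
      drop += base_auc - auc_stat(margin, y);
    }
    imp[f] = drop / n_shuffles;
  }
  return List::create(_["importance"] = imp, _["base_auc"] = base_auc);
}
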