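// Path-dependent TreeSHAP for binary decision trees/forests.
//
// Trees are passed as flat arrays (one block per tree, offsets in
// tree_start): left/right child ids (-1 = leaf), 0-based split feature,
// threshold (routing rule: x <= threshold goes left), leaf value, and node
// cover (sample count routed through the node). Forest attribution is the
// mean of per-tree attributions, matching a forest prediction that averages
// tree outputs; local accuracy (sum(phi) + base == prediction) holds
// exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
      static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight *
      (unique_depth - i) / static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(PathElement *path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
        (unique_depth - i) / static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
        static_cast<double>(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, int unique_depth,
                               int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0;
  if (one_fraction != 0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one_portion /
        static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
        tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += path[i].pweight /
        (zero_fraction * static_cast<double>(unique_depth - i));
    }
  }
  return total * (unique_depth + 1);
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void tree_shap_recursive(const Tree &tr, const double *x,
                                double *phi, PathElement *parent_path,
                                int node, int unique_depth,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index, double scale) {
  PathElement *path = parent_path + unique_depth + 1;
  for (int i = 0; i <= unique_depth; ++i) path[i] = parent_path[i];
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tr.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
        tr.value[node] * scale;
    }
    return;
  }

  const int split = tr.feature[node];
  int hot = tr.left[node], cold = tr.right[node];
  if (!(x[split] <= tr.threshold[node])) { hot = tr.right[node]; cold = tr.left[node]; }
  const double w = tr.cover[node];
  const double hot_zero = w > 0 ? tr.cover[hot] / w : 0.0;
  const double cold_zero = w > 0 ? tr.cover[cold] / w : 0.0;
  double incoming_zero = 1.0, incoming_one = 1.0;
  int path_index = 0;
  for (int i = 1; i <= unique_depth; ++i) {
    if (path[i].feature_index == split) { path_index = i; break; }
  }
  if (path_index > 0) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  tree_shap_recursive(tr, x, phi, path, hot, unique_depth + 1,
                      hot_zero * incoming_zero, incoming_one, split, scale);
  tree_shap_recursive(tr, x, phi, path, cold, unique_depth + 1,
                      cold_zero * incoming_zero, 0.0, split, scale);
}

static int tree_max_depth(const Tree &tr, int node) {
  if (tr.left[node] < 0) return 1;
  int dl = tree_max_depth(tr, tr.left[node]);
  int dr = tree_max_depth(tr, tr.right[node]);
  return 1 + (dl > dr ? dl : dr);
}

static double tree_expected_value(const Tree &tr, int node) {
  if (tr.left[node] < 0) return tr.value[node];
  const double w = tr.cover[node];
  if (w <= 0) return 0.0;
  return (tr.cover[tr.left[node]] * tree_expected_value(tr, tr.left[node]) +
          tr.cover[tr.right[node]] * tree_expected_value(tr, tr.right[node]))
         / w;
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix X, IntegerVector left, IntegerVector right,
                  IntegerVector feature, NumericVector threshold,
                  NumericVector value, NumericVector cover,
                  IntegerVector tree_start) {
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = tree_start.size() - 1;
  NumericMatrix phi(n, p);
  double base = 0.0;
  const double scale = 1.0 / n_trees;

  std::vector<double> xrow(p), phirow(p);
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_start[t];
    Tree tr = {left.begin() + off, right.begin() + off,
               feature.begin() + off, threshold.begin() + off,
               value.begin() + off, cover.begin() + off};
    base += tree_expected_value(tr, 0) * scale;
    const int maxd = tree_max_depth(tr, 0) + 2;
    std::vector<PathElement> paths((maxd + 1) * (maxd + 2) / 2 + maxd + 2);
    for (int r = 0; r < n; ++r) {
      for (int j = 0; j < p; ++j) { xrow[j] = X(r, j); phirow[j] = 0.0; }
      tree_shap_recursive(tr, xrow.data(), phirow.data(), paths.data(), 0, 0,
                          1.0, 1.0, -1, scale);
      for (int j = 0; j < p; ++j) phi(r, j) += phirow[j];
    }
  }
  return List::create(Named("phi") = phi, Named("base") = base);
}

// Node covers: count of rows of X routed through each node, per tree.
// [[Rcpp::export(name = ".tree_covers_cpp")]]
NumericVector tree_covers_cpp(NumericMatrix X, IntegerVector left,
                              IntegerVector right, IntegerVector feature,
                              NumericVector threshold,
                              IntegerVector tree_start) {
  const int n = X.nrow();
  const int n_trees = tree_start.size() - 1;
  NumericVector cover(left.size());
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_start[t];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (true) {
        cover[off + node] += 1.0;
        if (left[off + node] < 0) break;
        node = X(r, feature[off + node]) <= threshold[off + node]
                 ? left[off + node] : right[off + node];
      }
    }
  }
  return cover;
}

// Forest prediction = mean over trees of the leaf value reached.
// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(NumericMatrix X, IntegerVector left,
                                 IntegerVector right, IntegerVector feature,
                                 NumericVector threshold, NumericVector value,
                                 IntegerVector tree_start) {
  const int n = X.nrow();
  const int n_trees = tree_start.size() - 1;
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_start[t];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (left[off + node] >= 0) {
        node = X(r, feature[off + node]) <= threshold[off + node]
                 ? left[off + node] : right[off + node];
      }
      out[r] += value[off + node] / n_trees;
    }
  }
  return out;
}
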