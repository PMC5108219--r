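// Regression random forest with out-of-bag error and Breiman OOB
// permutation importance. Mirrors the classical regression-forest
// defaults (mtry = ceiling(m/3), nodesize 5, bootstrap the n samples
// with replacement). Written here because no random-forest package is
// available in the target R library.
//
// Split search uses per-feature value ranks precomputed once per forest:
// within a node, samples are counted into rank buckets (counting sort),
// so each candidate feature costs O(n_node + n_unique) without sorting.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;     // leaf mean
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> features_used;
};

struct Workspace {
  const NumericMatrix& X;
  const NumericVector& y;
  std::vector<std::vector<int>> rank;      // [feature][sample] value rank
  std::vector<std::vector<double>> uniq;   // [feature] sorted unique values
  std::vector<int> cnt;
  std::vector<double> ysum;
  int mtry, min_node;
  std::mt19937 rng;
  std::vector<int> feats;

  Workspace(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
            int min_node_, unsigned seed)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(seed) {
    const int n = X.nrow(), m = X.ncol();
    rank.resize(m);
    uniq.resize(m);
    std::vector<std::pair<double, int>> v(n);
    for (int f = 0; f < m; ++f) {
      for (int i = 0; i < n; ++i) v[i] = { X(i, f), i };
      std::sort(v.begin(), v.end());
      rank[f].resize(n);
      uniq[f].clear();
      for (int k = 0; k < n; ++k) {
        if (k == 0 || v[k].first != v[k - 1].first)
          uniq[f].push_back(v[k].first);
        rank[f][v[k].second] = uniq[f].size() - 1;
      }
    }
    cnt.resize(n);
    ysum.resize(n);
    feats.resize(m);
    for (int j = 0; j < m; ++j) feats[j] = j;
  }
};

void growNode(Tree& tree, int node_id, std::vector<int>& idx,
              Workspace& ws, std::vector<char>& used_mask) {
  const int n = idx.size();
  const int m = ws.X.ncol();
  double total = 0.0;
  for (int i : idx) total += ws.y[i];
  const double mean = total / n;
  tree.nodes[node_id].value = mean;
  if (n <= ws.min_node) return;
  double sse = 0.0;
  for (int i : idx) sse += (ws.y[i] - mean) * (ws.y[i] - mean);
  if (sse <= 1e-12) return;

  // sample mtry candidate features without replacement
  for (int j = 0; j < ws.mtry && j < m; ++j) {
    std::uniform_int_distribution<int> pick(j, m - 1);
    std::swap(ws.feats[j], ws.feats[pick(ws.rng)]);
  }

  int best_f = -1;
  double best_thr = 0.0, best_gain = 1e-12;
  for (int c = 0; c < ws.mtry && c < m; ++c) {
    const int f = ws.feats[c];
    const std::vector<int>& rk = ws.rank[f];
    const std::vector<double>& uv = ws.uniq[f];
    const int U = uv.size();
    if (U < 2) continue;
    for (int r = 0; r < U; ++r) { ws.cnt[r] = 0; ws.ysum[r] = 0.0; }
    for (int i : idx) {
      const int r = rk[i];
      ws.cnt[r] += 1;
      ws.ysum[r] += ws.y[i];
    }
    double suml = 0.0;
    int nl = 0, prev = -1;
    for (int r = 0; r < U; ++r) {
      if (ws.cnt[r] == 0) continue;
      if (prev >= 0 && nl > 0 && nl < n) {
        const double sumr = total - suml;
        const int nr = n - nl;
        const double gain = suml * suml / nl + sumr * sumr / nr
          - total * total / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (uv[prev] + uv[r]);
        }
      }
      suml += ws.ysum[r];
      nl += ws.cnt[r];
      prev = r;
    }
  }
  if (best_f < 0) return;

  std::vector<int> left_idx, right_idx;
  for (int i : idx)
    (ws.X(i, best_f) <= best_thr ? left_idx : right_idx).push_back(i);
  if (left_idx.empty() || right_idx.empty()) return;

  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].threshold = best_thr;
  if (!used_mask[best_f]) {
    used_mask[best_f] = 1;
    tree.features_used.push_back(best_f);
  }
  const int li = tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes.push_back(Node());
  tree.nodes[node_id].left = li;
  tree.nodes[node_id].right = li + 1;
  growNode(tree, li, left_idx, ws, used_mask);
  growNode(tree, li + 1, right_idx, ws, used_mask);
}

double predictTree(const Tree& tree, const NumericMatrix& X, int row,
                   int perm_feature = -1, int swap_row = -1) {
  int node = 0;
  while (tree.nodes[node].feature >= 0) {
    const Node& nd = tree.nodes[node];
    const int r = (nd.feature == perm_feature) ? swap_row : row;
    node = (X(r, nd.feature) <= nd.threshold) ? nd.left : nd.right;
  }
  return tree.nodes[node].value;
}

}  // namespace

// [[Rcpp::export(name = ".rf_regression_cpp")]]
List rf_regression_cpp(NumericMatrix X, NumericVector y, int ntree,
                       int mtry, int min_node, int seed) {
  const int n = X.nrow(), m = X.ncol();
  Workspace ws(X, y, mtry, min_node, static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> pick_n(0, n - 1);

  NumericVector importance(m);          // mean OOB (MSE_perm - MSE_oob)
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> idx;
  std::vector<char> inbag(n), used_mask(m);
  std::vector<int> oob_rows, perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::fill(used_mask.begin(), used_mask.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int r = pick_n(ws.rng);
      idx.push_back(r);
      inbag[r] = 1;
    }
    Tree tree;
    tree.nodes.push_back(Node());
    growNode(tree, 0, idx, ws, used_mask);

    oob_rows.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob_rows.push_back(i);
    if (oob_rows.empty()) continue;

    double mse_oob = 0.0;
    for (size_t k = 0; k < oob_rows.size(); ++k) {
      const double pr = predictTree(tree, X, oob_rows[k]);
      oob_sum[oob_rows[k]] += pr;
      oob_cnt[oob_rows[k]] += 1;
      const double d = pr - y[oob_rows[k]];
      mse_oob += d * d;
    }
    mse_oob /= oob_rows.size();

    // permutation importance, only features the tree actually uses
    // (permuting any other feature cannot change its predictions)
    perm.resize(oob_rows.size());
    for (int f : tree.features_used) {
      for (size_t k = 0; k < perm.size(); ++k) perm[k] = oob_rows[k];
      for (size_t k = perm.size(); k > 1; --k) {
        std::uniform_int_distribution<size_t> pk(0, k - 1);
        std::swap(perm[k - 1], perm[pk(ws.rng)]);
      }
      double mse_perm = 0.0;
      for (size_t k = 0; k < oob_rows.size(); ++k) {
        const double pr = predictTree(tree, X, oob_rows[k], f, perm[k]);
        const double d = pr - y[oob_rows[k]];
        mse_perm += d * d;
      }
      mse_perm /= oob_rows.size();
      importance[f] += (mse_perm - mse_oob);
    }
  }
  for (int f = 0; f < m; ++f) importance[f] /= ntree;

  double mse = 0.0, ybar = 0.0, yvar = 0.0;
  int n_pred = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
  yvar /= n;
  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      const double d = oob_pred[i] - y[i];
      mse += d * d;
      ++n_pred;
    }
  }
  mse = n_pred > 0 ? mse / n_pred : NA_REAL;
  const double r2 = (yvar > 0) ? 1.0 - mse / yvar : NA_REAL;

  return List::create(_["importance"] = importance,
                      _["oob_mse"] = mse,
                      _["pseudo_r2"] = r2,
                      _["oob_pred"] = oob_pred,
                      _["n_oob_predicted"] = n_pred);
}
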