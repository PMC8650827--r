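// Stagewise gradient boosting for binary outcomes with depth-limited
// regression trees, supporting the binomial deviance and exponential
// (AdaBoost) losses. Trees are grown level-wise on quantile-binned
// features (up to 32 bins per feature) with second-order split gain
// GL^2/HL + GR^2/HR - G^2/H; leaf values are Newton steps -G/H scaled by
// the learning rate. Everything is deterministic: no subsampling, ties
// resolved by feature order then first-best bin.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int MAX_BINS = 32;
static const double LAMBDA = 1e-6;    // ridge on leaf weights
static const double MIN_GAIN = 1e-12;
static const double LEAF_CLIP = 10.0; // cap on unscaled leaf values

struct TreeNode {
  bool leaf;
  int feature;      // 0-based
  double thr;       // real-valued threshold (go left if x <= thr)
  int split_bin;    // binned threshold (go left if bin <= split_bin)
  int left, right;
  double value;     // leaf value, already scaled by learning rate
};

static void grad_hess(const std::string &loss, const std::vector<double> &y,
                      const std::vector<double> &F,
                      std::vector<double> &g, std::vector<double> &h) {
  const int n = (int)y.size();
  if (loss == "deviance") {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-12);
    }
  } else {  // exponential, margins y~ in {-1, 1}
    for (int i = 0; i < n; ++i) {
      double yy = 2.0 * y[i] - 1.0;
      double m = std::max(-50.0, std::min(50.0, -yy * F[i]));
      double e = std::exp(m);
      g[i] = -yy * e;
      h[i] = std::max(e, 1e-12);
    }
  }
}

// Quantile binning: per feature, up to MAX_BINS upper-inclusive edges from
// the training column (last edge is the column maximum). bin(x) = index of
// the first edge >= x; values above the maximum map to the last bin.
static void make_bins(const NumericMatrix &X,
                      std::vector<std::vector<double>> &edges,
                      std::vector<uint8_t> &binX) {
  const int n = X.nrow(), p = X.ncol();
  edges.assign(p, {});
  binX.assign((size_t)n * p, 0);
  std::vector<double> col(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) col[i] = X(i, f);
    std::sort(col.begin(), col.end());
    col.erase(std::unique(col.begin(), col.end()), col.end());
    std::vector<double> &e = edges[f];
    const int nd = (int)col.size();
    if (nd <= MAX_BINS) {
      e = col;
    } else {
      e.reserve(MAX_BINS);
      for (int b = 1; b <= MAX_BINS; ++b) {
        int idx = (int)((double)b * nd / MAX_BINS) - 1;
        idx = std::max(0, std::min(nd - 1, idx));
        e.push_back(col[idx]);
      }
      e.erase(std::unique(e.begin(), e.end()), e.end());
    }
    for (int i = 0; i < n; ++i) {
      double x = X(i, f);
      int b = (int)(std::lower_bound(e.begin(), e.end(), x) - e.begin());
      if (b >= (int)e.size()) b = (int)e.size() - 1;
      binX[(size_t)i * p + f] = (uint8_t)b;
    }
  }
}

static double predict_tree(const std::vector<TreeNode> &tree,
                           const NumericMatrix &X, int row) {
  int nd = 0;
  while (!tree[nd].leaf) {
    nd = (X(row, tree[nd].feature) <= tree[nd].thr) ? tree[nd].left
                                                    : tree[nd].right;
  }
  return tree[nd].value;
}

// Grow one depth-limited tree on (g, h) over the binned features.
static std::vector<TreeNode> grow_tree(const std::vector<uint8_t> &binX,
                                       const std::vector<std::vector<double>> &edges,
                                       int n, int p,
                                       const std::vector<double> &g,
                                       const std::vector<double> &h,
                                       int max_depth, double lr,
                                       std::vector<int> &node_of,
                                       std::vector<double> &hist_g,
                                       std::vector<double> &hist_h,
                                       std::vector<int> &hist_c) {
  std::vector<TreeNode> tree;
  tree.push_back({true, -1, 0.0, -1, -1, -1, 0.0});
  std::fill(node_of.begin(), node_of.begin() + n, 0);
  std::vector<int> level_nodes(1, 0);

  for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
    const int nlev = (int)level_nodes.size();
    std::vector<int> pos(tree.size(), -1);
    for (int q = 0; q < nlev; ++q) pos[level_nodes[q]] = q;

    const size_t cells = (size_t)nlev * p * MAX_BINS;
    std::fill(hist_g.begin(), hist_g.begin() + cells, 0.0);
    std::fill(hist_h.begin(), hist_h.begin() + cells, 0.0);
    std::fill(hist_c.begin(), hist_c.begin() + cells, 0);

    for (int i = 0; i < n; ++i) {
      const int q = pos[node_of[i]];
      if (q < 0) continue;
      const uint8_t *row = &binX[(size_t)i * p];
      const size_t base = (size_t)q * p * MAX_BINS;
      const double gi = g[i], hi = h[i];
      for (int f = 0; f < p; ++f) {
        const size_t idx = base + (size_t)f * MAX_BINS + row[f];
        hist_g[idx] += gi;
        hist_h[idx] += hi;
        hist_c[idx] += 1;
      }
    }

    std::vector<int> next_level;
    for (int q = 0; q < nlev; ++q) {
      const int nd = level_nodes[q];
      const size_t base = (size_t)q * p * MAX_BINS;
      // node totals from feature 0's histogram
      double G = 0.0, H = 0.0; int C = 0;
      for (int b = 0; b < MAX_BINS; ++b) {
        G += hist_g[base + b];
        H += hist_h[base + b];
        C += hist_c[base + b];
      }
      if (C < 2) continue;
      const double parent = G * G / (H + LAMBDA);
      double best_gain = MIN_GAIN;
      int best_f = -1, best_b = -1;
      for (int f = 0; f < p; ++f) {
        const int nb = (int)edges[f].size();
        if (nb < 2) continue;
        const size_t fb = base + (size_t)f * MAX_BINS;
        double gl = 0.0, hl = 0.0; int cl = 0;
        for (int b = 0; b < nb - 1; ++b) {
          gl += hist_g[fb + b];
          hl += hist_h[fb + b];
          cl += hist_c[fb + b];
          if (cl == 0) continue;
          if (cl == C) break;
          const double gr = G - gl, hr = H - hl;
          const double gain = gl * gl / (hl + LAMBDA) +
                              gr * gr / (hr + LAMBDA) - parent;
          if (gain > best_gain) {
            best_gain = gain; best_f = f; best_b = b;
          }
        }
      }
      if (best_f < 0) continue;  // stays a leaf
      const int li = (int)tree.size(), ri = li + 1;
      tree[nd].leaf = false;
      tree[nd].feature = best_f;
      tree[nd].thr = edges[best_f][best_b];
      tree[nd].split_bin = best_b;
      tree[nd].left = li;
      tree[nd].right = ri;
      tree.push_back({true, -1, 0.0, -1, -1, -1, 0.0});
      tree.push_back({true, -1, 0.0, -1, -1, -1, 0.0});
      next_level.push_back(li);
      next_level.push_back(ri);
    }
    if (next_level.empty()) break;
    for (int i = 0; i < n; ++i) {
      const int nd = node_of[i];
      if (!tree[nd].leaf) {
        node_of[i] = (binX[(size_t)i * p + tree[nd].feature] <= tree[nd].split_bin)
                         ? tree[nd].left : tree[nd].right;
      }
    }
    level_nodes = next_level;
  }

  // leaf values: Newton step over the samples in each leaf
  std::vector<double> GL(tree.size(), 0.0), HL(tree.size(), 0.0);
  for (int i = 0; i < n; ++i) { GL[node_of[i]] += g[i]; HL[node_of[i]] += h[i]; }
  for (size_t t = 0; t < tree.size(); ++t) {
    if (tree[t].leaf) {
      double v = -GL[t] / (HL[t] + LAMBDA);
      v = std::max(-LEAF_CLIP, std::min(LEAF_CLIP, v));
      tree[t].value = lr * v;
    }
  }
  return tree;
}

static NumericMatrix tree_to_matrix(const std::vector<TreeNode> &tree) {
  NumericMatrix m(tree.size(), 6);
  for (size_t t = 0; t < tree.size(); ++t) {
    m(t, 0) = tree[t].leaf ? 1.0 : 0.0;
    m(t, 1) = tree[t].feature + 1;  // 1-based for R
    m(t, 2) = tree[t].thr;
    m(t, 3) = tree[t].left + 1;
    m(t, 4) = tree[t].right + 1;
    m(t, 5) = tree[t].value;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_gbm_train(NumericMatrix X, NumericVector y, std::string loss,
                   int nrounds, int max_depth, double lr,
                   NumericMatrix Xval, IntegerVector snapshots,
                   bool keep_trees) {
  const int n = X.nrow(), p = X.ncol(), nval = Xval.nrow();
  if (loss != "deviance" && loss != "exponential")
    stop("loss must be 'deviance' or 'exponential'");

  std::vector<std::vector<double>> edges;
  std::vector<uint8_t> binX;
  make_bins(X, edges, binX);

  std::vector<double> yv(n);
  double pbar = 0.0;
  for (int i = 0; i < n; ++i) { yv[i] = y[i]; pbar += y[i]; }
  pbar = std::max(1e-6, std::min(1.0 - 1e-6, pbar / n));
  double f0 = (loss == "deviance") ? std::log(pbar / (1.0 - pbar))
                                   : 0.5 * std::log(pbar / (1.0 - pbar));

  std::vector<double> F(n, f0), Fval(nval, f0), g(n), h(n);
  const int max_nodes_level = 1 << std::max(0, max_depth - 1);
  std::vector<double> hist_g((size_t)max_nodes_level * p * MAX_BINS),
      hist_h(hist_g.size());
  std::vector<int> hist_c(hist_g.size()), node_of(n);

  NumericMatrix val_margins(nval, snapshots.size());
  List trees(keep_trees ? nrounds : 0);
  int snap = 0;

  for (int round = 0; round < nrounds; ++round) {
    grad_hess(loss, yv, F, g, h);
    std::vector<TreeNode> tree =
        grow_tree(binX, edges, n, p, g, h, max_depth, lr, node_of,
                  hist_g, hist_h, hist_c);
    // train update via the final node assignment (node_of ends at a leaf)
    for (int i = 0; i < n; ++i) F[i] += tree[node_of[i]].value;
    for (int i = 0; i < nval; ++i) Fval[i] += predict_tree(tree, Xval, i);
    if (keep_trees) trees[round] = tree_to_matrix(tree);
    while (snap < snapshots.size() && snapshots[snap] == round + 1) {
      for (int i = 0; i < nval; ++i) val_margins(i, snap) = Fval[i];
      ++snap;
    }
  }

  NumericVector train_margin(n);
  for (int i = 0; i < n; ++i) train_margin[i] = F[i];
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["val_margins"] = val_margins,
                      _["train_margin"] = train_margin);
}

// [[Rcpp::export]]
NumericVector cpp_gbm_predict(List trees, double f0, NumericMatrix X,
                              int ntrees) {
  const int n = X.nrow();
  NumericVector out(n, f0);
  int use = std::min<int>(ntrees, trees.size());
  for (int t = 0; t < use; ++t) {
    NumericMatrix m = trees[t];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (m(nd, 0) < 0.5) {
        nd = (X(i, (int)m(nd, 1) - 1) <= m(nd, 2)) ? (int)m(nd, 3) - 1
                                                   : (int)m(nd, 4) - 1;
      }
      out[i] += m(nd, 5);
    }
  }
  return out;
}
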