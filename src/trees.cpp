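// Exact-greedy decision-tree growers used by the in-package gradient-boosting
// and random-forest learners. Each tree sorts its (sub)sample once per
// retained column; nodes own contiguous ranges of the per-column sorted index
// arrays, which are stably partitioned in place at each split. Growth is
// therefore O(depth * d * n) per tree after an O(d * n log n) presort, with
// no per-node allocation.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;  // -1 for leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double value = 0.0;   // regression leaf
  int dist_row = -1;    // classification leaf distribution row
};

// Shared frame: per retained column, sample indices sorted by that column,
// segmented into node ranges [lo, hi).
struct Frame {
  const double* X;  // column-major n_total x d_total
  int n_total;
  std::vector<int> cols;              // retained column ids
  std::vector<std::vector<int> > ord; // per retained column, sorted indices
  std::vector<int> scratch;

  double x(int row, int col) const { return X[(size_t)col * n_total + row]; }

  void init(const double* X_, int n_total_, const std::vector<int>& rows,
            const std::vector<int>& cols_) {
    X = X_;
    n_total = n_total_;
    cols = cols_;
    ord.assign(cols.size(), rows);
    scratch.resize(rows.size());
    for (size_t j = 0; j < cols.size(); ++j) {
      const int c = cols[j];
      std::stable_sort(ord[j].begin(), ord[j].end(),
                       [&](int a, int b) { return x(a, c) < x(b, c); });
    }
  }

  // Stable in-place partition of every column's [lo, hi) range by
  // x[., split_col] <= thr; returns the left-block size.
  int partition(int lo, int hi, int split_col, double thr) {
    int nl = 0;
    for (size_t j = 0; j < ord.size(); ++j) {
      std::vector<int>& o = ord[j];
      int l = lo, r = 0;
      for (int i = lo; i < hi; ++i) {
        const int s = o[i];
        if (x(s, split_col) <= thr) o[l++] = s;
        else scratch[r++] = s;
      }
      std::copy(scratch.begin(), scratch.begin() + r, o.begin() + l);
      nl = l - lo;
    }
    return nl;
  }
};

// ---------------------------------------------------------------------------
// Regression tree on gradient/hessian pairs (Newton boosting):
// gain = GL^2/(HL+la) + GR^2/(HR+la) - G^2/(H+la), leaf = -G/(H+la).
// ---------------------------------------------------------------------------
struct RegGrower {
  Frame f;
  const double *g, *h;
  int max_depth, min_leaf;
  double mcw, lambda;
  std::vector<Node> nodes;

  int grow(int lo, int hi, int depth) {
    double G = 0.0, H = 0.0;
    const std::vector<int>& o0 = f.ord[0];
    for (int i = lo; i < hi; ++i) { G += g[o0[i]]; H += h[o0[i]]; }

    const int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].value = -G / (H + lambda);
    const int n = hi - lo;
    if (depth >= max_depth || n < 2 * min_leaf) return me;

    const double parent_score = G * G / (H + lambda);
    double best_gain = 1e-12, best_thr = 0.0;
    int best_j = -1;

    for (size_t j = 0; j < f.ord.size(); ++j) {
      const int c = f.cols[j];
      const std::vector<int>& o = f.ord[j];
      double GL = 0.0, HL = 0.0;
      for (int i = lo; i < hi - 1; ++i) {
        GL += g[o[i]];
        HL += h[o[i]];
        const double xv = f.x(o[i], c), xn = f.x(o[i + 1], c);
        if (!(xv < xn)) continue;
        const int nl = i - lo + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double HR = H - HL;
        if (HL < mcw || HR < mcw) continue;
        const double GR = G - GL;
        const double gain = GL * GL / (HL + lambda) +
                            GR * GR / (HR + lambda) - parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_j = (int)j;
          // split exactly at the left value (x <= xv); a midpoint can round
          // onto xn for near-identical neighbors and empty a child
          best_thr = xv;
        }
      }
    }
    if (best_j < 0) return me;

    const int split_col = f.cols[best_j];
    const int nl = f.partition(lo, hi, split_col, best_thr);
    if (nl == 0 || nl == n) return me;  // degenerate split guard
    nodes[me].feat = split_col;
    nodes[me].thr = best_thr;
    const int l = grow(lo, lo + nl, depth + 1);
    const int r = grow(lo + nl, hi, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

// ---------------------------------------------------------------------------
// Gini classification tree (random-forest member) with per-node feature
// subsampling (mtry) from a seeded RNG.
// ---------------------------------------------------------------------------
struct ClsGrower {
  Frame f;
  const int* y;
  const double* w;
  int K, max_depth, min_leaf, min_split, mtry;
  std::mt19937 rng;
  std::vector<Node> nodes;
  std::vector<double> dists;  // node-major K-wide leaf distributions
  std::vector<int> cand;

  int grow(int lo, int hi, int depth) {
    std::vector<double> s(K, 0.0);
    double W = 0.0;
    const std::vector<int>& o0 = f.ord[0];
    for (int i = lo; i < hi; ++i) { s[y[o0[i]]] += w[o0[i]]; W += w[o0[i]]; }

    const int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].dist_row = me;
    for (int c = 0; c < K; ++c) dists.push_back(s[c] / W);

    const int n = hi - lo;
    if (depth >= max_depth || n < min_split || n < 2 * min_leaf) return me;
    for (int c = 0; c < K; ++c) if (s[c] == W) return me;  // pure

    double parent_score = 0.0;
    for (int c = 0; c < K; ++c) parent_score += s[c] * s[c];
    parent_score /= W;

    std::shuffle(cand.begin(), cand.end(), rng);
    const int m = std::min<int>(mtry, (int)cand.size());

    double best_gain = 1e-12, best_thr = 0.0;
    int best_j = -1;
    std::vector<double> sl(K);
    for (int jj = 0; jj < m; ++jj) {
      const int j = cand[jj];
      const int c = f.cols[j];
      const std::vector<int>& o = f.ord[j];
      std::fill(sl.begin(), sl.end(), 0.0);
      double WL = 0.0;
      for (int i = lo; i < hi - 1; ++i) {
        sl[y[o[i]]] += w[o[i]];
        WL += w[o[i]];
        const double xv = f.x(o[i], c), xn = f.x(o[i + 1], c);
        if (!(xv < xn)) continue;
        const int nl = i - lo + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double WR = W - WL;
        if (WL <= 0.0 || WR <= 0.0) continue;
        double score = 0.0;
        for (int k = 0; k < K; ++k) {
          const double sr = s[k] - sl[k];
          score += sl[k] * sl[k] / WL + sr * sr / WR;
        }
        if (score - parent_score > best_gain) {
          best_gain = score - parent_score;
          best_j = j;
          // split exactly at the left value (x <= xv); a midpoint can round
          // onto xn for near-identical neighbors and empty a child
          best_thr = xv;
        }
      }
    }
    if (best_j < 0) return me;

    const int split_col = f.cols[best_j];
    const int nl = f.partition(lo, hi, split_col, best_thr);
    if (nl == 0 || nl == n) return me;  // degenerate split guard
    nodes[me].feat = split_col;
    nodes[me].thr = best_thr;
    const int l = grow(lo, lo + nl, depth + 1);
    const int r = grow(lo + nl, hi, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

int descend(const IntegerVector& feat, const NumericVector& thr,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0)
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_reg_tree(NumericMatrix X, NumericVector grad, NumericVector hess,
                       IntegerVector rows, IntegerVector cols, int max_depth,
                       int min_leaf, double min_child_weight, double lambda) {
  RegGrower gr;
  gr.g = REAL(grad);
  gr.h = REAL(hess);
  gr.max_depth = max_depth;
  gr.min_leaf = min_leaf;
  gr.mcw = min_child_weight;
  gr.lambda = lambda;
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> cv(cols.begin(), cols.end());
  gr.f.init(REAL(X), X.nrow(), rv, cv);
  gr.grow(0, (int)rv.size(), 0);

  const int n = (int)gr.nodes.size();
  IntegerVector feat(n), left(n), right(n);
  NumericVector thr(n), value(n);
  for (int i = 0; i < n; ++i) {
    feat[i] = gr.nodes[i].feat;
    thr[i] = gr.nodes[i].thr;
    left[i] = gr.nodes[i].left;
    right[i] = gr.nodes[i].right;
    value[i] = gr.nodes[i].value;
  }
  return List::create(_["feature"] = feat, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

// [[Rcpp::export]]
NumericVector cpp_predict_reg_tree(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = value[descend(feat, thr, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
List cpp_grow_class_tree(NumericMatrix X, IntegerVector y, NumericVector w,
                         IntegerVector rows, int K, int max_depth, int min_leaf,
                         int min_split, int mtry, int seed) {
  ClsGrower gr;
  gr.y = INTEGER(y);
  gr.w = REAL(w);
  gr.K = K;
  gr.max_depth = max_depth;
  gr.min_leaf = min_leaf;
  gr.min_split = min_split;
  gr.mtry = mtry;
  gr.rng.seed((unsigned int)seed);
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> cv(X.ncol());
  for (int j = 0; j < X.ncol(); ++j) cv[j] = j;
  gr.cand = cv;
  for (size_t j = 0; j < gr.cand.size(); ++j) gr.cand[j] = (int)j;
  gr.f.init(REAL(X), X.nrow(), rv, cv);
  gr.grow(0, (int)rv.size(), 0);

  const int n = (int)gr.nodes.size();
  IntegerVector feat(n), left(n), right(n);
  NumericVector thr(n);
  NumericMatrix dist(n, K);
  for (int i = 0; i < n; ++i) {
    feat[i] = gr.nodes[i].feat;
    thr[i] = gr.nodes[i].thr;
    left[i] = gr.nodes[i].left;
    right[i] = gr.nodes[i].right;
    for (int c = 0; c < K; ++c) dist(i, c) = gr.dists[(size_t)i * K + c];
  }
  return List::create(_["feature"] = feat, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right, _["dist"] = dist);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_class_tree(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"];
  NumericMatrix dist = tree["dist"];
  const int n = X.nrow(), K = dist.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    const int leaf = descend(feat, thr, left, right, X, i);
    for (int c = 0; c < K; ++c) out(i, c) = dist(leaf, c);
  }
  return out;
}
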