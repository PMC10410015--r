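#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Background-based (interventional) Shapley attribution for tree ensembles.
//
// For one explained row x, one background row z and one tree, every path that
// a hybrid input (features taken from x inside the coalition, from z outside)
// can follow is enumerated. At each internal node, if x and z route to the
// same child the node's feature is irrelevant on this path; otherwise the
// feature is "in play" and the path forks: following x's child constrains the
// feature to be inside the coalition ("on"), following z's child constrains
// it outside ("off"). A repeated feature on the path keeps its earlier
// constraint. A leaf reached with k on-features out of u in-play features
// contributes its value v with the closed-form Shapley weights
//   +W(k-1, u) * v to each on-feature,  -W(k, u) * v to each off-feature,
// where W(a, b) = a! (b-a-1)! / b!. Contributions are averaged over the
// background rows. Feature values and split conditions are held as floats to
// replicate xgboost's single-precision comparisons; the routing of the
// explained row is precomputed once per tree.

static const int MAX_PLAY = 64;

struct Tree {
  std::vector<int> split_index;
  std::vector<float> split_cond;
  std::vector<double> leaf_value;
  std::vector<int> left, right; // -1 for leaves
  std::vector<int> miss;        // child taken on missing
};

class ShapEngine {
public:
  std::vector<Tree> trees;
  std::vector<std::vector<double>> W; // W[u][k]
  const float *x = nullptr, *z = nullptr;
  double *phi = nullptr;
  const int *xgo = nullptr; // precomputed routing of x for the current tree
  const Tree *tcur = nullptr;
  int on[MAX_PLAY], off[MAX_PLAY];

  ShapEngine() {
    W.resize(MAX_PLAY + 1);
    for (int b = 1; b <= MAX_PLAY; ++b) {
      W[b].resize(b);
      for (int a = 0; a < b; ++a)
        W[b][a] = std::exp(std::lgamma(a + 1.0) + std::lgamma((double)(b - a)) -
                           std::lgamma(b + 1.0));
    }
  }

  inline int route(const Tree &t, int node, float v) const {
    if (ISNAN(v)) return t.miss[node];
    return (v < t.split_cond[node]) ? t.left[node] : t.right[node];
  }

  void recurse(int node, int n_on, int n_off) {
    const Tree &t = *tcur;
    if (t.left[node] < 0) {
      int u = n_on + n_off;
      if (u == 0) return;
      double v = t.leaf_value[node];
      if (n_on > 0) {
        double w = W[u][n_on - 1] * v;
        for (int i = 0; i < n_on; ++i) phi[on[i]] += w;
      }
      if (n_off > 0) {
        double w = W[u][n_on] * v;
        for (int i = 0; i < n_off; ++i) phi[off[i]] -= w;
      }
      return;
    }
    int f = t.split_index[node];
    for (int i = 0; i < n_on; ++i)
      if (on[i] == f) { recurse(xgo[node], n_on, n_off); return; }
    for (int i = 0; i < n_off; ++i)
      if (off[i] == f) { recurse(route(t, node, z[f]), n_on, n_off); return; }
    int xg = xgo[node];
    int zg = route(t, node, z[f]);
    if (xg == zg) { recurse(xg, n_on, n_off); return; }
    if (n_on + n_off >= MAX_PLAY) stop("tree path exceeds supported depth");
    on[n_on] = f;
    recurse(xg, n_on + 1, n_off);
    off[n_off] = f;
    recurse(zg, n_on, n_off + 1);
  }
};

static std::vector<Tree> build_trees(const List &split_index, const List &split_cond,
                                     const List &left, const List &right,
                                     const List &default_left) {
  int ntree = split_index.size();
  std::vector<Tree> trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    IntegerVector si = split_index[t];
    NumericVector sc = split_cond[t];
    IntegerVector lc = left[t], rc = right[t], dl = default_left[t];
    int nn = si.size();
    Tree &tr = trees[t];
    tr.split_index.assign(si.begin(), si.end());
    tr.split_cond.resize(nn);
    tr.leaf_value.resize(nn);
    tr.left.assign(lc.begin(), lc.end());
    tr.right.assign(rc.begin(), rc.end());
    tr.miss.resize(nn);
    for (int i = 0; i < nn; ++i) {
      tr.split_cond[i] = (float)sc[i];
      tr.leaf_value[i] = sc[i];
      tr.miss[i] = (lc[i] >= 0 && dl[i]) ? lc[i] : rc[i];
    }
  }
  return trees;
}

static void to_float_rows(const NumericMatrix &M, std::vector<float> &out) {
  int n = M.nrow(), p = M.ncol();
  out.resize((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      double v = M(i, j);
      out[(size_t)i * p + j] = ISNAN(v) ? NAN : (float)v;
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_ind_treeshap(List split_index, List split_cond, List left,
                               List right, List default_left,
                               NumericMatrix X, NumericMatrix B) {
  int n = X.nrow(), p = X.ncol(), nb = B.nrow();
  if (B.ncol() != p) stop("foreground and background must share columns");
  if (nb == 0) stop("background is empty");
  ShapEngine eng;
  eng.trees = build_trees(split_index, split_cond, left, right, default_left);
  std::vector<float> Xf, Bf;
  to_float_rows(X, Xf);
  to_float_rows(B, Bf);
  size_t max_nodes = 0;
  for (size_t t = 0; t < eng.trees.size(); ++t)
    max_nodes = std::max(max_nodes, eng.trees[t].left.size());
  std::vector<int> xroute(max_nodes);
  NumericMatrix out(n, p);
  std::vector<double> acc(p);
  for (int i = 0; i < n; ++i) {
    const float *xr = &Xf[(size_t)i * p];
    std::fill(acc.begin(), acc.end(), 0.0);
    eng.x = xr;
    eng.phi = acc.data();
    for (size_t t = 0; t < eng.trees.size(); ++t) {
      const Tree &tr = eng.trees[t];
      eng.tcur = &tr;
      int nn = tr.left.size();
      for (int nd = 0; nd < nn; ++nd)
        if (tr.left[nd] >= 0) xroute[nd] = eng.route(tr, nd, xr[tr.split_index[nd]]);
      eng.xgo = xroute.data();
      for (int b = 0; b < nb; ++b) {
        eng.z = &Bf[(size_t)b * p];
        eng.recurse(0, 0, 0);
      }
    }
    for (int j = 0; j < p; ++j) out(i, j) = acc[j] / nb;
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Margin predictions from the parsed trees (base score excluded).
// [[Rcpp::export]]
NumericVector cpp_predict_trees(List split_index, List split_cond, List left,
                                List right, List default_left, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  ShapEngine eng;
  eng.trees = build_trees(split_index, split_cond, left, right, default_left);
  std::vector<float> Xf;
  to_float_rows(X, Xf);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const float *xr = &Xf[(size_t)i * p];
    double s = 0;
    for (size_t t = 0; t < eng.trees.size(); ++t) {
      const Tree &tv = eng.trees[t];
      int node = 0;
      while (tv.left[node] >= 0) node = eng.route(tv, node, xr[tv.split_index[node]]);
      s += tv.leaf_value[node];
    }
    out[i] = s;
  }
  return out;
}
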