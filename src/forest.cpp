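#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Bagged CART forest engine.
//
// Trees are grown on bootstrap samples of size n (with replacement); at each
// node `mtry` candidate features are drawn without replacement and the best
// split among them (variance reduction for regression, Gini for class
// probabilities) is taken.  Trees are grown as deep as possible: any node
// holding at least 2*nodesize bootstrap cases is split (daughters may be as
// small as one case), matching the reference forest implementation, so
// terminal nodes hold between 1 and 2*nodesize - 1 bootstrap cases.  All
// randomness comes from R's RNG: callers seed with set.seed().

namespace {

struct Tree {
  std::vector<int> var;        // split feature (0-based), -1 for leaf
  std::vector<double> thr;     // go left iff x <= thr
  std::vector<int> left, right;
  std::vector<double> value;   // regression: leaf mean; classification: J probs per node
  int J;                       // 0 for regression

  int new_node(int nclass) {
    var.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    if (nclass == 0) value.push_back(0.0);
    else value.insert(value.end(), nclass, 0.0);
    return (int)var.size() - 1;
  }
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;      // regression response (unused if J > 0)
  const IntegerVector& ycls;   // 0-based class labels (unused if J == 0)
  int J, mtry, nodesize, p;
  std::vector<int> feat;       // scratch for feature subsampling
  std::vector<int> ord;        // scratch sort order within a node
  std::vector<int> cnt_l, cnt_tot;  // classification scratch

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const IntegerVector& ycls_, int J_, int mtry_, int nodesize_)
      : X(X_), y(y_), ycls(ycls_), J(J_), mtry(mtry_), nodesize(nodesize_),
        p(X_.ncol()), feat(p), cnt_l(J_ > 0 ? J_ : 1), cnt_tot(J_ > 0 ? J_ : 1) {
    for (int j = 0; j < p; ++j) feat[j] = j;
  }

  void make_leaf(Tree& T, int node, std::vector<int>& cases, int lo, int hi) {
    int m = hi - lo;
    if (J == 0) {
      double s = 0.0;
      for (int i = lo; i < hi; ++i) s += y[cases[i]];
      T.value[node] = s / m;
    } else {
      std::fill(cnt_tot.begin(), cnt_tot.end(), 0);
      for (int i = lo; i < hi; ++i) cnt_tot[ycls[cases[i]]]++;
      for (int j = 0; j < J; ++j) T.value[(size_t)node * J + j] = (double)cnt_tot[j] / m;
    }
  }

  int build(Tree& T, std::vector<int>& cases, int lo, int hi) {
    int node = T.new_node(J);
    int m = hi - lo;

    bool pure = true;
    if (J == 0) {
      double y0 = y[cases[lo]];
      for (int i = lo + 1; i < hi; ++i)
        if (y[cases[i]] != y0) { pure = false; break; }
    } else {
      int c0 = ycls[cases[lo]];
      for (int i = lo + 1; i < hi; ++i)
        if (ycls[cases[i]] != c0) { pure = false; break; }
    }
    if (pure || m < 2 * nodesize) {
      make_leaf(T, node, cases, lo, hi);
      return node;
    }

    // draw mtry candidate features by partial Fisher-Yates
    for (int k = 0; k < mtry; ++k) {
      int j = k + (int)(unif_rand() * (p - k));
      if (j >= p) j = p - 1;
      std::swap(feat[k], feat[j]);
    }

    double best_score = -1.0, parent_score;
    int best_var = -1, best_nl = 0;
    double best_thr = 0.0;

    if (J == 0) {
      double s_tot = 0.0;
      for (int i = lo; i < hi; ++i) s_tot += y[cases[i]];
      parent_score = s_tot * s_tot / m;

      for (int k = 0; k < mtry; ++k) {
        int f = feat[k];
        ord.assign(cases.begin() + lo, cases.begin() + hi);
        std::sort(ord.begin(), ord.end(), [&](int a, int b) { return X(a, f) < X(b, f); });
        if (X(ord[0], f) == X(ord[m - 1], f)) continue;  // constant feature
        double sl = 0.0;
        for (int i = 0; i < m - 1; ++i) {
          sl += y[ord[i]];
          int nl = i + 1, nr = m - nl;
          if (X(ord[i], f) == X(ord[i + 1], f)) continue;  // not a cut point
          double sr = s_tot - sl;
          double score = sl * sl / nl + sr * sr / nr;
          if (score > best_score) {
            best_score = score;
            best_var = f;
            best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
            best_nl = nl;
          }
        }
      }
    } else {
      std::fill(cnt_tot.begin(), cnt_tot.end(), 0);
      for (int i = lo; i < hi; ++i) cnt_tot[ycls[cases[i]]]++;
      parent_score = 0.0;
      for (int j = 0; j < J; ++j) parent_score += (double)cnt_tot[j] * cnt_tot[j] / m;

      for (int k = 0; k < mtry; ++k) {
        int f = feat[k];
        ord.assign(cases.begin() + lo, cases.begin() + hi);
        std::sort(ord.begin(), ord.end(), [&](int a, int b) { return X(a, f) < X(b, f); });
        if (X(ord[0], f) == X(ord[m - 1], f)) continue;
        std::fill(cnt_l.begin(), cnt_l.end(), 0);
        for (int i = 0; i < m - 1; ++i) {
          cnt_l[ycls[ord[i]]]++;
          int nl = i + 1, nr = m - nl;
          if (X(ord[i], f) == X(ord[i + 1], f)) continue;
          double score = 0.0;
          for (int j = 0; j < J; ++j) {
            double cl = cnt_l[j], cr = cnt_tot[j] - cnt_l[j];
            score += cl * cl / nl + cr * cr / nr;
          }
          if (score > best_score) {
            best_score = score;
            best_var = f;
            best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
            best_nl = nl;
          }
        }
      }
    }

    double tol = 1e-10 * std::max(1.0, std::fabs(parent_score));
    if (best_var < 0 || best_score <= parent_score + tol) {
      make_leaf(T, node, cases, lo, hi);
      return node;
    }

    int f = best_var;
    double th = best_thr;
    std::stable_partition(cases.begin() + lo, cases.begin() + hi,
                          [&](int a) { return X(a, f) <= th; });
    int mid = lo + best_nl;

    T.var[node] = best_var;
    T.thr[node] = best_thr;
    T.left[node] = build(T, cases, lo, mid);
    T.right[node] = build(T, cases, mid, hi);
    return node;
  }
};

// flat view of one tree, extracted once per tree before the row loop
struct TreeView {
  const int *var, *left, *right;
  const double *thr;
  IntegerVector var_, left_, right_;
  NumericVector thr_;
  explicit TreeView(const List& tree)
      : var_(as<IntegerVector>(tree["var"])),
        left_(as<IntegerVector>(tree["left"])),
        right_(as<IntegerVector>(tree["right"])),
        thr_(as<NumericVector>(tree["thr"])) {
    var = var_.begin(); left = left_.begin(); right = right_.begin();
    thr = thr_.begin();
  }
  int leaf(const NumericMatrix& X, int row) const {
    int node = 0;
    while (var[node] >= 0)
      node = (X(row, var[node]) <= thr[node]) ? left[node] : right[node];
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, IntegerVector ycls,
                     int J, int ntree, int mtry, int nodesize) {
  int n = X.nrow();
  Builder B(X, y, ycls, J, mtry, nodesize);
  List trees(ntree);
  IntegerMatrix inbag(ntree, n);
  std::vector<int> cases(n);

  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      cases[i] = k;
      inbag(t, k)++;
    }
    Tree T;
    T.J = J;
    B.build(T, cases, 0, n);
    int nn = (int)T.var.size();
    List tr = List::create(
        _["var"] = IntegerVector(T.var.begin(), T.var.end()),
        _["thr"] = NumericVector(T.thr.begin(), T.thr.end()),
        _["left"] = IntegerVector(T.left.begin(), T.left.end()),
        _["right"] = IntegerVector(T.right.begin(), T.right.end()),
        _["value"] = (J == 0)
            ? (SEXP)NumericVector(T.value.begin(), T.value.end())
            : (SEXP)NumericMatrix(J, nn, T.value.begin()));  // J x nnodes, col = node
    trees[t] = tr;
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_forest(List trees, NumericMatrix X, int J, bool bytree) {
  int ntree = trees.size(), n = X.nrow();
  if (J == 0) {
    NumericMatrix out(n, bytree ? ntree : 1);
    for (int t = 0; t < ntree; ++t) {
      List tr = trees[t];
      TreeView tv(tr);
      NumericVector val = tr["value"];
      for (int i = 0; i < n; ++i) {
        double v = val[tv.leaf(X, i)];
        if (bytree) out(i, t) = v; else out(i, 0) += v / ntree;
      }
    }
    return out;
  }
  if (bytree) stop("bytree predictions are regression-only");
  NumericMatrix out(n, J);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    TreeView tv(tr);
    NumericMatrix val = tr["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = tv.leaf(X, i);
      for (int j = 0; j < J; ++j) out(i, j) += val(j, leaf) / ntree;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_oob_predict(List trees, IntegerMatrix inbag, NumericMatrix X, int J) {
  int ntree = trees.size(), n = X.nrow();
  int q = (J == 0) ? 1 : J;
  NumericMatrix acc(n, q);
  IntegerVector cnt(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    TreeView tv(tr);
    NumericVector val = tr["value"];  // regression: nnodes; classification: J x nnodes
    const double* vp = val.begin();
    for (int i = 0; i < n; ++i) {
      if (inbag(t, i) > 0) continue;
      int leaf = tv.leaf(X, i);
      if (J == 0) {
        acc(i, 0) += vp[leaf];
      } else {
        for (int j = 0; j < J; ++j) acc(i, j) += vp[(size_t)leaf * J + j];
      }
      cnt[i]++;
    }
  }
  LogicalVector covered(n);
  for (int i = 0; i < n; ++i) {
    covered[i] = cnt[i] > 0;
    for (int j = 0; j < q; ++j)
      acc(i, j) = cnt[i] > 0 ? acc(i, j) / cnt[i] : NA_REAL;
  }
  return List::create(_["values"] = acc, _["covered"] = covered,
                      _["n_trees_oob"] = cnt);
}

// COBRA zero-one proximity aggregation ---------------------------------------

// For each holdout/test row, weight_i = 1 iff |train_preds(i,m) - test_preds(k,m)|
// <= eps for at least kmin machines; prediction = mean train_y over weight-1 rows.
// self_idx[k] (0-based, or -1) marks a training row to exclude (calibration on
// the training set itself). Empty neighbour set falls back to mean(train_y).

// [[Rcpp::export]]
List cpp_cobra_predict(NumericMatrix train_preds, NumericVector train_y,
                       NumericMatrix test_preds, double eps, int kmin,
                       IntegerVector self_idx) {
  int n = train_preds.nrow(), M = train_preds.ncol(), nt = test_preds.nrow();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += train_y[i];
  ybar /= n;
  NumericVector pred(nt);
  IntegerVector nnbr(nt);
  int nfall = 0;
  for (int k = 0; k < nt; ++k) {
    int skip = (self_idx.size() == nt) ? self_idx[k] : -1;
    double s = 0.0;
    int c = 0;
    for (int i = 0; i < n; ++i) {
      if (i == skip) continue;
      int agree = 0;
      for (int m = 0; m < M; ++m)
        if (std::fabs(train_preds(i, m) - test_preds(k, m)) <= eps) agree++;
      if (agree >= kmin) { s += train_y[i]; c++; }
    }
    nnbr[k] = c;
    if (c == 0) { pred[k] = ybar; nfall++; }
    else pred[k] = s / c;
  }
  return List::create(_["pred"] = pred, _["n_neighbors"] = nnbr,
                      _["n_fallback"] = nfall);
}

// [[Rcpp::export]]
NumericVector cpp_cobra_risk(NumericMatrix train_preds, NumericVector train_y,
                             NumericMatrix hold_preds, NumericVector hold_y,
                             NumericVector eps_grid, int kmin,
                             IntegerVector self_idx) {
  int G = eps_grid.size();
  NumericVector risk(G);
  for (int g = 0; g < G; ++g) {
    List r = cpp_cobra_predict(train_preds, train_y, hold_preds, eps_grid[g],
                               kmin, self_idx);
    NumericVector pred = r["pred"];
    double s = 0.0;
    for (int k = 0; k < pred.size(); ++k) {
      double d = pred[k] - hold_y[k];
      s += d * d;
    }
    risk[g] = s / pred.size();
  }
  return risk;
}
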