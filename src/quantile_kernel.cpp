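#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Weighted empirical quantiles of training outcomes under leaf
// co-membership weights (Meinshausen-style quantile regression forest).
//
// For a query point x, each tree t assigns weight 1/(ntree * |leaf_t(x)|)
// to every training observation falling in the same terminal node as x
// (all training observations are dropped down each tree, not only the
// resampled ones). Quantiles are lower-order-statistic (type 1) quantiles
// of the weighted empirical distribution: the smallest training outcome
// whose cumulative weight reaches q.
//
// tn_train: n_train x n_tree terminal node ids for training rows
// tn_query: n_query x n_tree terminal node ids for query rows
// y:        training outcomes, length n_train
// qs:       probabilities, strictly increasing, each in (0,1)
//
// Returns an n_query x length(qs) matrix.
// [[Rcpp::export]]
NumericMatrix qrf_weighted_quantiles(IntegerMatrix tn_train,
                                     IntegerMatrix tn_query,
                                     NumericVector y,
                                     NumericVector qs) {
  const int n_train = tn_train.nrow();
  const int n_tree = tn_train.ncol();
  const int n_query = tn_query.nrow();
  const int n_q = qs.size();
  if (tn_query.ncol() != n_tree)
    stop("query and training terminal-node matrices must have the same number of trees");
  if (y.size() != n_train)
    stop("length of training outcomes must match terminal-node rows");

  // order training rows by outcome value (ascending, stable)
  std::vector<int> ord(n_train);
  for (int i = 0; i < n_train; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return y[a] < y[b]; });
  std::vector<double> y_sorted(n_train);
  std::vector<int> pos_of(n_train); // training row -> position in sorted order
  for (int i = 0; i < n_train; ++i) {
    y_sorted[i] = y[ord[i]];
    pos_of[ord[i]] = i;
  }

  // Per tree: CSR layout of leaf members, members stored as sorted-y
  // positions in ascending order so per-query accumulation touches
  // positions that a single forward scan can consume.
  std::vector<int> node_max(n_tree, 0);
  for (int t = 0; t < n_tree; ++t) {
    int mx = 0;
    for (int i = 0; i < n_train; ++i) {
      int id = tn_train(i, t);
      if (id < 0) stop("negative terminal node id");
      if (id > mx) mx = id;
    }
    node_max[t] = mx;
  }
  std::vector<long long> tree_off(n_tree + 1, 0);
  for (int t = 0; t < n_tree; ++t)
    tree_off[t + 1] = tree_off[t] + (node_max[t] + 1);
  const long long n_slots = tree_off[n_tree];
  std::vector<int> leaf_size((size_t)n_slots, 0);
  for (int t = 0; t < n_tree; ++t)
    for (int i = 0; i < n_train; ++i)
      leaf_size[(size_t)(tree_off[t] + tn_train(i, t))]++;
  std::vector<long long> leaf_start((size_t)n_slots + 1, 0);
  for (long long s = 0; s < n_slots; ++s)
    leaf_start[(size_t)s + 1] = leaf_start[(size_t)s] + leaf_size[(size_t)s];
  std::vector<int> members((size_t)(leaf_start[(size_t)n_slots]));
  {
    std::vector<long long> fill(leaf_start.begin(), leaf_start.end() - 1);
    // iterate training rows in ascending-y order so member lists are sorted
    for (int k = 0; k < n_train; ++k) {
      int i = ord[k];
      for (int t = 0; t < n_tree; ++t) {
        long long slot = tree_off[t] + tn_train(i, t);
        members[(size_t)(fill[(size_t)slot]++)] = k; // sorted position
      }
    }
  }

  NumericMatrix out(n_query, n_q);
  std::vector<double> w(n_train, 0.0);
  std::vector<char> touched(n_train, 0);
  std::vector<int> touched_idx;
  touched_idx.reserve(n_train);
  const double inv_tree = 1.0 / (double)n_tree;
  const double eps = 1e-9;

  for (int qrow = 0; qrow < n_query; ++qrow) {
    if (qrow % 4096 == 0) Rcpp::checkUserInterrupt();
    touched_idx.clear();
    for (int t = 0; t < n_tree; ++t) {
      int id = tn_query(qrow, t);
      if (id < 0 || id > node_max[t])
        stop("query terminal node id outside training forest at tree %d", t + 1);
      long long slot = tree_off[t] + id;
      int sz = leaf_size[(size_t)slot];
      if (sz == 0)
        stop("query landed in a terminal node with no training observations");
      double wadd = inv_tree / (double)sz;
      long long s0 = leaf_start[(size_t)slot];
      for (int m = 0; m < sz; ++m) {
        int p = members[(size_t)(s0 + m)];
        if (!touched[p]) {
          touched[p] = 1;
          touched_idx.push_back(p);
        }
        w[p] += wadd;
      }
    }
    std::sort(touched_idx.begin(), touched_idx.end());
    double cum = 0.0;
    int qi = 0;
    int last = touched_idx.empty() ? -1 : touched_idx.back();
    for (size_t k = 0; k < touched_idx.size() && qi < n_q; ++k) {
      int p = touched_idx[k];
      cum += w[p];
      while (qi < n_q && cum >= qs[qi] - eps) {
        out(qrow, qi) = y_sorted[p];
        ++qi;
      }
    }
    // guard against cumulative rounding leaving the largest quantiles unset
    for (; qi < n_q; ++qi) out(qrow, qi) = y_sorted[last];
    for (size_t k = 0; k < touched_idx.size(); ++k) {
      w[touched_idx[k]] = 0.0;
      touched[touched_idx[k]] = 0;
    }
  }
  return out;
}
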