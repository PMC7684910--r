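#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Per-tree bucketing of in-bag training rows by terminal node, shared by the
// weight and quantile routines. Leaf co-membership with bootstrap
// multiplicities is the whole QRF device: a prediction point's conditional
// distribution is the in-bag-weighted empirical distribution of training
// responses in the leaves it falls into, averaged over trees.
struct TreeIndex {
  std::unordered_map<int, std::pair<int, int> > range; // leaf -> [start, end)
  std::vector<int> rows;          // training row indices grouped by leaf
  std::vector<double> leaf_total; // total in-bag multiplicity per leaf (parallel to range order)
  std::unordered_map<int, double> total;
};

static void build_tree_index(const IntegerMatrix &leaf_train,
                             const IntegerMatrix &inbag, int t,
                             TreeIndex &idx) {
  const int n = leaf_train.nrow();
  std::unordered_map<int, std::vector<int> > buckets;
  for (int i = 0; i < n; ++i) {
    if (inbag(i, t) > 0) buckets[leaf_train(i, t)].push_back(i);
  }
  idx.rows.clear();
  idx.range.clear();
  idx.total.clear();
  idx.rows.reserve(n);
  for (std::unordered_map<int, std::vector<int> >::iterator it = buckets.begin();
       it != buckets.end(); ++it) {
    int start = (int)idx.rows.size();
    double tot = 0.0;
    for (size_t k = 0; k < it->second.size(); ++k) {
      idx.rows.push_back(it->second[k]);
      tot += inbag(it->second[k], t);
    }
    idx.range[it->first] = std::make_pair(start, (int)idx.rows.size());
    idx.total[it->first] = tot;
  }
}

// Accumulate, for every evaluation row, the per-training-row weight vector
// w_i(x) = mean over (used) trees of inbag(i,t) / S_leaf, where S_leaf is the
// total in-bag multiplicity of the leaf x falls into in tree t.
// oob = true restricts row i (eval rows must then coincide with training rows)
// to trees where it is out of bag; such rows carry no weight on themselves
// because their in-bag count there is zero.
// [[Rcpp::export]]
List qrf_weights_cpp(IntegerMatrix leaf_train, IntegerMatrix inbag,
                     IntegerMatrix leaf_eval, bool oob) {
  const int n = leaf_train.nrow(), T = leaf_train.ncol(), m = leaf_eval.nrow();
  if (inbag.nrow() != n || inbag.ncol() != T)
    stop("inbag dimensions do not match leaf_train");
  if (leaf_eval.ncol() != T) stop("leaf_eval has wrong number of trees");
  if (oob && m != n) stop("oob weights require eval rows = training rows");
  NumericMatrix W(m, n);
  IntegerVector used(m);
  std::vector<TreeIndex> trees(T);
  for (int t = 0; t < T; ++t) build_tree_index(leaf_train, inbag, t, trees[t]);
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < T; ++t) {
      if (oob && inbag(i, t) > 0) continue;
      std::unordered_map<int, std::pair<int, int> >::const_iterator it =
          trees[t].range.find(leaf_eval(i, t));
      if (it == trees[t].range.end()) continue; // empty leaf cannot occur for valid forests
      double S = trees[t].total[leaf_eval(i, t)];
      for (int k = it->second.first; k < it->second.second; ++k) {
        int j = trees[t].rows[k];
        W(i, j) += inbag(j, t) / S;
      }
      ++used[i];
    }
    if (used[i] > 0) {
      for (int j = 0; j < n; ++j) W(i, j) /= used[i];
    }
  }
  return List::create(_["weights"] = W, _["trees_used"] = used);
}

// Conditional quantiles by left-continuous inversion of the weighted ECDF,
// computed without materialising the m x n weight matrix. ord is the 1-based
// ordering of y ascending; taus must be sorted ascending. Also returns the
// weighted mean prediction (used by mean-squared-error importance).
// [[Rcpp::export]]
List qrf_quantiles_cpp(IntegerMatrix leaf_train, IntegerMatrix inbag,
                       IntegerMatrix leaf_eval, bool oob, NumericVector y,
                       IntegerVector ord, NumericVector taus) {
  const int n = leaf_train.nrow(), T = leaf_train.ncol(), m = leaf_eval.nrow();
  const int ntau = taus.size();
  if (y.size() != n) stop("y has wrong length");
  if (oob && m != n) stop("oob quantiles require eval rows = training rows");
  for (int k = 1; k < ntau; ++k)
    if (taus[k] < taus[k - 1]) stop("taus must be sorted ascending");
  NumericMatrix Q(m, ntau);
  NumericVector mean_pred(m);
  IntegerVector used(m);
  std::vector<TreeIndex> trees(T);
  for (int t = 0; t < T; ++t) build_tree_index(leaf_train, inbag, t, trees[t]);
  std::vector<double> w(n);
  const double eps = 1e-10;
  for (int i = 0; i < m; ++i) {
    std::fill(w.begin(), w.end(), 0.0);
    int nt = 0;
    for (int t = 0; t < T; ++t) {
      if (oob && inbag(i, t) > 0) continue;
      std::unordered_map<int, std::pair<int, int> >::const_iterator it =
          trees[t].range.find(leaf_eval(i, t));
      if (it == trees[t].range.end()) continue;
      double S = trees[t].total[leaf_eval(i, t)];
      for (int k = it->second.first; k < it->second.second; ++k) {
        int j = trees[t].rows[k];
        w[j] += inbag(j, t) / S;
      }
      ++nt;
    }
    used[i] = nt;
    if (nt == 0) {
      for (int k = 0; k < ntau; ++k) Q(i, k) = NA_REAL;
      mean_pred[i] = NA_REAL;
      continue;
    }
    double mp = 0.0;
    for (int j = 0; j < n; ++j) {
      w[j] /= nt;
      mp += w[j] * y[j];
    }
    mean_pred[i] = mp;
    double cum = 0.0;
    int k = 0;
    for (int s = 0; s < n && k < ntau; ++s) {
      int j = ord[s] - 1;
      cum += w[j];
      while (k < ntau && cum >= taus[k] - eps) {
        Q(i, k) = y[j];
        ++k;
      }
    }
    // numerical shortfall of the cumulative sum below 1: assign the maximum
    for (; k < ntau; ++k) Q(i, k) = y[ord[n - 1] - 1];
  }
  return List::create(_["quantiles"] = Q, _["mean"] = mean_pred,
                      _["trees_used"] = used);
}
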