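// CART induction core. Kept in C++ for the same reason rpart and
// scikit-learn keep it compiled: the exhaustive best-split scan dominates
// the pipeline's runtime during incremental feature selection.
//
// Conventions (fixed for bit-reproducibility):
//   * candidate thresholds are midpoints of consecutive distinct sorted values
//   * routing: value <= threshold goes left
//   * split criterion: minimise nL*gini(L) + nR*gini(R); accepted only when
//     strictly below the parent's n*gini (impurity decrease > 0)
//   * ties: lowest feature index, then smallest threshold (guaranteed by
//     scanning features ascending and thresholds ascending with strict '<')
//   * leaf prediction: majority class, ties -> class 0

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct BestSplit {
  int feature = -1;  // 0-based
  double threshold = 0.0;
  double child_score = 0.0;  // nL*giniL + nR*giniR (lower is better)
  bool found = false;
};

// Scan one feature over a node's samples, `ord` sorted ascending by value.
void scan_feature(const double* col, const int* ord, int n, const int* y,
                  int c1_total, int min_leaf, int feat, double parent_score,
                  BestSplit& best) {
  int c1L = 0;
  for (int i = 0; i < n - 1; ++i) {
    c1L += y[ord[i]];
    const double v = col[ord[i]], vnext = col[ord[i + 1]];
    if (!(v < vnext)) continue;  // only split between distinct values
    const int nL = i + 1, nR = n - nL;
    if (nL < min_leaf || nR < min_leaf) continue;
    const int c0L = nL - c1L;
    const int c1R = c1_total - c1L, c0R = nR - c1R;
    const double score =
        (double)nL - ((double)c0L * c0L + (double)c1L * c1L) / nL +
        (double)nR - ((double)c0R * c0R + (double)c1R * c1R) / nR;
    const double bound = best.found ? best.child_score : parent_score;
    if (score < bound) {
      best.found = true;
      best.feature = feat;
      best.threshold = (v + vnext) / 2.0;
      best.child_score = score;
    }
  }
}

}  // namespace

// Best split over samples `idx` (1-based row indices). Returns a list with
// found / feature (1-based) / threshold / gain (weighted gini decrease).
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, IntegerVector idx,
                    int min_leaf) {
  const int m = idx.size(), p = X.ncol();
  std::vector<int> rows(m);
  int c1 = 0;
  for (int i = 0; i < m; ++i) {
    rows[i] = idx[i] - 1;
    c1 += y[rows[i]];
  }
  const int c0 = m - c1;
  const double parent =
      (double)m - ((double)c0 * c0 + (double)c1 * c1) / m;
  const int* yp = INTEGER(y);
  BestSplit best;
  std::vector<int> o(m);
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    std::copy(rows.begin(), rows.end(), o.begin());
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    scan_feature(col, o.data(), m, yp, c1, min_leaf, j, parent, best);
  }
  if (!best.found) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["feature"] = best.feature + 1,
                      _["threshold"] = best.threshold,
                      _["gain"] = (parent - best.child_score) / m);
}

// Grow a full binary CART tree. max_depth < 0 means unlimited. Returns a
// flat node table; left/right are 1-based node indices (0 = leaf).
// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int max_depth,
                   int min_split, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  const int* yp = INTEGER(y);

  // Per-feature sample order, sorted once at the root and partitioned in
  // place down the tree (keeps induction O(p * n) per node after the sort).
  std::vector<int> ord((size_t)p * n);
  for (int j = 0; j < p; ++j) {
    int* oj = ord.data() + (size_t)j * n;
    for (int i = 0; i < n; ++i) oj[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(oj, oj + n,
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<int> scratch(n);
  std::vector<char> go_left(n);

  std::vector<int> feature, left, right, n0s, n1s, pred, is_leaf;
  std::vector<double> thr;
  auto new_node = [&]() {
    feature.push_back(NA_INTEGER);
    thr.push_back(NA_REAL);
    left.push_back(0);
    right.push_back(0);
    n0s.push_back(0);
    n1s.push_back(0);
    pred.push_back(0);
    is_leaf.push_back(1);
    return (int)feature.size() - 1;
  };

  struct Frame {
    int lo, hi, depth, id;
  };
  std::vector<Frame> stack;
  stack.push_back({0, n, 0, new_node()});

  while (!stack.empty()) {
    const Frame f = stack.back();
    stack.pop_back();
    const int lo = f.lo, m = f.hi - f.lo, id = f.id;
    const int* o0 = ord.data() + lo;  // feature-0 segment holds node samples
    int c1 = 0;
    for (int i = 0; i < m; ++i) c1 += yp[o0[i]];
    const int c0 = m - c1;
    n0s[id] = c0;
    n1s[id] = c1;
    pred[id] = (c1 > c0) ? 1 : 0;

    const bool stop = c0 == 0 || c1 == 0 || m < min_split ||
                      (max_depth >= 0 && f.depth >= max_depth);
    BestSplit best;
    if (!stop) {
      const double parent =
          (double)m - ((double)c0 * c0 + (double)c1 * c1) / m;
      for (int j = 0; j < p; ++j) {
        scan_feature(&X(0, j), ord.data() + (size_t)j * n + lo, m, yp, c1,
                     min_leaf, j, parent, best);
      }
    }
    if (!best.found) continue;

    is_leaf[id] = 0;
    feature[id] = best.feature + 1;
    thr[id] = best.threshold;
    const double* bc = &X(0, best.feature);
    int nL = 0;
    for (int i = 0; i < m; ++i) {
      const int s = o0[i];
      const bool gl = bc[s] <= best.threshold;
      go_left[s] = gl;
      nL += gl;
    }
    for (int j = 0; j < p; ++j) {
      int* oj = ord.data() + (size_t)j * n + lo;
      int a = 0, b = 0;
      for (int i = 0; i < m; ++i) {
        const int s = oj[i];
        if (go_left[s])
          oj[a++] = s;
        else
          scratch[b++] = s;
      }
      std::copy(scratch.begin(), scratch.begin() + b, oj + a);
    }
    const int lid = new_node(), rid = new_node();
    left[id] = lid + 1;
    right[id] = rid + 1;
    stack.push_back({lo + nL, f.hi, f.depth + 1, rid});
    stack.push_back({lo, lo + nL, f.depth + 1, lid});
  }

  return List::create(
      _["is_leaf"] = IntegerVector(is_leaf.begin(), is_leaf.end()),
      _["feature"] = IntegerVector(feature.begin(), feature.end()),
      _["threshold"] = NumericVector(thr.begin(), thr.end()),
      _["left"] = IntegerVector(left.begin(), left.end()),
      _["right"] = IntegerVector(right.begin(), right.end()),
      _["n0"] = IntegerVector(n0s.begin(), n0s.end()),
      _["n1"] = IntegerVector(n1s.begin(), n1s.end()),
      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}
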