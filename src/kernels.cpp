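#include <Rcpp.h>
#include <algorithm>
#include <cfloat>
using namespace Rcpp;

static inline double sqdist(const NumericMatrix &A, int i,
                            const NumericMatrix &B, int j) {
  double dx = A(i, 0) - B(j, 0);
  double dy = A(i, 1) - B(j, 1);
  double dz = A(i, 2) - B(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// Greedy farthest point sampling. Each new index maximises the distance to
// the already selected set; ties broken by lowest index. 1-based in/out.
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix X, int m, int start) {
  int n = X.nrow();
  if (m < 1 || m > n) stop("m must be in [1, n]");
  if (start < 1 || start > n) stop("start index out of range");
  IntegerVector sel(m);
  std::vector<double> d2(n, DBL_MAX);
  int cur = start - 1;
  sel[0] = cur + 1;
  for (int j = 1; j < m; ++j) {
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      double d = sqdist(X, i, X, cur);
      if (d < d2[i]) d2[i] = d;
      if (d2[i] > bestd) {  // strict: lowest index wins ties
        bestd = d2[i];
        best = i;
      }
    }
    cur = best;
    sel[j] = cur + 1;
  }
  return sel;
}

// Maximum pairwise Euclidean distance (exhaustive O(m^2) scan).
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix X) {
  int n = X.nrow();
  if (n < 2) stop("need at least two points");
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = sqdist(X, i, X, j);
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Ball query: for each centroid, up to `cap` indices of points within
// `radius`, in ascending input-index order. Fewer than cap found: pad by
// repeating the first found index. None found: repeat the nearest point.
// Returns an m x cap matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix ball_query_cpp(NumericMatrix X, NumericMatrix C, double radius,
                             int cap) {
  int n = X.nrow(), m = C.nrow();
  if (n < 1) stop("empty cloud");
  if (radius <= 0) stop("radius must be positive");
  if (cap < 1) stop("cap must be >= 1");
  double r2 = radius * radius;
  IntegerMatrix out(m, cap);
  for (int c = 0; c < m; ++c) {
    int found = 0;
    int nearest = 0;
    double neard = DBL_MAX;
    for (int i = 0; i < n && found < cap; ++i) {
      double d = sqdist(X, i, C, c);
      if (d < neard) {
        neard = d;
        nearest = i;
      }
      if (d <= r2) out(c, found++) = i + 1;
    }
    if (found == 0) {
      // finish the nearest scan (loop above may have stopped early only
      // when found == cap, so here it saw all points)
      for (int j = 0; j < cap; ++j) out(c, j) = nearest + 1;
    } else {
      for (int j = found; j < cap; ++j) out(c, j) = out(c, 0);
    }
  }
  return out;
}

// Ball query over several radii sharing the same centroids: each
// centroid's distances are computed once. Same member/padding semantics
// as ball_query_cpp, applied per radius.
// [[Rcpp::export]]
List ball_query_multi_cpp(NumericMatrix X, NumericMatrix C,
                          NumericVector radii, IntegerVector caps) {
  int n = X.nrow(), m = C.nrow(), nb = radii.size();
  if (n < 1) stop("empty cloud");
  List out(nb);
  std::vector<IntegerMatrix> mats(nb);
  std::vector<double> r2(nb);
  for (int b = 0; b < nb; ++b) {
    if (radii[b] <= 0) stop("radius must be positive");
    if (caps[b] < 1) stop("cap must be >= 1");
    mats[b] = IntegerMatrix(m, caps[b]);
    r2[b] = radii[b] * radii[b];
  }
  std::vector<int> found(nb);
  for (int c = 0; c < m; ++c) {
    std::fill(found.begin(), found.end(), 0);
    int nearest = 0;
    double neard = DBL_MAX;
    for (int i = 0; i < n; ++i) {
      double d = sqdist(X, i, C, c);
      if (d < neard) {
        neard = d;
        nearest = i;
      }
      for (int b = 0; b < nb; ++b)
        if (found[b] < caps[b] && d <= r2[b]) mats[b](c, found[b]++) = i + 1;
    }
    for (int b = 0; b < nb; ++b) {
      if (found[b] == 0)
        for (int j = 0; j < caps[b]; ++j) mats[b](c, j) = nearest + 1;
      else
        for (int j = found[b]; j < caps[b]; ++j) mats[b](c, j) = mats[b](c, 0);
    }
  }
  for (int b = 0; b < nb; ++b) out[b] = mats[b];
  return out;
}

// Max over each centroid's `cap` contiguous rows. Returns the pooled
// m x C matrix and the (1-based) source row of each maximum.
// [[Rcpp::export]]
List pool_max_cpp(NumericMatrix H, int m, int cap) {
  int C = H.ncol();
  NumericMatrix M(m, C);
  IntegerMatrix A(m, C);
  for (int g = 0; g < m; ++g) {
    int r0 = g * cap;
    for (int j = 0; j < C; ++j) {
      double best = H(r0, j);
      int bi = r0;
      for (int r = r0 + 1; r < r0 + cap; ++r)
        if (H(r, j) > best) {
          best = H(r, j);
          bi = r;
        }
      M(g, j) = best;
      A(g, j) = bi + 1;
    }
  }
  return List::create(_["M"] = M, _["argmax"] = A);
}

// Add a bias per column and optionally apply ReLU, in place on a freshly
// allocated matmul result.
// [[Rcpp::export]]
NumericMatrix bias_act_cpp(NumericMatrix Z, NumericVector b, bool relu) {
  int n = Z.nrow(), C = Z.ncol();
  for (int j = 0; j < C; ++j) {
    double bj = b[j];
    for (int i = 0; i < n; ++i) {
      double v = Z(i, j) + bj;
      Z(i, j) = (relu && v < 0) ? 0 : v;
    }
  }
  return Z;
}

// k nearest neighbours of each query row among the reference rows.
// Returns idx (q x k, 1-based, ascending distance) and dist (q x k).
// [[Rcpp::export]]
List knn_cpp(NumericMatrix Q, NumericMatrix R, int k) {
  int q = Q.nrow(), n = R.nrow();
  if (k < 1 || k > n) stop("k must be in [1, nrow(ref)]");
  IntegerMatrix idx(q, k);
  NumericMatrix dist(q, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j < n; ++j) d[j] = std::make_pair(sqdist(Q, i, R, j), j);
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d[j].second + 1;
      dist(i, j) = std::sqrt(d[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
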