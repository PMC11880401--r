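#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming kernels for dynamic time warping (DTW), DTW barycenter
// averaging (DBA) and soft-DTW.  Inner cost is the squared difference
// d(x_i, y_j) = (x_i - y_j)^2; the accumulated optimum is returned un-rooted
// (callers take one final sqrt to obtain the DTW distance).

static inline double sq(double a, double b) {
  double d = a - b;
  return d * d;
}

// Accumulated-cost matrix, row-major (M+1)x(N+1) with +Inf borders.
static std::vector<double> acc_matrix(const NumericVector& x,
                                      const NumericVector& y) {
  const int M = x.size(), N = y.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> D((M + 1) * (N + 1), inf);
  D[0] = 0.0;
  for (int i = 1; i <= M; ++i) {
    for (int j = 1; j <= N; ++j) {
      double diag = D[(i - 1) * (N + 1) + (j - 1)];
      double vert = D[(i - 1) * (N + 1) + j];
      double horz = D[i * (N + 1) + (j - 1)];
      double best = diag;
      if (vert < best) best = vert;
      if (horz < best) best = horz;
      D[i * (N + 1) + j] = sq(x[i - 1], y[j - 1]) + best;
    }
  }
  return D;
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y) {
  if (x.size() == 0 || y.size() == 0)
    stop("empty series in DTW");
  std::vector<double> D = acc_matrix(x, y);
  return D[x.size() * (y.size() + 1) + y.size()];
}

// Optimal cost plus warp path (1-based index pairs).  Ties in backtracking are
// broken diagonal, then vertical (advance i), then horizontal, so paths are
// bit-reproducible.
// [[Rcpp::export]]
List dtw_path_cpp(NumericVector x, NumericVector y) {
  if (x.size() == 0 || y.size() == 0)
    stop("empty series in DTW");
  const int M = x.size(), N = y.size();
  std::vector<double> D = acc_matrix(x, y);
  std::vector<std::pair<int, int> > rev;
  int i = M, j = N;
  rev.push_back(std::make_pair(i, j));
  while (i > 1 || j > 1) {
    double diag = D[(i - 1) * (N + 1) + (j - 1)];
    double vert = D[(i - 1) * (N + 1) + j];
    double horz = D[i * (N + 1) + (j - 1)];
    if (diag <= vert && diag <= horz) {
      --i; --j;
    } else if (vert <= horz) {
      --i;
    } else {
      --j;
    }
    rev.push_back(std::make_pair(i, j));
  }
  const int K = rev.size();
  IntegerMatrix path(K, 2);
  for (int k = 0; k < K; ++k) {
    path(k, 0) = rev[K - 1 - k].first;
    path(k, 1) = rev[K - 1 - k].second;
  }
  return List::create(_["cost"] = D[M * (N + 1) + N], _["path"] = path);
}

// Full pairwise DTW distance matrix (sqrt of optimal accumulated cost).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series) {
  const int n = series.size();
  NumericMatrix out(n, n);
  std::vector<NumericVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::sqrt(dtw_cost_cpp(xs[i], xs[j]));
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// DTW distances (sqrt) from every series to every reference series.
// [[Rcpp::export]]
NumericMatrix dtw_to_refs_cpp(List series, List refs) {
  const int n = series.size(), k = refs.size();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    NumericVector mu = as<NumericVector>(refs[j]);
    for (int i = 0; i < n; ++i)
      out(i, j) = std::sqrt(dtw_cost_cpp(as<NumericVector>(series[i]), mu));
  }
  return out;
}

// One DBA update step: align every series to mu along the optimal warp path,
// average the values mapped onto each barycenter coordinate.  Returns the
// updated barycenter and the objective (sum of squared DTW costs) evaluated
// at the *incoming* mu.
// [[Rcpp::export]]
List dba_update_cpp(List series, NumericVector mu) {
  const int T = mu.size(), n = series.size();
  std::vector<double> sums(T, 0.0);
  std::vector<double> counts(T, 0.0);
  double objective = 0.0;
  for (int s = 0; s < n; ++s) {
    NumericVector x = as<NumericVector>(series[s]);
    List pr = dtw_path_cpp(mu, x);
    objective += as<double>(pr["cost"]);
    IntegerMatrix path = pr["path"];
    for (int k = 0; k < path.nrow(); ++k) {
      sums[path(k, 0) - 1] += x[path(k, 1) - 1];
      counts[path(k, 0) - 1] += 1.0;
    }
  }
  NumericVector mu_new(T);
  for (int t = 0; t < T; ++t)
    mu_new[t] = counts[t] > 0 ? sums[t] / counts[t] : mu[t];
  return List::create(_["mu"] = mu_new, _["objective"] = objective);
}

static inline double softmin3(double a, double b, double c, double gamma) {
  double m = a;
  if (b < m) m = b;
  if (c < m) m = c;
  if (!std::isfinite(m)) return m;
  double s = std::exp(-(a - m) / gamma) + std::exp(-(b - m) / gamma) +
             std::exp(-(c - m) / gamma);
  return m - gamma * std::log(s);
}

// Soft-DTW accumulated cost (Cuturi & Blondel): min replaced by
// softmin_gamma(a) = -gamma * log(sum_i exp(-a_i/gamma)).
// [[Rcpp::export]]
double softdtw_cpp(NumericVector x, NumericVector y, double gamma) {
  if (gamma <= 0) stop("gamma must be positive");
  if (x.size() == 0 || y.size() == 0) stop("empty series in soft-DTW");
  const int M = x.size(), N = y.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> R((M + 1) * (N + 1), inf);
  R[0] = 0.0;
  for (int i = 1; i <= M; ++i)
    for (int j = 1; j <= N; ++j)
      R[i * (N + 1) + j] =
        sq(x[i - 1], y[j - 1]) +
        softmin3(R[(i - 1) * (N + 1) + (j - 1)], R[(i - 1) * (N + 1) + j],
                 R[i * (N + 1) + (j - 1)], gamma);
  return R[M * (N + 1) + N];
}

// Soft-DTW cost plus gradient with respect to z (first argument), via the
// backward (E-matrix) recursion.
// [[Rcpp::export]]
List softdtw_grad_cpp(NumericVector z, NumericVector x, double gamma) {
  if (gamma <= 0) stop("gamma must be positive");
  const int M = z.size(), N = x.size();
  const double inf = std::numeric_limits<double>::infinity();
  // R padded (M+2)x(N+2)
  std::vector<double> R((M + 2) * (N + 2), -inf);
  std::vector<double> d((M + 2) * (N + 2), 0.0);
  const int W = N + 2;
  R[0] = 0.0;
  for (int i = 1; i <= M; ++i) R[i * W] = inf;
  for (int j = 1; j <= N; ++j) R[j] = inf;
  for (int i = 1; i <= M; ++i) {
    for (int j = 1; j <= N; ++j) {
      d[i * W + j] = sq(z[i - 1], x[j - 1]);
      R[i * W + j] = d[i * W + j] +
        softmin3(R[(i - 1) * W + (j - 1)], R[(i - 1) * W + j],
                 R[i * W + (j - 1)], gamma);
    }
  }
  double cost = R[M * W + N];
  std::vector<double> E((M + 2) * (N + 2), 0.0);
  E[(M + 1) * W + (N + 1)] = 1.0;
  R[(M + 1) * W + (N + 1)] = cost;
  for (int i = M; i >= 1; --i) {
    for (int j = N; j >= 1; --j) {
      double rij = R[i * W + j];
      double a = E[(i + 1) * W + j] *
        std::exp((R[(i + 1) * W + j] - rij - d[(i + 1) * W + j]) / gamma);
      double b = E[i * W + (j + 1)] *
        std::exp((R[i * W + (j + 1)] - rij - d[i * W + (j + 1)]) / gamma);
      double c = E[(i + 1) * W + (j + 1)] *
        std::exp((R[(i + 1) * W + (j + 1)] - rij - d[(i + 1) * W + (j + 1)]) /
                 gamma);
      if (!std::isfinite(a)) a = 0.0;
      if (!std::isfinite(b)) b = 0.0;
      if (!std::isfinite(c)) c = 0.0;
      E[i * W + j] = a + b + c;
    }
  }
  NumericVector grad(M);
  for (int i = 1; i <= M; ++i) {
    double g = 0.0;
    for (int j = 1; j <= N; ++j)
      g += E[i * W + j] * 2.0 * (z[i - 1] - x[j - 1]);
    grad[i - 1] = g;
  }
  return List::create(_["cost"] = cost, _["grad"] = grad);
}
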