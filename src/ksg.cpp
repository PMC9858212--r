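#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual-information estimator (variant 1)
// with max-norm balls, brute-force O(n^2). Inputs must be tie-free (the R
// wrapper adds deterministic jitter).
//
// I(X;Y) = digamma(k) + digamma(n) - < digamma(nx + 1) + digamma(ny + 1) >
// where nx, ny count points strictly inside the k-th joint neighbour
// distance in the marginal spaces.

static inline double cheb(const double* a, const double* b, int d, int n) {
  // column-major rows a, b of an n x d matrix
  double m = 0.0;
  for (int j = 0; j < d; ++j) {
    double v = std::fabs(a[(size_t)j * n] - b[(size_t)j * n]);
    if (v > m) m = v;
  }
  return m;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  const int dx = x.ncol();
  const int dy = y.ncol();
  if (y.nrow() != n) stop("x and y need equal sample counts");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");

  const double* px = REAL(x);
  const double* py = REAL(y);

  std::vector<double> dxv(n), dyv(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = px + i;
    const double* yi = py + i;
    for (int j = 0; j < n; ++j) {
      dxv[j] = cheb(xi, px + j, dx, n);
      dyv[j] = cheb(yi, py + j, dy, n);
    }
    // k-th smallest joint distance among j != i
    std::vector<double> joint(n);
    for (int j = 0; j < n; ++j) joint[j] = std::max(dxv[j], dyv[j]);
    joint[i] = R_PosInf;
    std::nth_element(joint.begin(), joint.begin() + (k - 1), joint.end());
    const double eps = joint[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dxv[j] < eps) ++nx;
      if (dyv[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi;
}
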