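#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Plug-in resubstitution MI on copula-transformed data with a fixed-width
// Gaussian kernel. The 1/(h*sqrt(2*pi)) kernel constant cancels between the
// joint density and the product of marginals, so kernels are left
// unnormalized throughout.
//
// MI = mean_i log f2(x_i, y_i) + log n - (mean_i log f1(x_i) + mean_i log f1(y_i))
//
// Grouping the two marginal terms before the subtraction keeps the estimate
// bit-identical under argument swap.

static void fill_kernel(const double *x, int n, double inv2h2,
                        std::vector<double> &K) {
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = 0; j < i; ++j) {
      double d = x[i] - x[j];
      double v = std::exp(-d * d * inv2h2);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
}

// mean_i log( sum_j K[i,j] )  (the log-marginal term, up to the shared log n)
static double mean_log_rowsum(const std::vector<double> &K, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    const double *k = &K[(size_t)i * n];
    for (int j = 0; j < n; ++j) r += k[j];
    s += std::log(r);
  }
  return s / n;
}

static double mi_joint_term(const std::vector<double> &Kx,
                            const std::vector<double> &Ky, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double f2 = 0.0;
    const double *kx = &Kx[(size_t)i * n];
    const double *ky = &Ky[(size_t)i * n];
    for (int j = 0; j < n; ++j) f2 += kx[j] * ky[j];
    s += std::log(f2);
  }
  return s / n;
}

// [[Rcpp::export]]
double mi_pair_cpp(NumericVector x, NumericVector y, double h) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<double> Kx((size_t)n * n), Ky((size_t)n * n);
  fill_kernel(REAL(x), n, inv2h2, Kx);
  fill_kernel(REAL(y), n, inv2h2, Ky);
  double m1 = mean_log_rowsum(Kx, n) + mean_log_rowsum(Ky, n);
  return mi_joint_term(Kx, Ky, n) + std::log((double)n) - m1;
}

// All-pairs MI between rows of X (p x n) and rows of Y (q x n).
// If symmetric is true (X and Y are the same matrix), only the upper
// triangle j > i is computed; other entries are NA.
// [[Rcpp::export]]
NumericMatrix mi_cross_cpp(NumericMatrix X, NumericMatrix Y, double h,
                           bool symmetric) {
  int p = X.nrow(), q = Y.nrow(), n = X.ncol();
  if (Y.ncol() != n) stop("X and Y must have the same number of columns");
  double inv2h2 = 1.0 / (2.0 * h * h);

  std::vector<std::vector<double>> KX(p), KY;
  std::vector<double> a1x(p), a1y;
  std::vector<double> row(n);
  for (int i = 0; i < p; ++i) {
    KX[i].resize((size_t)n * n);
    for (int s = 0; s < n; ++s) row[s] = X(i, s);
    fill_kernel(row.data(), n, inv2h2, KX[i]);
    a1x[i] = mean_log_rowsum(KX[i], n);
  }
  const std::vector<std::vector<double>> *KYp = &KX;
  const std::vector<double> *a1yp = &a1x;
  if (!symmetric) {
    KY.resize(q);
    a1y.resize(q);
    for (int i = 0; i < q; ++i) {
      KY[i].resize((size_t)n * n);
      for (int s = 0; s < n; ++s) row[s] = Y(i, s);
      fill_kernel(row.data(), n, inv2h2, KY[i]);
      a1y[i] = mean_log_rowsum(KY[i], n);
    }
    KYp = &KY;
    a1yp = &a1y;
  }

  double logn = std::log((double)n);
  NumericMatrix out(p, q);
  for (int i = 0; i < p; ++i) {
    Rcpp::checkUserInterrupt();
    int j0 = symmetric ? i + 1 : 0;
    if (symmetric)
      for (int j = 0; j <= i; ++j) out(i, j) = NA_REAL;
    for (int j = j0; j < q; ++j) {
      out(i, j) =
          mi_joint_term(KX[i], (*KYp)[j], n) + logn - (a1x[i] + (*a1yp)[j]);
    }
  }
  return out;
}

// MI of x against column-permutations of y. perms is n x m, 1-based.
// [[Rcpp::export]]
NumericVector mi_perm_cpp(NumericVector x, NumericVector y, double h,
                          IntegerMatrix perms) {
  int n = x.size(), m = perms.ncol();
  if (y.size() != n || perms.nrow() != n) stop("dimension mismatch");
  double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<double> Kx((size_t)n * n), Ky((size_t)n * n);
  fill_kernel(REAL(x), n, inv2h2, Kx);
  fill_kernel(REAL(y), n, inv2h2, Ky);
  // marginal terms are permutation-invariant (same multiset of row sums)
  double m1 = mean_log_rowsum(Kx, n) + mean_log_rowsum(Ky, n);
  double logn = std::log((double)n);

  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<int> p0(n);
    for (int i = 0; i < n; ++i) p0[i] = perms(i, t) - 1;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double f2 = 0.0;
      const double *kx = &Kx[(size_t)i * n];
      const double *ky = &Ky[(size_t)p0[i] * n];
      for (int j = 0; j < n; ++j) f2 += kx[j] * ky[p0[j]];
      s += std::log(f2);
    }
    out[t] = s / n + logn - m1;
  }
  return out;
}
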