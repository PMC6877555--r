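#include <Rcpp.h>
using namespace Rcpp;

// Linear L1-loss (hinge) SVM solved in the dual by coordinate descent,
// one-vs-rest for multiclass. The bias is handled through an augmented
// constant feature, so it is (weakly) regularized like the weights.
// Deterministic: the coordinate order is shuffled by a fixed xorshift
// stream, so identical inputs give identical models.

static void solve_binary(const NumericMatrix& X, const std::vector<double>& y,
                         double C, double tol, int max_epoch,
                         std::vector<double>& w) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), Q(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented bias feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    Q[i] = s;
  }
  std::fill(w.begin(), w.end(), 0.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long rng = 88172645463325252ULL;
  for (int epoch = 0; epoch < max_epoch; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
      int j = (int)(rng % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    // stop on the projected-gradient gap over the epoch (liblinear-style)
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      double G = -1.0 + y[i] * w[d];
      for (int j = 0; j < d; ++j) G += y[i] * w[j] * X(i, j);
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (PG != 0.0) {
        const double a_old = alpha[i];
        const double a_new = std::min(std::max(a_old - G / Q[i], 0.0), C);
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        w[d] += delta;
      }
    }
    if (pg_max - pg_min < tol) break;
  }
}

// Returns a (d+1) x K matrix of weights; last row is the bias of each
// one-vs-rest classifier. Labels must be integers in 1..n_class.
// [[Rcpp::export]]
NumericMatrix ovr_svm_train(NumericMatrix X, IntegerVector y, int n_class,
                            double C, double tol = 0.1, int max_epoch = 1000) {
  const int d = X.ncol(), n = X.nrow();
  if (y.size() != n) stop("label length does not match row count");
  NumericMatrix W(d + 1, n_class);
  std::vector<double> yy(n), w(d + 1);
  for (int c = 0; c < n_class; ++c) {
    for (int i = 0; i < n; ++i) yy[i] = (y[i] == c + 1) ? 1.0 : -1.0;
    solve_binary(X, yy, C, tol, max_epoch, w);
    for (int j = 0; j <= d; ++j) W(j, c) = w[j];
  }
  return W;
}

// Predict class index (1..K) by the largest one-vs-rest decision value.
// [[Rcpp::export]]
IntegerVector ovr_svm_predict(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), d = X.ncol(), K = W.ncol();
  if (W.nrow() != d + 1) stop("weight matrix does not match feature count");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = -std::numeric_limits<double>::infinity();
    int arg = 1;
    for (int c = 0; c < K; ++c) {
      double s = W(d, c);
      for (int j = 0; j < d; ++j) s += W(j, c) * X(i, j);
      if (s > best) { best = s; arg = c + 1; }
    }
    out[i] = arg;
  }
  return out;
}

// Column-wise median and inter-quartile range (type-7 quantiles), used for
// robust feature scaling inside the cross-validation loop.
// [[Rcpp::export]]
NumericMatrix col_med_iqr(NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least two rows");
  NumericMatrix out(2, d);
  std::vector<double> v(n);
  auto q7 = [&](double p) {
    const double h = (n - 1) * p;
    const int lo = (int)std::floor(h);
    const int hi = std::min(lo + 1, n - 1);
    return v[lo] + (h - lo) * (v[hi] - v[lo]);
  };
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    out(0, j) = q7(0.5);
    out(1, j) = q7(0.75) - q7(0.25);
  }
  return out;
}
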