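#include <Rcpp.h>
using namespace Rcpp;

// Steady-state initial filter state for a unit-step input (the classic
// lfilter_zi construction): solve (I - A^T) zi = B with A the companion
// matrix of a and B = b[1:] - b[0] * a[1:], by Gaussian elimination.
static std::vector<double> step_zi(const std::vector<double>& b,
                                   const std::vector<double>& a,
                                   size_t nz) {
  std::vector<double> M(nz * nz, 0.0), B(nz);
  auto bk = [&](size_t k) { return (k < b.size()) ? b[k] : 0.0; };
  auto ak = [&](size_t k) { return (k < a.size()) ? a[k] : 0.0; };
  for (size_t i = 0; i < nz; ++i) {
    M[i * nz + 0] += ak(i + 1);
    M[i * nz + i] += 1.0;
    if (i + 1 < nz) M[i * nz + i + 1] -= 1.0;
    B[i] = bk(i + 1) - ak(i + 1) * bk(0);
  }
  for (size_t c = 0; c < nz; ++c) {          // partial-pivot elimination
    size_t p = c;
    for (size_t r = c + 1; r < nz; ++r)
      if (std::fabs(M[r * nz + c]) > std::fabs(M[p * nz + c])) p = r;
    if (p != c) {
      for (size_t k = 0; k < nz; ++k) std::swap(M[c * nz + k], M[p * nz + k]);
      std::swap(B[c], B[p]);
    }
    const double piv = M[c * nz + c];
    for (size_t r = c + 1; r < nz; ++r) {
      const double f = M[r * nz + c] / piv;
      for (size_t k = c; k < nz; ++k) M[r * nz + k] -= f * M[c * nz + k];
      B[r] -= f * B[c];
    }
  }
  std::vector<double> zi(nz);
  for (size_t i = nz; i-- > 0;) {
    double s = B[i];
    for (size_t k = i + 1; k < nz; ++k) s -= M[i * nz + k] * zi[k];
    zi[i] = s / M[i * nz + i];
  }
  return zi;
}

// Direct-form II transposed IIR filter, single pass, state seeded with the
// steady-state response to the first sample so edge transients vanish.
static std::vector<double> iir_pass(const std::vector<double>& b,
                                    const std::vector<double>& a,
                                    const std::vector<double>& x) {
  const size_t n = x.size(), nb = b.size(), na = a.size();
  const size_t nz = std::max(nb, na) - 1;
  std::vector<double> z = step_zi(b, a, nz), y(n);
  for (size_t k = 0; k < nz; ++k) z[k] *= x.empty() ? 0.0 : x[0];
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = (nz ? z[0] : 0.0) + b[0] * xi;
    for (size_t k = 0; k < nz; ++k) {
      const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      const double znext = (k + 1 < nz) ? z[k + 1] : 0.0;
      z[k] = znext + bk * xi - ak * yi;
    }
    y[i] = yi;
  }
  return y;
}

// Zero-phase forward-backward IIR filtering with odd-symmetric edge
// extension of length 3 * (filter order), as is conventional for
// transient suppression. Coefficients are assumed normalized (a[0] = 1).
// [[Rcpp::export]]
NumericVector filtfilt_iir(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int order = std::max(b.size(), a.size()) - 1;
  const int pad = 3 * order;
  if (n <= pad)
    stop("signal too short for zero-phase filtering (need > %d samples)", pad);
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  std::vector<double> ext(n + 2 * pad);
  for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) ext[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  std::vector<double> y = iir_pass(bb, aa, ext);
  std::reverse(y.begin(), y.end());
  y = iir_pass(bb, aa, y);
  std::reverse(y.begin(), y.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[pad + i];
  return out;
}
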