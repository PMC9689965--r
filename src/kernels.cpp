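#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Lempel-Ziv 1976 production-style pattern counter (Kaspar & Schuster
// formulation).  The counter starts at 1 (the first symbol is the first
// pattern) and is incremented once more for the final, possibly incomplete,
// phrase.  A constant sequence therefore yields C(n) = 2 for n >= 2.
// [[Rcpp::export]]
int lz76_count(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) stop("empty symbol sequence");
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Bulk standard-normal matrix from a dedicated 64-bit Mersenne stream.
// Used for the synthetic generator's high-volume noise; the stream seed is
// itself drawn from R's seeded RNG, so cohort reproducibility is preserved.
// [[Rcpp::export]]
NumericMatrix rnorm_mat(int n, int p, double seed) {
  std::mt19937_64 eng((uint64_t)seed);
  std::normal_distribution<double> N(0.0, 1.0);
  NumericMatrix out(n, p);
  double* ptr = out.begin();
  const R_xlen_t total = (R_xlen_t)n * p;
  for (R_xlen_t i = 0; i < total; ++i) ptr[i] = N(eng);
  return out;
}

// Assemble MI trials: out[ch, t, trial] = noise[(trial,t), ch] +
// mu[(trial,t), ch] * scale[trial, ch], where mu/noise are (win*ntr) x nc
// long matrices with trials stacked in time.  Avoids several large
// intermediate copies on the R side.
// [[Rcpp::export]]
NumericVector assemble_trials(const NumericMatrix& mu,
                              const NumericMatrix& noise,
                              const NumericMatrix& scale, int win) {
  const int nc = mu.ncol();
  const int ntr = scale.nrow();
  if (mu.nrow() != win * ntr || noise.nrow() != mu.nrow() ||
      scale.ncol() != nc)
    stop("inconsistent dimensions in assemble_trials");
  NumericVector out(Dimension(nc, win, ntr));
  double* o = out.begin();
  for (int tr = 0; tr < ntr; ++tr)
    for (int c = 0; c < nc; ++c) {
      const double s = scale(tr, c);
      const double* m = &mu(tr * win, c);
      const double* w = &noise(tr * win, c);
      double* dst = o + (R_xlen_t)tr * nc * win + c;
      for (int t = 0; t < win; ++t) dst[(R_xlen_t)t * nc] = w[t] + m[t] * s;
    }
  return out;
}

// Direct-form II transposed IIR filter of one vector, in place.
// b and a are already normalised (a[0] == 1) and zero-padded to equal
// length m; z holds m-1 states and is consumed.
static void df2t_filter(const std::vector<double>& b,
                        const std::vector<double>& a,
                        std::vector<double>& z,
                        double* x, int n) {
  const int m = (int)b.size();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of every column of x, with
// odd-reflection padding of length `padlen` at both ends and steady-state
// initial conditions `zi` scaled by the first padded sample -- the standard
// filtfilt edge treatment.
// [[Rcpp::export]]
NumericMatrix filtfilt_cols(const NumericVector& b, const NumericVector& a,
                            const NumericMatrix& x, const NumericVector& zi,
                            int padlen) {
  const int n = x.nrow(), p = x.ncol();
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  const int m = (int)std::max(b.size(), a.size());
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < m; ++i) { bb[i] /= aa[0]; }
  for (int i = m - 1; i >= 0; --i) aa[i] /= aa[0];
  if ((int)zi.size() != m - 1) stop("zi has wrong length");

  NumericMatrix out(n, p);
  const int N = n + 2 * padlen;
  std::vector<double> w(N), z(m - 1);
  for (int col = 0; col < p; ++col) {
    // odd reflection about the end points
    for (int i = 0; i < padlen; ++i) w[i] = 2.0 * x(0, col) - x(padlen - i, col);
    for (int i = 0; i < n; ++i) w[padlen + i] = x(i, col);
    for (int i = 0; i < padlen; ++i)
      w[padlen + n + i] = 2.0 * x(n - 1, col) - x(n - 2 - i, col);
    // forward pass
    for (int j = 0; j < m - 1; ++j) z[j] = zi[j] * w[0];
    df2t_filter(bb, aa, z, w.data(), N);
    // backward pass
    std::reverse(w.begin(), w.end());
    for (int j = 0; j < m - 1; ++j) z[j] = zi[j] * w[0];
    df2t_filter(bb, aa, z, w.data(), N);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(i, col) = w[padlen + i];
  }
  return out;
}
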