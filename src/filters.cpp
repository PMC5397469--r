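#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, optionally with initial state zi
// (length max(nb,na)-1). Coefficients must be normalised so a[0] == 1.
// [[Rcpp::export]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x,
                       NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[1] must be non-zero");
  if (aa[0] != 1.0) {
    for (int i = 0; i < n; ++i) { bb[i] /= aa[0]; }
    for (int i = n - 1; i >= 0; --i) aa[i] /= aa[0];
  }
  int ns = n - 1;
  std::vector<double> z(ns, 0.0);
  if (zi.size() > 0) {
    if ((int)zi.size() != ns) stop("zi must have length max(nb,na)-1");
    for (int i = 0; i < ns; ++i) z[i] = zi[i];
  }
  int N = x.size();
  NumericVector y(N);
  const double *xp = x.begin();
  double *yp = y.begin();
  if (ns == 8) {
    // order-8 state space (4th-order band-pass): keep states in registers
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3],
           z4 = z[4], z5 = z[5], z6 = z[6], z7 = z[7];
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4],
                 b5 = bb[5], b6 = bb[6], b7 = bb[7], b8 = bb[8];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4],
                 a5 = aa[5], a6 = aa[6], a7 = aa[7], a8 = aa[8];
    for (int i = 0; i < N; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi + z4 - a4 * yi;
      z4 = b5 * xi + z5 - a5 * yi;
      z5 = b6 * xi + z6 - a6 * yi;
      z6 = b7 * xi + z7 - a7 * yi;
      z7 = b8 * xi - a8 * yi;
      yp[i] = yi;
    }
    return y;
  }
  for (int i = 0; i < N; ++i) {
    double xi = xp[i];
    double yi = bb[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int j = 0; j < ns - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (ns > 0) z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    y[i] = yi;
  }
  return y;
}

// Cascade of second-order sections, direct form II transposed. sos is
// nsec x 6 (b0 b1 b2 a0 a1 a2, a0 == 1); zi is nsec x 2 initial states.
// [[Rcpp::export]]
NumericVector sos_df2t(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int nsec = sos.nrow(), N = x.size();
  if (zi.nrow() != nsec || zi.ncol() != 2) stop("zi must be nsec x 2");
  std::vector<double> b0(nsec), b1(nsec), b2(nsec), a1(nsec), a2(nsec),
      z1(nsec), z2(nsec);
  for (int s = 0; s < nsec; ++s) {
    double a0 = sos(s, 3);
    if (a0 == 0.0) stop("a0 must be non-zero");
    b0[s] = sos(s, 0) / a0; b1[s] = sos(s, 1) / a0; b2[s] = sos(s, 2) / a0;
    a1[s] = sos(s, 4) / a0; a2[s] = sos(s, 5) / a0;
    z1[s] = zi(s, 0); z2[s] = zi(s, 1);
  }
  NumericVector y(N);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int i = 0; i < N; ++i) {
    double v = xp[i];
    for (int s = 0; s < nsec; ++s) {
      const double w = b0[s] * v + z1[s];
      z1[s] = b1[s] * v + z2[s] - a1[s] * w;
      z2[s] = b2[s] * v - a2[s] * w;
      v = w;
    }
    yp[i] = v;
  }
  return y;
}

// Centred moving RMS over a window of w samples (clipped at the edges).
// [[Rcpp::export]]
NumericVector moving_rms_cpp(NumericVector x, int w) {
  int n = x.size();
  int h = w / 2;
  NumericVector y(n);
  std::vector<double> cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs2[i + 1] = cs2[i] + x[i] * x[i];
  for (int i = 0; i < n; ++i) {
    int lo = i - h; if (lo < 0) lo = 0;
    int hi = i + h + 1; if (hi > n) hi = n;
    y[i] = std::sqrt((cs2[hi] - cs2[lo]) / (hi - lo));
  }
  return y;
}
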