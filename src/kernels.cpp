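#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
// Counts unordered template pairs (i != j), both indices in 1..N-m (the
// printed normalisations cancel in the SampEn ratio, so raw counts suffice):
//   B = pairs whose length-m templates match (Chebyshev distance strictly < r)
//   A = pairs whose length-(m+1) templates match
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;           // number of usable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Lyapunov-style divergence terms for the spatial heterogeneity index.
// pts is an N x 3 trajectory. For each n with n + step < N, the nearest
// neighbour j (Euclidean, excluding |j - n| <= theiler and j with no advanced
// image) is found; the term is log(d2/d1) with d1 = |x_n - x_j| and
// d2 = |x_{n+step} - x_{j+step}|. Zero distances are skipped and counted.
// [[Rcpp::export]]
List shi_terms(NumericMatrix pts, int step, int theiler) {
  const int n = pts.nrow();
  std::vector<double> terms;
  int skipped = 0;
  for (int i = 0; i + step < n; ++i) {
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j + step < n; ++j) {
      if (std::abs(j - i) <= theiler) continue;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; jbest = j; }
    }
    if (jbest < 0) continue;
    double d1 = std::sqrt(best);
    double ax = pts(i + step, 0) - pts(jbest + step, 0);
    double ay = pts(i + step, 1) - pts(jbest + step, 1);
    double az = pts(i + step, 2) - pts(jbest + step, 2);
    double d2adv = std::sqrt(ax * ax + ay * ay + az * az);
    if (d1 == 0.0 || d2adv == 0.0) { ++skipped; continue; }
    terms.push_back(std::log(d2adv / d1));
  }
  return List::create(_["terms"] = wrap(terms), _["skipped"] = skipped);
}

// Direct-form II transposed IIR filter, single pass.
// a[0] is assumed 1 (caller normalises).
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = (nb > 0 ? b[0] * xi : 0.0) + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz; ++k) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      double znext = (k + 1 < nz) ? z[k + 1] : 0.0;
      z[k] = bk * xi - ak * yi + znext;
    }
    y[i] = yi;
  }
  return y;
}
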