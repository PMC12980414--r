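// Hot loops of the ensemble-selection stage: batched per-frame chi-square
// (histogram-accelerated Debye) and SMACOF stress majorization.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sinc2(double x) {
  return (std::fabs(x) < 1e-8) ? 1.0 - x * x / 6.0 : std::sin(x) / x;
}

// Scale-optimized chi-square of every frame against one experimental curve
// (q-independent form factors, pair-distance histogram of width bin_width).
// [[Rcpp::export]]
NumericVector cpp_chi2_frames(List frames, NumericVector f0, NumericVector q,
                              NumericVector Iexp, NumericVector sigma,
                              double bin_width) {
  int nf = frames.size(), nq = q.size();
  NumericVector out(nf);
  std::vector<double> w(nq), It(nq);
  for (int k = 0; k < nq; ++k) w[k] = 1.0 / (sigma[k] * sigma[k]);
  for (int m = 0; m < nf; ++m) {
    NumericMatrix xyz = frames[m];
    int n = xyz.nrow();
    double dmax2 = 0, self = 0;
    for (int i = 0; i < n; ++i) self += f0[i] * f0[i];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
               dz = xyz(i, 2) - xyz(j, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > dmax2) dmax2 = r2;
      }
    int n_bins = (int)(std::sqrt(dmax2) / bin_width) + 2;
    std::vector<double> h(n_bins, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
               dz = xyz(i, 2) - xyz(j, 2);
        h[(int)(std::sqrt(dx * dx + dy * dy + dz * dz) / bin_width)] +=
            2.0 * f0[i] * f0[j];
      }
    double swt = 0, swe = 0;
    for (int k = 0; k < nq; ++k) {
      double s = self;
      for (int b = 0; b < n_bins; ++b)
        if (h[b] != 0) s += h[b] * sinc2(q[k] * (b + 0.5) * bin_width);
      It[k] = s;
      swt += w[k] * s * s;
      swe += w[k] * Iexp[k] * s;
    }
    double c = swe / swt, s2 = 0;
    for (int k = 0; k < nq; ++k) {
      double r = Iexp[k] - c * It[k];
      s2 += w[k] * r * r;
    }
    out[m] = s2 / nq;
  }
  return out;
}

// One SMACOF run with uniform weights: X <- B(X) X / n, stress recorded per
// iteration (normalized: sqrt(sum (d-delta)^2 / sum delta^2)).
// [[Rcpp::export]]
List cpp_smacof(NumericMatrix Delta, NumericMatrix X0, int max_iter,
                double tol) {
  int n = X0.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = X0(i, 0); y[i] = X0(i, 1); }
  double denom = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) denom += Delta(i, j) * Delta(i, j);
  std::vector<double> trace;
  auto stress = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double d = std::sqrt(dx * dx + dy * dy) - Delta(i, j);
        s += d * d;
      }
    return std::sqrt(s / denom);
  };
  double s_old = stress();
  trace.push_back(s_old);
  bool converged = false;
  std::vector<double> bx(n), by(n), brow(n);
  for (int it = 0; it < max_iter; ++it) {
    std::fill(bx.begin(), bx.end(), 0.0);
    std::fill(by.begin(), by.end(), 0.0);
    std::fill(brow.begin(), brow.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double d = std::sqrt(dx * dx + dy * dy);
        double r = d > 1e-12 ? Delta(i, j) / d : 0.0;
        // off-diagonal B_ij = -r; contributes r * (x_j) to (B X)_i minus ...
        bx[i] += -r * x[j]; by[i] += -r * y[j];
        bx[j] += -r * x[i]; by[j] += -r * y[i];
        brow[i] += r; brow[j] += r;  // diagonal accumulates +r
      }
    // (B X)_i = diag_i x_i + sum_{j != i} B_ij x_j = brow[i] x_i + bx[i]
    for (int i = 0; i < n; ++i) {
      double nx = brow[i] * x[i] + bx[i];
      double ny = brow[i] * y[i] + by[i];
      bx[i] = nx / n; by[i] = ny / n;
    }
    for (int i = 0; i < n; ++i) { x[i] = bx[i]; y[i] = by[i]; }
    double s_new = stress();
    trace.push_back(s_new);
    if (std::fabs(s_old - s_new) <= tol * std::max(s_old, 1e-300) ||
        s_new < 1e-12) {
      converged = true;
      s_old = s_new;
      break;
    }
    s_old = s_new;
  }
  NumericMatrix X(n, 2);
  for (int i = 0; i < n; ++i) { X(i, 0) = x[i]; X(i, 1) = y[i]; }
  return List::create(_["X"] = X, _["stress"] = s_old,
                      _["trace"] = wrap(trace),
                      _["converged"] = converged);
}
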