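// Orientationally averaged scattering intensity by the Debye double sum:
//   I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij)
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  return (std::fabs(x) < 1e-8) ? 1.0 - x * x / 6.0 : std::sin(x) / x;
}

// f: N x nq matrix of form factors evaluated on the q grid.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix xyz, NumericMatrix f, NumericVector q) {
  int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {  // self terms
    double s = 0;
    for (int i = 0; i < n; ++i) s += f(i, k) * f(i, k);
    I[k] = s;
  }
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k)
        I[k] += 2.0 * f(i, k) * f(j, k) * sinc(q[k] * r);
    }
  }
  return I;
}

// Debye sum accelerated by a pair-distance histogram (q-independent form
// factors): I(q) = sum_i f_i^2 + sum_bins h_b sinc(q r_b), with h_b the
// f-weighted pair counts at the bin centres. Error O((q dr)^2) relative.
// [[Rcpp::export]]
NumericVector cpp_debye_hist(NumericMatrix xyz, NumericVector f0,
                             NumericVector q, double bin_width) {
  int n = xyz.nrow(), nq = q.size();
  double dmax = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > dmax) dmax = r2;
    }
  int n_bins = (int)(std::sqrt(dmax) / bin_width) + 2;
  std::vector<double> h(n_bins, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      h[(int)(r / bin_width)] += 2.0 * f0[i] * f0[j];
    }
  double self = 0;
  for (int i = 0; i < n; ++i) self += f0[i] * f0[i];
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = self;
    for (int b = 0; b < n_bins; ++b) {
      if (h[b] == 0) continue;
      s += h[b] * sinc(q[k] * (b + 0.5) * bin_width);
    }
    I[k] = s;
  }
  return I;
}

// Pairwise-distance histogram weighted by f_i(0) f_j(0) products (i < j).
// [[Rcpp::export]]
NumericVector cpp_pair_histogram(NumericMatrix xyz, NumericVector f0,
                                 double bin_width, int n_bins) {
  int n = xyz.nrow();
  NumericVector h(n_bins);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(r / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      h[b] += 2.0 * f0[i] * f0[j];
    }
  return h;
}
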