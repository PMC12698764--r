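#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-match counts for sample entropy at m = 2 and m = 3 for every
// window (column). Row order: B2, A2, B3, A3. Both counts of a level use
// the same N - m template set; distances are Chebyshev; pairs i < j only.
// [[Rcpp::export(name = ".sampen_counts_mat")]]
NumericMatrix sampen_counts_mat(NumericMatrix seg, NumericVector r) {
  const int n = seg.nrow(), nw = seg.ncol();
  NumericMatrix out(4, nw);
  for (int w = 0; w < nw; ++w) {
    const double rw = r[w];
    double B2 = 0, A2 = 0, B3 = 0, A3 = 0;
    if (rw > 0 && n >= 5) {
      const double* x = &seg(0, w);
      for (int i = 0; i < n - 2; ++i) {
        for (int j = i + 1; j < n - 2; ++j) {
          double d0 = std::fabs(x[i] - x[j]);
          if (d0 >= rw) continue;
          double d1 = std::fabs(x[i + 1] - x[j + 1]);
          double m2 = d0 > d1 ? d0 : d1;
          if (m2 >= rw) continue;
          B2 += 1.0;
          double d2 = std::fabs(x[i + 2] - x[j + 2]);
          double m3 = m2 > d2 ? m2 : d2;
          if (m3 < rw) {
            A2 += 1.0;
            if (j < n - 3) {
              B3 += 1.0;
              double d3 = std::fabs(x[i + 3] - x[j + 3]);
              if ((m3 > d3 ? m3 : d3) < rw) A3 += 1.0;
            }
          }
        }
      }
    }
    out(0, w) = B2; out(1, w) = A2; out(2, w) = B3; out(3, w) = A3;
  }
  return out;
}

// Normalized permutation entropy per window: Shannon entropy of Lehmer-
// coded ordinal patterns over log(order!).
// [[Rcpp::export(name = ".permen_mat")]]
NumericVector permen_mat(NumericMatrix seg, int order, int delay) {
  const int n = seg.nrow(), nw = seg.ncol();
  int nfact = 1;
  for (int k = 2; k <= order; ++k) nfact *= k;
  std::vector<int> w(order, 1); // Lehmer weights (order-1-i)!
  for (int i = order - 2; i >= 0; --i) {
    w[i] = w[i + 1] * (order - 1 - i);
  }
  const int npat = n - (order - 1) * delay;
  if (npat < 1) stop("segment too short for the requested order/delay");
  NumericVector out(nw);
  std::vector<double> counts(nfact);
  std::vector<double> win(order);
  for (int c = 0; c < nw; ++c) {
    std::fill(counts.begin(), counts.end(), 0.0);
    const double* x = &seg(0, c);
    for (int t = 0; t < npat; ++t) {
      int code = 0;
      for (int i = 0; i < order - 1; ++i) {
        int ci = 0;
        double xi = x[t + i * delay];
        for (int j = i + 1; j < order; ++j) {
          if (x[t + j * delay] < xi) ++ci;
        }
        code += ci * w[i + 1 - 1]; // weight (order-1-i)! is w[i]
      }
      counts[code] += 1.0;
    }
    double h = 0.0;
    for (int k = 0; k < nfact; ++k) {
      if (counts[k] > 0) {
        double p = counts[k] / npat;
        h -= p * std::log(p);
      }
    }
    out[c] = h / std::log((double)nfact);
  }
  return out;
}
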