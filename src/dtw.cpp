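#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Banded (Sakoe-Chiba) dynamic time warping of two sequences of similar
// length. Returns, for every index i of `a`, the mean of the `b` samples
// matched to i by the optimal path, which yields one aligned sample per
// reference time point. Cost is squared difference; the band half-width
// is in samples.
// [[Rcpp::export(name = ".dtw_align_band")]]
NumericVector dtw_align_band(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band < 1) band = 1;
  const int width = 2 * band + 1;
  const double INF = std::numeric_limits<double>::infinity();

  // cost[i*width + (j - center(i) + band)] with center(i) = i*(m-1)/(n-1)
  std::vector<double> cost((size_t)n * width, INF);
  std::vector<signed char> step((size_t)n * width, -1); // 0=diag,1=up(i-1),2=left(j-1)

  auto center = [&](int i) -> int {
    return (n == 1) ? 0 : (int)std::llround((double)i * (m - 1) / (n - 1));
  };
  auto jlo = [&](int i) { int c = center(i) - band; return c < 0 ? 0 : c; };
  auto jhi = [&](int i) { int c = center(i) + band; return c > m - 1 ? m - 1 : c; };
  auto idx = [&](int i, int j) -> size_t {
    return (size_t)i * width + (j - center(i) + band);
  };
  auto get = [&](int i, int j) -> double {
    if (j < jlo(i) || j > jhi(i)) return INF;
    return cost[idx(i, j)];
  };

  for (int j = jlo(0); j <= jhi(0); ++j) {
    double d = a[0] - b[j];
    cost[idx(0, j)] = d * d + (j > jlo(0) ? cost[idx(0, j - 1)] : 0.0);
    step[idx(0, j)] = (j > jlo(0)) ? 2 : -1;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = jlo(i); j <= jhi(i); ++j) {
      double diag = (j > 0) ? get(i - 1, j - 1) : INF;
      double up = get(i - 1, j);
      double left = (j > jlo(i)) ? cost[idx(i, j - 1)] : INF;
      double best = diag; signed char s = 0;
      if (up < best) { best = up; s = 1; }
      if (left < best) { best = left; s = 2; }
      if (i == 1 && j == 0 && !std::isfinite(best)) { best = get(0, 0); s = 1; }
      double d = a[i] - b[j];
      cost[idx(i, j)] = d * d + best;
      step[idx(i, j)] = s;
    }
  }

  NumericVector sum(n, 0.0);
  IntegerVector cnt(n, 0);
  int i = n - 1, j = m - 1;
  if (j > jhi(i)) j = jhi(i);
  while (true) {
    sum[i] += b[j];
    cnt[i] += 1;
    signed char s = step[idx(i, j)];
    if (i == 0 && (s < 0 || j == jlo(0))) break;
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else if (s == 2) { --j; }
    else break;
  }
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = cnt[k] ? sum[k] / cnt[k] : NA_REAL;
  // fill any unvisited reference indices (possible only off-path corners)
  for (int k = 1; k < n; ++k) if (NumericVector::is_na(out[k])) out[k] = out[k - 1];
  for (int k = n - 2; k >= 0; --k) if (NumericVector::is_na(out[k])) out[k] = out[k + 1];
  return out;
}
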