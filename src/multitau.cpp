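// Multi-tau correlation estimator on a quasi-logarithmic lag grid.
//
// Estimator definition (symmetric normalisation): for traces a, b of common
// bin width, at integer lag k over the overlap of length M = n - k,
//   G(k) = [ (1/M) sum_i a_i b_{i+k} ] / [ mean(a_1..M) * mean(b_{k+1}..n) ] - 1.
// The first octave evaluates lags 1..m on the raw traces; every further
// octave halves the resolution by pairwise rebinning and evaluates lags
// m/2+1 .. m in rebinned units.  Lag zero is excluded (shot noise).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double corr_at(const std::vector<double> &a,
                             const std::vector<double> &b, long k) {
  long n = static_cast<long>(a.size());
  long M = n - k;
  if (M < 2) return NA_REAL;
  double sab = 0.0, sa = 0.0, sb = 0.0;
  const double *pa = a.data(), *pb = b.data() + k;
  for (long i = 0; i < M; ++i) {
    sab += pa[i] * pb[i];
    sa += pa[i];
    sb += pb[i];
  }
  if (sa <= 0.0 || sb <= 0.0) return NA_REAL;
  return (sab * M) / (sa * sb) - 1.0;
}

// [[Rcpp::export(name = ".multitau_cpp")]]
List multitau_cpp(NumericVector trace_a, NumericVector trace_b, int m,
                  double max_lag_bins) {
  if (m < 4 || m % 2 != 0) stop("points per octave must be an even number >= 4");
  std::vector<double> a(trace_a.begin(), trace_a.end());
  std::vector<double> b(trace_b.begin(), trace_b.end());

  std::vector<double> lag_out, g_out;
  long scale = 1;  // current bin size in base bins
  int level = 0;

  while (true) {
    long lo = (level == 0) ? 1 : m / 2 + 1;
    long n = static_cast<long>(a.size());
    bool done = false;
    for (long k = lo; k <= m; ++k) {
      double lag = static_cast<double>(k) * scale;
      if (lag > max_lag_bins || k >= n - 1) {
        done = true;
        break;
      }
      double g = corr_at(a, b, k);
      if (ISNAN(g)) {
        done = true;
        break;
      }
      lag_out.push_back(lag);
      g_out.push_back(g);
    }
    if (done || n / 2 <= m + 2) break;
    // pairwise rebin (mean, preserving intensity scale)
    long nh = n / 2;
    for (long i = 0; i < nh; ++i) {
      a[i] = 0.5 * (a[2 * i] + a[2 * i + 1]);
      b[i] = 0.5 * (b[2 * i] + b[2 * i + 1]);
    }
    a.resize(nh);
    b.resize(nh);
    scale *= 2;
    ++level;
  }
  return List::create(_["lag_bins"] = wrap(lag_out), _["G"] = wrap(g_out));
}

// Direct event-mode correlator: pair counting between two sorted photon
// arrival time lists over a grid of lag windows [edges[i], edges[i+1]).
// G for a window is the pair density normalised by the uncorrelated
// expectation N_a * N_b * width / T, minus 1.
// [[Rcpp::export(name = ".photon_corr_cpp")]]
List photon_corr_cpp(NumericVector ta, NumericVector tb, NumericVector edges,
                     double T) {
  int ne = edges.size() - 1;
  std::vector<double> counts(ne, 0.0);
  long na = ta.size(), nb = tb.size();
  double lag_min = edges[0], lag_max = edges[ne];

  long j_lo = 0;
  for (long i = 0; i < na; ++i) {
    double t = ta[i];
    while (j_lo < nb && tb[j_lo] < t + lag_min) ++j_lo;
    for (long j = j_lo; j < nb; ++j) {
      double d = tb[j] - t;
      if (d >= lag_max) break;
      int bin = static_cast<int>(std::upper_bound(edges.begin(), edges.end(), d)
                                 - edges.begin()) - 1;
      if (bin >= 0 && bin < ne) counts[bin] += 1.0;
    }
  }
  NumericVector G(ne), lag(ne);
  for (int k = 0; k < ne; ++k) {
    double width = edges[k + 1] - edges[k];
    double mid = 0.5 * (edges[k] + edges[k + 1]);
    double overlap = T - mid;
    double expected = static_cast<double>(na) * nb * width * overlap / (T * T);
    lag[k] = mid;
    G[k] = (expected > 0.0) ? counts[k] / expected - 1.0 : NA_REAL;
  }
  return List::create(_["lag"] = lag, _["G"] = G);
}
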