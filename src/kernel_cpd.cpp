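#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Penalized change-point detection with a Gaussian (RBF) kernel cost,
// solved exactly by PELT-style pruned dynamic programming.
//
// Cost of a half-open segment [s, t) of the series x (rows = samples):
//   c(s, t) = l - S(s, t) / l,   l = t - s,
//   S(s, t) = sum_{i,j in [s,t)} exp(-gamma * ||x_i - x_j||^2).
// The recursion F(t) = min_s F(s) + c(s, t) + lambda with F(0) = -lambda
// yields the global minimizer of total cost + lambda * (#changepoints).
//
// Kernel sums are maintained incrementally: extending every candidate
// segment by the sample t-1 costs one pass of kernel evaluations from the
// oldest unpruned candidate, which keeps the run linear in practice.

static inline double rbf(const double *a, const double *b, int d, double gamma) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = a[k] - b[k];
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".kernel_pelt_cpp")]]
List kernel_pelt_cpp(NumericMatrix series, double gamma, double penalty,
                     int min_size) {
  const int n = series.nrow();
  const int d = series.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // row-major copy for cache locality
  std::vector<double> x((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) x[(size_t)i * d + k] = series(i, k);

  if (n < 2 * min_size) {
    // no admissible split: single segment, cost computed directly
    double S = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        S += rbf(&x[(size_t)i * d], &x[(size_t)j * d], d, gamma);
    double cost = n > 0 ? (double)n - S / (double)n : 0.0;
    return List::create(_["boundaries"] = IntegerVector::create(0, n),
                        _["objective"] = cost);
  }

  std::vector<double> F(n + 1, INF);
  std::vector<int> prev(n + 1, -1);
  F[0] = -penalty;

  // active candidates (ascending start indices) and their running kernel
  // sums S(s, t) over the current right end t
  std::vector<int> cand;
  std::vector<double> csum;
  cand.reserve(256);
  csum.reserve(256);
  std::vector<double> kv(n);  // kernel evals vs the newly absorbed sample

  for (int t = 1; t <= n; ++t) {
    // absorb sample t-1 into all candidate segment sums
    const double *xt = &x[(size_t)(t - 1) * d];
    if (!cand.empty()) {
      int smin = cand.front();
      // suffix sums of k(x_i, x_{t-1}) for i in [smin, t-1)
      double acc = 0.0;
      for (int i = t - 2; i >= smin; --i) {
        acc += rbf(&x[(size_t)i * d], xt, d, gamma);
        kv[i] = acc;  // kv[i] = sum_{j=i}^{t-2} k(x_j, x_{t-1})
      }
      for (size_t c = 0; c < cand.size(); ++c) {
        int s = cand[c];
        double v = (s <= t - 2) ? kv[s] : 0.0;
        csum[c] += 2.0 * v + 1.0;  // k(x,x) = 1 for RBF
      }
    }
    // admit s = t-1 as a candidate if a previous segment can end there
    if (R_finite(F[t - 1]) || t - 1 == 0) {
      cand.push_back(t - 1);
      csum.push_back(1.0);  // S over the single sample t-1
    }

    // minimize over candidates with segment length >= min_size
    double best = INF;
    int argbest = -1;
    for (size_t c = 0; c < cand.size(); ++c) {
      int s = cand[c];
      int len = t - s;
      if (len < min_size) continue;
      double cost = (double)len - csum[c] / (double)len;
      double val = F[s] + cost + penalty;
      if (val < best) {  // strict: earliest boundary wins on ties
        best = val;
        argbest = s;
      }
    }
    F[t] = best;
    prev[t] = argbest;

    // PELT pruning (kernel cost is superadditive under concatenation)
    if (R_finite(best)) {
      size_t w = 0;
      for (size_t c = 0; c < cand.size(); ++c) {
        int s = cand[c];
        int len = t - s;
        if (len >= min_size) {
          double cost = (double)len - csum[c] / (double)len;
          if (F[s] + cost > best) continue;  // prune
        }
        cand[w] = cand[c];
        csum[w] = csum[c];
        ++w;
      }
      cand.resize(w);
      csum.resize(w);
    }
  }

  // backtrack
  std::vector<int> bnd;
  int t = n;
  while (t > 0) {
    bnd.push_back(t);
    t = prev[t];
    if (t < 0) stop("internal error: broken backtracking chain");
  }
  bnd.push_back(0);
  IntegerVector boundaries(bnd.rbegin(), bnd.rend());

  return List::create(_["boundaries"] = boundaries,
                      _["objective"] = F[n]);
}
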