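#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernel: maximal arc t-statistic scan and its
// permutation reference distribution. For a segment of length m the arc
// (i, j] (0-based boundaries, arc = elements i..j-1, k = j - i) has
//   T(i,j) = |mean_in - mean_out| / sqrt(1/k + 1/(m-k))
//          = |S[j] - S[i] - k * mean_all| * sqrt(m / (k (m-k))),
// the two-sample t numerator with the common-variance factor dropped (it is
// constant over (i,j) and cancels in the permutation comparison).
//
// Boundary constraints guarantee every resulting part has >= min_width
// elements: the arc itself, and any non-empty flank.

struct ArcScan {
  int m;
  std::vector<double> S; // prefix sums, length m+1
  std::vector<double> u; // u[k] = sqrt(m / (k (m-k))), length m
  explicit ArcScan(int m_) : m(m_), S(m_ + 1), u(m_) {
    for (int k = 1; k < m; ++k)
      u[k] = std::sqrt((double)m / ((double)k * (m - k)));
  }
  double scan(const double *x, int min_width, int *best_i, int *best_j) {
    S[0] = 0.0;
    for (int t = 0; t < m; ++t) S[t + 1] = S[t] + x[t];
    const double mu = S[m] / m;
    double best = -1.0;
    int bi = -1, bj = -1;
    const int jhi = m - min_width;
    for (int i = 0; i <= m - min_width; ++i) {
      if (i > 0 && i < min_width) continue; // left flank too small
      const double Si = S[i];
      for (int j = i + min_width; j <= jhi; ++j) {
        int k = j - i;
        double t = std::fabs(S[j] - Si - k * mu) * u[k];
        if (t > best) { best = t; bi = i; bj = j; }
      }
      if (i >= min_width) { // suffix arc (i, m]
        int k = m - i;
        if (k >= min_width && k < m) {
          double t = std::fabs(S[m] - Si - k * mu) * u[k];
          if (t > best) { best = t; bi = i; bj = m; }
        }
      }
    }
    *best_i = bi;
    *best_j = bj;
    return best;
  }
};

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc(NumericVector x, int min_width) {
  ArcScan sc(x.size());
  int i, j;
  double t = sc.scan(REAL(x), min_width, &i, &j);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Permutation p-value with early stopping: once the exceedance count can no
// longer come in under alpha * n_perm, stop and report the interim estimate
// (sufficient to declare non-significance). Uses R's RNG, so set.seed()
// upstream makes the segmentation deterministic.
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
List cbs_perm_pvalue(NumericVector x, int min_width, int n_perm,
                     double alpha) {
  int m = x.size();
  ArcScan sc(m);
  int oi, oj, pi, pj;
  double obs = sc.scan(REAL(x), min_width, &oi, &oj);
  std::vector<double> y(REAL(x), REAL(x) + m);
  int exceed = 0, done = 0;
  int stop_at = (int)std::floor(alpha * n_perm) + 1;
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates with R's uniform RNG
    for (int t = m - 1; t > 0; --t) {
      int s = (int)(unif_rand() * (t + 1));
      if (s > t) s = t;
      std::swap(y[t], y[s]);
    }
    double tp = sc.scan(y.data(), min_width, &pi, &pj);
    if (tp >= obs) ++exceed;
    ++done;
    if (exceed >= stop_at) break;
  }
  double pval = (double)(exceed + 1) / (double)(done + 1);
  return List::create(_["p"] = pval, _["i"] = oi, _["j"] = oj,
                      _["t"] = obs, _["n_perm_done"] = done);
}
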