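#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-group log-rank chi-square for patients already sorted by time
// (ascending). grp[i] = 1 for the "high" group. Returns the statistic;
// sets ok = false when the split is inadmissible (a group empty or no
// events). A split with zero variance but balanced observed/expected
// events scores 0.
static double logrank_sorted(const std::vector<double>& time,
                             const std::vector<int>& event,
                             const std::vector<int>& grp,
                             bool& ok) {
  const int n = (int)time.size();
  int n1_total = 0, ev_total = 0;
  for (int i = 0; i < n; ++i) {
    n1_total += grp[i];
    ev_total += event[i];
  }
  if (n1_total == 0 || n1_total == n || ev_total == 0) {
    ok = false;
    return NA_REAL;
  }
  ok = true;
  double sum_oe = 0.0, sum_v = 0.0;
  int at_risk = n, at_risk1 = n1_total;
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0, d1 = 0, block = 0, block1 = 0;
    // tie block: all patients with this time leave the risk set together
    while (j < n && time[j] == time[i]) {
      d += event[j];
      d1 += event[j] * grp[j];
      block += 1;
      block1 += grp[j];
      ++j;
    }
    if (d > 0) {
      double nn = (double)at_risk, nn1 = (double)at_risk1, dd = (double)d;
      sum_oe += (double)d1 - dd * nn1 / nn;
      if (at_risk > 1) {
        sum_v += dd * (nn1 / nn) * (1.0 - nn1 / nn) * (nn - dd) / (nn - 1.0);
      }
    }
    at_risk -= block;
    at_risk1 -= block1;
    i = j;
  }
  if (sum_v <= 0.0) return 0.0;
  return sum_oe * sum_oe / sum_v;
}

// Sort (time, event, expr) jointly by time ascending.
static void sort_by_time(std::vector<double>& time, std::vector<int>& event,
                         std::vector<double>& expr) {
  const int n = (int)time.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> t2(n), e2(n);
  std::vector<int> ev2(n);
  for (int i = 0; i < n; ++i) {
    t2[i] = time[idx[i]];
    ev2[i] = event[idx[i]];
    e2[i] = expr[idx[i]];
  }
  time.swap(t2);
  event.swap(ev2);
  expr.swap(e2);
}

// Log-rank statistic per threshold. High group: expr strictly greater
// than the threshold. A threshold is skipped (NA) when either group has
// fewer than min_group members or the split is otherwise inadmissible.
static void scan_thresholds(const std::vector<double>& time,
                            const std::vector<int>& event,
                            const std::vector<double>& expr,
                            const NumericVector& thresholds,
                            int min_group,
                            std::vector<double>& stats_out) {
  const int n = (int)time.size();
  const int K = thresholds.size();
  std::vector<int> grp(n);
  for (int k = 0; k < K; ++k) {
    const double thr = thresholds[k];
    int n_high = 0;
    for (int i = 0; i < n; ++i) {
      grp[i] = expr[i] > thr ? 1 : 0;
      n_high += grp[i];
    }
    if (n_high < min_group || n - n_high < min_group) {
      stats_out[k] = NA_REAL;
      continue;
    }
    bool ok = false;
    double s = logrank_sorted(time, event, grp, ok);
    stats_out[k] = ok ? s : NA_REAL;
  }
}

// [[Rcpp::export]]
double logrank_cpp(NumericVector time, IntegerVector event, IntegerVector group) {
  const int n = time.size();
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> ev(event.begin(), event.end());
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = (double)group[i];
  sort_by_time(t, ev, g);
  std::vector<int> grp(n);
  for (int i = 0; i < n; ++i) grp[i] = g[i] > 0.5 ? 1 : 0;
  bool ok = false;
  double s = logrank_sorted(t, ev, grp, ok);
  return ok ? s : NA_REAL;
}

// [[Rcpp::export]]
NumericVector logrank_scan_cpp(NumericVector time, IntegerVector event,
                               NumericVector expr, NumericVector thresholds,
                               int min_group) {
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> ev(event.begin(), event.end());
  std::vector<double> x(expr.begin(), expr.end());
  sort_by_time(t, ev, x);
  std::vector<double> out(thresholds.size());
  scan_thresholds(t, ev, x, thresholds, min_group, out);
  return NumericVector(out.begin(), out.end());
}

// Permutation null for the re-optimized cutpoint scan: (time, event)
// pairs are jointly shuffled against the fixed expression vector and the
// full threshold scan is repeated; the maximal statistic per permutation
// is returned (0 when no threshold is admissible). Uses R's RNG, so
// set.seed() upstream makes the draw reproducible.
// [[Rcpp::export]]
List perm_scan_cpp(NumericVector time, IntegerVector event, NumericVector expr,
                   NumericVector thresholds, int n_perm, int min_group) {
  const int n = time.size();
  const int K = thresholds.size();
  NumericVector max_stats(n_perm);
  int n_failed = 0;

  std::vector<double> t0(time.begin(), time.end());
  std::vector<int> ev0(event.begin(), event.end());
  std::vector<double> x0(expr.begin(), expr.end());

  std::vector<int> perm(n);
  std::vector<double> t(n), x(n);
  std::vector<int> ev(n);
  std::vector<double> stats(K);

  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of patient order, applied to (time, event)
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < n; ++i) {
      t[i] = t0[perm[i]];
      ev[i] = ev0[perm[i]];
      x[i] = x0[i];
    }
    sort_by_time(t, ev, x);
    scan_thresholds(t, ev, x, thresholds, min_group, stats);
    double best = R_NegInf;
    bool any_ok = false;
    for (int k = 0; k < K; ++k) {
      if (!ISNA(stats[k]) && stats[k] > best) {
        best = stats[k];
        any_ok = true;
      }
    }
    if (!any_ok) {
      max_stats[p] = 0.0;  // weakest possible evidence
      ++n_failed;
    } else {
      max_stats[p] = best;
    }
  }
  return List::create(Named("max_stats") = max_stats,
                      Named("n_failed") = n_failed);
}
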