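#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Objective pieces for the flip-move annealer.
// penalty = sum_s pen_coef[s] * shortfall_s, where
// shortfall_s = max(0, tnum[s] - held[s] * den) / den  (exact at boundary
// for integer counts because tnum and held*den are integers in doubles).
static double penalty_of(const NumericVector& held,
                         const NumericVector& tnum,
                         double den,
                         const NumericVector& pen_coef) {
  double pen = 0.0;
  const int S = held.size();
  for (int s = 0; s < S; ++s) {
    double gap = tnum[s] - held[s] * den;
    if (gap > 0) pen += pen_coef[s] * gap / den;
  }
  return pen;
}

// Change in penalty when PU i is flipped (sign = +1 add, -1 remove).
static double penalty_delta(const NumericMatrix& a, int i, int sign,
                            const NumericVector& held,
                            const NumericVector& tnum,
                            double den,
                            const NumericVector& pen_coef) {
  double d = 0.0;
  const int S = a.nrow();
  for (int s = 0; s < S; ++s) {
    double asi = a(s, i);
    if (asi == 0.0 || pen_coef[s] == 0.0) continue;
    double old_gap = tnum[s] - held[s] * den;
    double new_gap = tnum[s] - (held[s] + sign * asi) * den;
    double old_short = old_gap > 0 ? old_gap / den : 0.0;
    double new_short = new_gap > 0 ? new_gap / den : 0.0;
    d += pen_coef[s] * (new_short - old_short);
  }
  return d;
}

// [[Rcpp::export]]
LogicalVector anneal_core(NumericMatrix a, NumericVector cost,
                          NumericVector tnum, double den,
                          NumericVector pen_coef, int iterations,
                          double temp_floor_ratio) {
  const int S = a.nrow(), N = a.ncol();
  LogicalVector sel(N);
  NumericVector held(S);

  // random initial state: each PU in with probability 1/2
  for (int i = 0; i < N; ++i) {
    if (unif_rand() < 0.5) {
      sel[i] = true;
      for (int s = 0; s < S; ++s) held[s] += a(s, i);
    }
  }

  // adaptive initial temperature: median |delta| over 100 probe flips
  // accepted with probability ~0.8
  std::vector<double> probes;
  probes.reserve(100);
  for (int t = 0; t < 100; ++t) {
    int i = std::min(N - 1, (int)std::floor(unif_rand() * N));
    int sign = sel[i] ? -1 : 1;
    double d = sign * cost[i] +
      penalty_delta(a, i, sign, held, tnum, den, pen_coef);
    probes.push_back(std::fabs(d));
  }
  std::sort(probes.begin(), probes.end());
  double med = probes[probes.size() / 2];
  double temp = med > 0 ? -med / std::log(0.8) : 1.0;
  double cool = std::pow(temp_floor_ratio, 1.0 / std::max(1, iterations));

  // track the best state visited; the walk may wander uphill late in the
  // schedule and the caller wants the incumbent, not the endpoint
  double cur_cost = 0.0;
  for (int i = 0; i < N; ++i) if (sel[i]) cur_cost += cost[i];
  double cur_obj = cur_cost + penalty_of(held, tnum, den, pen_coef);
  LogicalVector best = clone(sel);
  double best_obj = cur_obj;

  for (int it = 0; it < iterations; ++it) {
    int i = std::min(N - 1, (int)std::floor(unif_rand() * N));
    int sign = sel[i] ? -1 : 1;
    double d = sign * cost[i] +
      penalty_delta(a, i, sign, held, tnum, den, pen_coef);
    if (d <= 0.0 || unif_rand() < std::exp(-d / temp)) {
      sel[i] = !sel[i];
      for (int s = 0; s < S; ++s) held[s] += sign * a(s, i);
      cur_obj += d;
      if (cur_obj < best_obj) {
        best_obj = cur_obj;
        best = clone(sel);
      }
    }
    temp *= cool;
  }
  return best;
}
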