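#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-method Gillespie simulation of the four-state promoter plus mRNA
// birth-death.  State labels: 1 = OFF1, 2 = OFF2, 3 = ON1, 4 = ON2; the
// promoter moves only along the square-cycle edges 1-2, 1-3, 2-4, 3-4.
// Uses R's RNG (two uniform draws per event) so trajectories are fully
// reproducible through set.seed().
//
// rates8 order: lam14, lam12, lam21, lam23, lam32, lam43, lam34, lam41.

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(NumericVector rates8, double mu1, double mu2, double delta,
                 double t_end, double burn_in, int state0, int m0,
                 bool record, NumericVector probe_times) {
  if (rates8.size() != 8) stop("rates8 must have length 8");
  const double l14 = rates8[0], l12 = rates8[1], l21 = rates8[2],
               l23 = rates8[3], l32 = rates8[4], l43 = rates8[5],
               l34 = rates8[6], l41 = rates8[7];
  if (t_end <= 0 || burn_in < 0 || burn_in >= t_end)
    stop("need 0 <= burn_in < t_end");

  int s = state0, m = m0;
  double t = 0.0;
  std::vector<double> hist;  // time-weighted occupancy of copy numbers
  hist.reserve(256);
  double state_time[4] = {0.0, 0.0, 0.0, 0.0};
  double sum_m = 0.0, sum_m2 = 0.0;

  std::vector<double> ev_t;
  std::vector<int> ev_s, ev_m;
  const std::size_t max_events = 2000000;
  if (record) { ev_t.reserve(1024); ev_s.reserve(1024); ev_m.reserve(1024); }

  int np = probe_times.size(), jp = 0;
  IntegerVector probe_m(np), probe_s(np);

  RNGScope scope;
  while (t < t_end) {
    // propensities in the current (state, count)
    double a_sw1 = 0, a_sw2 = 0;  // the two switching channels
    int to1 = 0, to2 = 0;
    switch (s) {
      case 1: a_sw1 = l14; to1 = 3; a_sw2 = l12; to2 = 2; break;
      case 2: a_sw1 = l21; to1 = 1; a_sw2 = l23; to2 = 4; break;
      case 3: a_sw1 = l41; to1 = 1; a_sw2 = l43; to2 = 4; break;
      case 4: a_sw1 = l32; to1 = 2; a_sw2 = l34; to2 = 3; break;
      default: stop("promoter state out of range");
    }
    double a_birth = (s == 3) ? mu1 : (s == 4) ? mu2 : 0.0;
    double a_death = delta * m;
    double a0 = a_sw1 + a_sw2 + a_birth + a_death;

    double t_next;
    if (a0 <= 0.0) {
      t_next = t_end;  // absorbing: sit still until the horizon
    } else {
      double u1 = unif_rand();
      t_next = t + (-std::log(u1) / a0);
    }
    double seg_hi = std::min(t_next, t_end);
    double w = std::min(seg_hi, t_end) - std::max(t, burn_in);
    if (w > 0.0) {
      if (static_cast<std::size_t>(m) >= hist.size()) hist.resize(m + 1, 0.0);
      hist[m] += w;
      state_time[s - 1] += w;
      sum_m += w * m;
      sum_m2 += w * static_cast<double>(m) * m;
    }
    while (jp < np && probe_times[jp] < seg_hi) {
      if (probe_times[jp] >= t) { probe_m[jp] = m; probe_s[jp] = s; ++jp; }
      else ++jp;  // probe before current time (should not happen for sorted grids)
    }
    if (a0 <= 0.0 || t_next >= t_end) break;
    t = t_next;

    double u2 = unif_rand() * a0;
    if (u2 < a_sw1) s = to1;
    else if (u2 < a_sw1 + a_sw2) s = to2;
    else if (u2 < a_sw1 + a_sw2 + a_birth) ++m;
    else --m;

    if (record) {
      if (ev_t.size() >= max_events)
        stop("trajectory exceeds %d events; rerun with record = FALSE",
             static_cast<int>(max_events));
      ev_t.push_back(t);
      ev_s.push_back(s);
      ev_m.push_back(m);
    }
  }
  // probes at/after the last event time up to t_end
  while (jp < np && probe_times[jp] <= t_end) { probe_m[jp] = m; probe_s[jp] = s; ++jp; }

  List out = List::create(
    _["hist"] = NumericVector(hist.begin(), hist.end()),
    _["state_time"] = NumericVector(state_time, state_time + 4),
    _["sum_m"] = sum_m,
    _["sum_m2"] = sum_m2,
    _["t_obs"] = t_end - burn_in,
    _["final_state"] = s,
    _["final_count"] = m);
  if (np > 0) { out["probe_counts"] = probe_m; out["probe_states"] = probe_s; }
  if (record) {
    out["times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["states"] = IntegerVector(ev_s.begin(), ev_s.end());
    out["counts"] = IntegerVector(ev_m.begin(), ev_m.end());
  }
  return out;
}
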