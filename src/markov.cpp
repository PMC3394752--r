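#include <Rcpp.h>
using namespace Rcpp;

// Per-epoch inhomogeneous Markov chain over vigilance states.
//
// trans: 3 x 3 x 2 array of transition probabilities (rows = from-state,
//        cols = to-state, slice 1 = light phase, slice 2 = dark phase).
// phase: integer vector, one entry per epoch, 1 = light, 2 = dark.
// forced: integer vector of the same length; 0 = free-running, otherwise the
//         1-based state index imposed on that epoch (forced-wake protocols).
// u:     uniform(0,1) draws, one per epoch, supplied by the caller so that
//        all randomness flows through R's RNG and honours set.seed().
//
// Epoch 0 takes `init`; each later epoch draws from the row of its
// predecessor's state under the phase in force at that epoch. A forced epoch
// overrides the draw but the chain continues from the forced state.
// [[Rcpp::export]]
IntegerVector markov_chain_sim(int n, NumericVector trans, IntegerVector phase,
                               IntegerVector forced, int init, NumericVector u) {
  if (n <= 0) stop("n must be positive");
  if (phase.size() != n || forced.size() != n || u.size() != n)
    stop("phase, forced and u must have length n");
  IntegerVector out(n);
  int cur = init - 1; // 0-based
  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      int ph = phase[t] - 1;
      double r = u[t];
      double acc = 0.0;
      int nxt = 2;
      for (int j = 0; j < 3; ++j) {
        acc += trans[cur + 3 * j + 9 * ph];
        if (r < acc) { nxt = j; break; }
      }
      cur = nxt;
    }
    if (forced[t] > 0) cur = forced[t] - 1;
    out[t] = cur + 1;
  }
  return out;
}

// Two-process-style homeostatic slow-wave process, one value per epoch.
// Saturating exponential rise toward `ceiling` during wake/REM (is_nrem = 0)
// with time constant tau_r, exponential decay toward `floor` during NREM
// (is_nrem = 1) with tau_d; both taus and dt in seconds. The value reported
// for epoch t is the level at the *start* of the epoch; the update for the
// epoch's own state is applied afterwards.
// [[Rcpp::export]]
NumericVector homeostat_process(IntegerVector is_nrem, double s0, double dt,
                                double tau_r, double tau_d,
                                double floor_, double ceiling_) {
  int n = is_nrem.size();
  if (tau_r <= 0 || tau_d <= 0) stop("time constants must be positive");
  if (ceiling_ <= floor_) stop("ceiling must exceed floor");
  NumericVector out(n);
  double s = s0;
  if (s < floor_) s = floor_;
  if (s > ceiling_) s = ceiling_;
  double kr = std::exp(-dt / tau_r), kd = std::exp(-dt / tau_d);
  for (int t = 0; t < n; ++t) {
    out[t] = s;
    if (is_nrem[t] == 1) s = floor_ + (s - floor_) * kd;
    else                 s = ceiling_ - (ceiling_ - s) * kr;
  }
  return out;
}
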