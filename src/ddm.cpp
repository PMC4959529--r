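#include <Rcpp.h>
using namespace Rcpp;

// Gaze-coupled diffusion: Euler steps on the top-minus-bottom evidence.
// While a payoff in one row is fixated, that row's payoff signal enters at
// full weight and the other row's at gaze_discount. Fixations follow a
// first-order Markov walk over the 8 AOIs with the supplied weight matrix.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List ddm_simulate_cpp(int n_trials, double s_top, double s_bot,
                      NumericMatrix gaze_w,
                      double drift_scale, double threshold, double noise_sd,
                      double gaze_discount, double dt_ms,
                      double dur_meanlog, double dur_sdlog,
                      double nondecision_ms, int max_steps) {
  IntegerVector choice(n_trials);
  NumericVector rt(n_trials);
  LogicalVector censored(n_trials);
  std::vector<int> fix_trial, fix_aoi;
  std::vector<double> fix_dur;
  fix_trial.reserve(n_trials * 20);
  fix_aoi.reserve(n_trials * 20);
  fix_dur.reserve(n_trials * 20);

  for (int t = 0; t < n_trials; ++t) {
    double E = 0.0;
    int steps = 0;
    bool done = false, cens = false;
    int ch = 0;
    int cur = (int)(unif_rand() * 8.0);
    if (cur > 7) cur = 7;
    while (!done) {
      double dur = R::rlnorm(dur_meanlog, dur_sdlog);
      int nst = (int)std::lround(dur / dt_ms);
      if (nst < 1) nst = 1;
      bool top_fix = cur < 4;
      double mu = drift_scale * ((top_fix ? 1.0 : gaze_discount) * s_top -
                                 (top_fix ? gaze_discount : 1.0) * s_bot);
      int used = 0;
      for (int s = 0; s < nst; ++s) {
        E += mu + noise_sd * norm_rand();
        ++steps; ++used;
        if (E >= threshold) { ch = 1; done = true; break; }
        if (E <= -threshold) { ch = 0; done = true; break; }
        if (steps >= max_steps) { cens = true; done = true; ch = (E >= 0) ? 1 : 0; break; }
      }
      fix_trial.push_back(t + 1);
      fix_aoi.push_back(cur + 1);
      fix_dur.push_back(used * dt_ms);
      if (!done) {
        double tot = 0.0;
        for (int j = 0; j < 8; ++j) tot += gaze_w(cur, j);
        double u = unif_rand() * tot, acc = 0.0;
        int nxt = 7;
        for (int j = 0; j < 8; ++j) {
          acc += gaze_w(cur, j);
          if (u <= acc) { nxt = j; break; }
        }
        cur = nxt;
      }
    }
    choice[t] = ch;
    rt[t] = steps * dt_ms + nondecision_ms;
    censored[t] = cens;
  }
  return List::create(_["choice"] = choice, _["rt_ms"] = rt,
                      _["censored"] = censored, _["fix_trial"] = wrap(fix_trial),
                      _["fix_aoi"] = wrap(fix_aoi), _["fix_dur"] = wrap(fix_dur));
}
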