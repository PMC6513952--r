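#include <Rcpp.h>
using namespace Rcpp;

// Event-based update loop. Each step draws four uniforms in fixed order
// (recruitment, beta, direct NURD, direct PR-DUB), converts them to
// exponential waiting times, executes the channel with the smallest
// increment, and advances the raw time counter by that minimum even when the
// attempted move fails. Plotted time = raw time / N. All randomness comes
// from R's RNG stream so that set.seed() fully determines a run; the draw
// order below is frozen (see the R-level reference stepper in the tests).

static inline int unif_index(int n) {
  // uniform integer in 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List run_engine_cpp(IntegerVector init,
                    double beta, double dn, double dp,
                    NumericVector mult,           // 7 enzyme multipliers
                    List recruiters,              // 12 integer vectors (1-based enzyme ids)
                    IntegerMatrix actions,        // 7 x 12, 0 = no-op
                    double generation_raw,        // raw time between replications, <= 0 -> off
                    double duration,              // plotted time units
                    double sample_interval) {
  const int N = init.size();
  std::vector<int> state(init.begin(), init.end());

  // recruiter table as flat arrays
  std::vector<std::vector<int>> rec(12);
  for (int s = 0; s < 12; ++s) {
    IntegerVector v = recruiters[s];
    rec[s] = std::vector<int>(v.begin(), v.end());
  }

  double max_mult = 1.0;
  for (int e = 0; e < 7; ++e) if (mult[e] > max_mult) max_mult = mult[e];
  const int n_samples = (int)std::floor(duration / sample_interval + 1e-9) + 1;
  IntegerMatrix samples(n_samples, N);
  NumericVector sample_times(n_samples);
  std::vector<double> repl_times;

  // event counters: per-channel executions + per-enzyme attempt/accept
  IntegerVector channel_events(4);
  IntegerVector enzyme_attempts(7), enzyme_accepts(7);
  int repl_count = 0;

  double t_raw = 0.0;           // raw time counter
  double last_rep = 0.0;
  int next_sample = 0;

  // record the t = 0 sample
  sample_times[next_sample] = 0.0;
  for (int i = 0; i < N; ++i) samples(next_sample, i) = state[i];
  ++next_sample;

  while (next_sample < n_samples) {
    // four waiting times, fixed draw order; a zero-rate channel still
    // consumes its uniform so the stream layout is parameter-independent
    double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand(), u4 = unif_rand();
    double t1 = -std::log(u1);
    double t2 = beta > 0 ? -std::log(u2) / beta : R_PosInf;
    double t3 = dn > 0 ? -std::log(u3) / dn : R_PosInf;
    double t4 = dp > 0 ? -std::log(u4) / dp : R_PosInf;

    int channel = 0;
    double dt = t1;
    if (t2 < dt) { dt = t2; channel = 1; }
    if (t3 < dt) { dt = t3; channel = 2; }
    if (t4 < dt) { dt = t4; channel = 3; }

    double t_new = t_raw + dt;
    double plot_new = t_new / N;

    // samples cover the state that held during (t_raw, t_new]
    while (next_sample < n_samples &&
           next_sample * sample_interval <= plot_new) {
      sample_times[next_sample] = next_sample * sample_interval;
      for (int i = 0; i < N; ++i) samples(next_sample, i) = state[i];
      ++next_sample;
    }

    // execute the chosen move
    if (channel == 0) {
      int recruiter = unif_index(N);
      const std::vector<int> &enz = rec[state[recruiter] - 1];
      if (!enz.empty()) {
        int e = enz[unif_index((int)enz.size())] - 1;   // 0-based enzyme
        int target = unif_index(N - 1);
        if (target >= recruiter) ++target;              // exclude self
        int to = actions(e, state[target] - 1);
        if (to > 0) {
          ++enzyme_attempts[e];
          double u = unif_rand();
          if (u < mult[e] / max_mult) {
            state[target] = to;
            ++enzyme_accepts[e];
            ++channel_events[0];
          }
        }
      }
    } else if (channel == 1) {
      int h = unif_index(N);
      int site = unif_index(3);                         // 0 K27, 1 K436, 2 H2A
      int s = state[h] - 1;                             // 0-based state
      int k27 = s / 4;                                  // 0 ac, 1 none, 2 me3
      int within = s % 4;                               // layer position
      int k436 = (within < 2) ? 1 : 0;                  // 1 = me
      int ub = (within == 1 || within == 2) ? 1 : 0;
      if (site == 0) {
        if (k27 == 1) k27 = (unif_rand() < 0.5) ? 0 : 2;
        else k27 = 1;
      } else if (site == 1) {
        k436 = 1 - k436;
      } else {
        ub = 1 - ub;
      }
      int w = k436 ? (ub ? 1 : 0) : (ub ? 2 : 3);
      state[h] = 4 * k27 + w + 1;
      ++channel_events[1];
    } else if (channel == 2) {
      int h = unif_index(N);
      if (state[h] >= 1 && state[h] <= 4) {             // carries H3K27ac
        state[h] += 4;
        ++channel_events[2];
      }
    } else {
      int h = unif_index(N);
      int s = state[h];
      if (s == 2 || s == 3 || s == 6 || s == 7 || s == 10 || s == 11) {
        // remove ubiquitin: layout within each K27 layer is me/no-ub,
        // me/ub, no-me/ub, no-me/no-ub
        state[h] += (s % 4 == 2) ? -1 : 1;
        ++channel_events[3];
      }
    }

    t_raw = t_new;

    if (generation_raw > 0 && t_raw - last_rep >= generation_raw) {
      for (int i = 0; i < N; ++i)
        if (unif_rand() < 0.5) state[i] = 8;
      last_rep = t_raw;
      repl_times.push_back(t_raw / N);
      ++repl_count;
    }
  }

  return List::create(
    _["time"] = sample_times,
    _["states"] = samples,
    _["repl_times"] = NumericVector(repl_times.begin(), repl_times.end()),
    _["channel_events"] = channel_events,
    _["enzyme_attempts"] = enzyme_attempts,
    _["enzyme_accepts"] = enzyme_accepts,
    _["repl_count"] = repl_count,
    _["end_time"] = t_raw / N
  );
}
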