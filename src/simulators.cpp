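#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli-thinned inhomogeneous point-process network.
//
// rate0  : Q x K matrix, exogenous rate (spikes/s) per neuron and bin
//          (baseline + Gaussian bump, before trial gain and interactions).
// gains  : Q x P matrix of per-(neuron, trial) multiplicative gains.
// delta  : Q x Q x L array (target, source, lag) of interaction weights on
//          the log rate; lag windows have width w_bins bins.
// Returns an integer array (P x Q x K) of 0/1 occupancies. Errors when
// lambda * dt exceeds 1 at any bin (the Bernoulli thinning model is invalid
// at that granularity).
// [[Rcpp::export]]
IntegerVector simulate_pp_cpp(NumericMatrix rate0, NumericMatrix gains,
                              NumericVector delta, int w_bins, int n_lags,
                              double dt) {
  const int Q = rate0.nrow(), K = rate0.ncol(), P = gains.ncol();
  const int L = n_lags;
  IntegerVector out(P * Q * K);
  out.attr("dim") = IntegerVector::create(P, Q, K);

  // nonzero interaction entries per target
  std::vector<std::vector<int>> src(Q), lag(Q);
  std::vector<std::vector<double>> wgt(Q);
  for (int i = 0; i < Q; ++i)
    for (int q = 0; q < Q; ++q)
      for (int m = 0; m < L; ++m) {
        double d = delta[i + Q * (q + Q * m)];
        if (d != 0.0) {
          src[i].push_back(q); lag[i].push_back(m); wgt[i].push_back(d);
        }
      }

  // cs[q][j] = number of spikes of neuron q in bins < j (prefix sums)
  std::vector<std::vector<int>> cs(Q, std::vector<int>(K + 1, 0));

  for (int p = 0; p < P; ++p) {
    for (int q = 0; q < Q; ++q) std::fill(cs[q].begin(), cs[q].end(), 0);
    for (int t = 0; t < K; ++t) {
      for (int i = 0; i < Q; ++i) {
        double s = 0.0;
        for (size_t e = 0; e < src[i].size(); ++e) {
          int q = src[i][e], m = lag[i][e];
          int hi = t - m * w_bins;            // bin after window end
          int lo = t - (m + 1) * w_bins;      // bin before window start
          if (hi < 0) hi = 0;
          if (lo < 0) lo = 0;
          s += wgt[i][e] * (cs[q][hi] - cs[q][lo]);
        }
        double lam = gains(i, p) * rate0(i, t) * std::exp(s);
        double pr = lam * dt;
        if (pr > 1.0)
          stop("rate * bin width = %.3f > 1 (rate %.1f spikes/s) for neuron "
               "%d, trial %d, bin %d: model invalid at this granularity",
               pr, lam, i + 1, p + 1, t + 1);
        if (unif_rand() < pr) out[p + P * (i + Q * t)] = 1;
      }
      for (int q = 0; q < Q; ++q)
        cs[q][t + 1] = cs[q][t] + out[p + P * (q + Q * t)];
    }
  }
  return out;
}

// Integrate-and-fire network (pure integrator, no leak).
//
// drive  : Q x K matrix, membrane increment per step for each unit and bin.
// syn    : Q x Q matrix; syn(i, j) is added to unit i's potential on the
//          step after unit j spikes.
// Threshold is redrawn from an exponential distribution with mean
// theta_mean after every spike when fixed_threshold is false; otherwise it
// stays at theta_fixed. Potentials reset to `reset` after a spike. Each
// synaptic increment is delivered after a delay drawn uniformly from
// 1..jitter_steps steps (jitter_steps = 1 gives exact one-step delays).
// Returns an integer 0/1 array (P x Q x K).
// [[Rcpp::export]]
IntegerVector simulate_if_cpp(NumericMatrix drive, NumericMatrix syn,
                              double theta_mean, bool fixed_threshold,
                              double theta_fixed, double reset, int n_trials,
                              int jitter_steps) {
  const int Q = drive.nrow(), K = drive.ncol(), P = n_trials;
  const int J = jitter_steps < 1 ? 1 : jitter_steps;
  IntegerVector out(P * Q * K);
  out.attr("dim") = IntegerVector::create(P, Q, K);

  std::vector<double> V(Q), theta(Q);
  std::vector<int> spiked(Q);
  // pending[i][(t + d) % (J + 1)] accumulates input due at step t + d
  std::vector<std::vector<double>> pending(Q, std::vector<double>(J + 1));

  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < Q; ++i) {
      V[i] = reset;
      theta[i] = fixed_threshold ? theta_fixed : exp_rand() * theta_mean;
      std::fill(pending[i].begin(), pending[i].end(), 0.0);
    }
    for (int t = 0; t < K; ++t) {
      const int slot = t % (J + 1);
      for (int i = 0; i < Q; ++i) {
        double v = V[i] + drive(i, t) + pending[i][slot];
        pending[i][slot] = 0.0;
        if (v >= theta[i]) {
          spiked[i] = 1;
          V[i] = reset;
          theta[i] = fixed_threshold ? theta_fixed : exp_rand() * theta_mean;
        } else {
          spiked[i] = 0;
          V[i] = v;
        }
      }
      for (int j = 0; j < Q; ++j) {
        out[p + P * (j + Q * t)] = spiked[j];
        if (spiked[j])
          for (int i = 0; i < Q; ++i)
            if (syn(i, j) != 0.0) {
              int d = J == 1 ? 1 : 1 + (int)(unif_rand() * J);
              if (d > J) d = J;
              pending[i][(t + d) % (J + 1)] += syn(i, j);
            }
      }
    }
  }
  return out;
}
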