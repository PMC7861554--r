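# Small generators used across tests (independent of the package simulators
# where they serve as oracles).

# Homogeneous Poisson spike times on (0, T] via cumulative exponential ISIs.
poisson_spikes <- function(rate, trial_duration) {
  u <- numeric(0)
  t <- stats::rexp(1, rate)
  while (t <= trial_duration) {
    u <- c(u, t)
    t <- t + stats::rexp(1, rate)
  }
  u
}

# A spike_train_set of independent homogeneous Poisson neurons.
poisson_set <- function(n_neurons, n_trials, rate, trial_duration = 3) {
  spike_train_set(
    lapply(seq_len(n_neurons), function(i)
      lapply(seq_len(n_trials), function(p)
        poisson_spikes(rate, trial_duration))),
    trial_duration)
}

# Binning with the occasional-collision warning silenced (collisions are
# expected at these rates and clamping is the documented behavior).
bin_quiet <- function(x, bin_width = 0.001)
  suppressWarnings(bin_spikes(x, bin_width))

# Brute-force history covariate oracle: re-counts occupied bins per lag
# interval for every bin, directly from spike times (same-bin collisions
# count once, matching the 0/1 occupancy the model sees).
brute_history <- function(spikes, target_trial, source, bin_width, W, M,
                          n_bins) {
  u <- spikes$spikes[[source]][[target_trial]]
  u <- (unique(ceiling(u / bin_width)) - 0.5) * bin_width  # occupied bins
  R <- matrix(0, n_bins, M)
  for (k in seq_len(n_bins)) {
    t_bin <- (k - 1) * bin_width   # bin start; spikes strictly before it
    for (m in seq_len(M)) {
      lo <- t_bin - m * W
      hi <- t_bin - (m - 1) * W
      # spike at time u occupies bin ceiling(u / bin_width); it is "before"
      # bin k when its bin index < k, i.e. u <= (k-1)*bin_width
      R[k, m] <- sum(u > lo & u <= hi & u <= t_bin + 1e-12)
    }
  }
  R
}
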