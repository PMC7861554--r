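# Deterministic child seeds: scaled-down and full-scale experiments share a
# prefix of randomness derived from one master seed.
child_seed <- function(master, index) {
  s <- (as.double(master) * 48271 + as.double(index)) %% 2147483647
  as.integer(s) + 1L
}

#' Score an estimated connectivity pattern against ground truth
#'
#' Percent correct divides the number of significant true edges by the
#' number of true edges; percent false positive divides the number of
#' significant non-edges by the number of non-edges. The pair universe is
#' all Q^2 ordered pairs including the diagonal.
#'
#' @param result A [connectivity()] result.
#' @param truth A `network_spec`/`if_network_spec`, or a data frame with
#'   columns `source` and `target` listing the true directed edges.
#' @return A list with `percent_correct` (`NA` when the truth has no edges),
#'   `percent_false_positive`, and the raw counts.
#' @export
evaluate_connectivity <- function(result, truth) {
  stopifnot(inherits(result, "connectivity_result"))
  if (!is.data.frame(truth)) truth <- truth_edges(truth)
  Q <- result$n_neurons
  if (nrow(truth) &&
      (max(truth$source) > Q || max(truth$target) > Q))
    stop("truth edges reference neurons outside the result's pair universe")
  is_edge <- matrix(FALSE, Q, Q)
  if (nrow(truth)) is_edge[cbind(truth$source, truth$target)] <- TRUE
  sig <- result$significant
  sig[is.na(sig)] <- FALSE  # non-converged pair tests are never significant
  n_edges <- sum(is_edge)
  n_non <- Q * Q - n_edges
  hits <- sum(sig & is_edge)
  fps <- sum(sig & !is_edge)
  list(
    percent_correct = if (n_edges) 100 * hits / n_edges else NA_real_,
    percent_false_positive = if (n_non) 100 * fps / n_non else NA_real_,
    n_edges = n_edges, n_non_edges = n_non, n_hits = hits,
    n_false_positives = fps)
}

# Draw one experiment realization (network + spike trains). Networks whose
# conditional rate would exceed the Bernoulli bound are redrawn from the
# next child seed; the number of redraws is reported.
draw_experiment <- function(experiment, run_seed, n_trials, trial_duration,
                            max_attempts = 25) {
  for (attempt in seq_len(max_attempts)) {
    s <- child_seed(run_seed, attempt)
    out <- switch(
      experiment,
      fig4_pp = {
        net <- random_network(4, 6, seed = s)
        sp <- tryCatch(simulate_network(net, n_trials, trial_duration),
                       error = function(e) NULL)
        list(net = net, spikes = sp)
      },
      fig5_if = {
        net <- random_if_network(4, 6, seed = s)
        list(net = net,
             spikes = simulate_if_network(net, n_trials, trial_duration))
      },
      fig9_trialvar = {
        net <- random_network(4, 6, seed = s)
        g <- stats::runif(n_trials, 0.55, 2.05)
        net$trial_gains <- matrix(rep(g, each = net$n_neurons),
                                  net$n_neurons)
        sp <- tryCatch(simulate_network(net, n_trials, trial_duration),
                       error = function(e) NULL)
        list(net = net, spikes = sp)
      },
      stop("unknown experiment: ", experiment))
    if (!is.null(out$spikes)) {
      out$attempts <- attempt
      return(out)
    }
  }
  stop("could not draw a valid network in ", max_attempts, " attempts")
}

#' Monte-Carlo comparison of CIF models on random networks
#'
#' Repeats the random-network protocol: per run, draw a 4-neuron network
#' with 6 random directed connections (self-pairs allowed), simulate
#' `n_trials` trials, estimate connectivity with each method, and score
#' percent correct (denominator 6) and percent false positive (denominator
#' 10) against the ground truth. Experiments: `"fig4_pp"` (point-process
#' generator with Gaussian exogenous bumps), `"fig5_if"`
#' (integrate-and-fire generator, exponential thresholds),
#' `"fig9_trialvar"` (point-process generator plus one shared per-trial
#' gain uniform in [0.55, 2.05) multiplying all neurons' rates).
#'
#' @param experiment One of `"fig4_pp"`, `"fig5_if"`, `"fig9_trialvar"`.
#' @param methods Character vector of methods to compare; defaults to
#'   `c("kim", "getm")` (`c("getm", "getmv")` for `"fig9_trialvar"`).
#' @param n_runs Number of Monte-Carlo runs; default 25.
#' @param seed Master seed; per-run seeds derive deterministically from it.
#' @param n_trials Trials per run; default 40.
#' @param trial_duration Trial duration (s); default 3.
#' @param grid Hyperparameter grid; defaults to the compact experiment grid
#'   (W = 4 ms, M = 4, N in {12, 24}).
#' @param alpha Per-connection significance level; default 0.05.
#' @return An object of class `mc_summary`: per-method means and standard
#'   deviations of the two percentages, the per-run raw table, and the
#'   configuration snapshot.
#' @export
run_comparison <- function(experiment = c("fig4_pp", "fig5_if",
                                          "fig9_trialvar"),
                           methods = NULL, n_runs = 25, seed = 1,
                           n_trials = 40, trial_duration = 3,
                           grid = NULL, alpha = 0.05) {
  experiment <- match.arg(experiment)
  if (is.null(methods))
    methods <- if (experiment == "fig9_trialvar") c("getm", "getmv")
               else c("kim", "getm")
  if (is.null(grid)) grid <- mc_grid()
  stopifnot(n_runs >= 1)
  rows <- list()
  n_redraws <- 0L
  n_fit_failures <- 0L
  for (r in seq_len(n_runs)) {
    run_seed <- child_seed(seed, r)
    drawn <- draw_experiment(experiment, run_seed, n_trials, trial_duration)
    n_redraws <- n_redraws + drawn$attempts - 1L
    truth <- truth_edges(drawn$net)
    for (meth in methods) {
      res <- tryCatch(
        connectivity(drawn$spikes, meth, alpha = alpha, grid = grid),
        error = function(e) NULL)
      if (is.null(res)) {
        n_fit_failures <- n_fit_failures + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, method = meth, percent_correct = NA_real_,
          percent_false_positive = NA_real_, n_hits = NA_integer_,
          n_false_positives = NA_integer_)
        next
      }
      sc <- evaluate_connectivity(res, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, method = meth, percent_correct = sc$percent_correct,
        percent_false_positive = sc$percent_false_positive,
        n_hits = sc$n_hits, n_false_positives = sc$n_false_positives)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(methods, function(meth) {
    d <- runs[runs$method == meth & !is.na(runs$percent_false_positive), ]
    data.frame(
      method = meth, n_runs = nrow(d),
      percent_correct = mean(d$percent_correct),
      percent_correct_sd = stats::sd(d$percent_correct),
      percent_false_positive = mean(d$percent_false_positive),
      percent_false_positive_sd = stats::sd(d$percent_false_positive))
  }))
  structure(
    list(experiment = experiment, summary = agg, runs = runs,
         n_redraws = n_redraws, n_fit_failures = n_fit_failures,
         config = list(methods = methods, n_runs = n_runs, seed = seed,
                       n_trials = n_trials, trial_duration = trial_duration,
                       alpha = alpha, grid = grid)),
    class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("mc_summary [%s]: %d runs, seed %d\n", x$experiment,
              x$config$n_runs, x$config$seed))
  print(x$summary, row.names = FALSE, digits = 3)
  if (x$n_redraws) cat("  network redraws:", x$n_redraws, "\n")
  if (x$n_fit_failures) cat("  fit failures:", x$n_fit_failures, "\n")
  invisible(x)
}

#' Sensitivity of detection to connection strength and trial count
#'
#' Two-neuron, single-edge (1 -> 2) experiment: sweeps the edge strength and
#' the number of trials; per cell, runs `n_runs` seeded replicates, fits the
#' chosen model and records whether the true edge was detected, the
#' false-positive fraction over the other three ordered pairs, and
#' (optionally) whether the naive firing-rate benchmark ([rate_benchmark()])
#' detects the influence.
#'
#' @param strengths Numeric vector of edge strengths; default
#'   `c(0.5, 1, 1.5)`.
#' @param trial_counts Integer vector of trial counts; default
#'   `c(20, 40, 60)`.
#' @param n_runs Replicates per cell; default 10.
#' @param seed Master seed.
#' @param method CIF model; default `"getm"`.
#' @param grid Hyperparameter grid; defaults to the compact experiment grid.
#' @param alpha Significance level; default 0.05.
#' @param benchmark Also run the firing-rate benchmark per run; default TRUE.
#' @param benchmark_test `"t"` or `"wilcoxon"`.
#' @return An object of class `sensitivity_grid`: `detection`, `fp` and
#'   `benchmark` matrices (strength x trials), `grand_fp` (grand-average
#'   false-positive percentage), and the per-run table.
#' @export
sensitivity_grid <- function(strengths = c(0.5, 1, 1.5),
                             trial_counts = c(20, 40, 60), n_runs = 10,
                             seed = 1, method = "getm", grid = NULL,
                             alpha = 0.05, benchmark = TRUE,
                             benchmark_test = "t") {
  if (is.null(grid)) grid <- mc_grid()
  mk <- function() matrix(NA_real_, length(strengths), length(trial_counts),
                          dimnames = list(strength = strengths,
                                          trials = trial_counts))
  det <- mk(); fp <- mk(); bench <- mk()
  rows <- list()
  cell <- 0L
  for (si in seq_along(strengths)) for (ti in seq_along(trial_counts)) {
    cell <- cell + 1L
    d_runs <- f_runs <- b_runs <- numeric(0)
    for (r in seq_len(n_runs)) {
      s <- child_seed(seed, cell * 1000L + r)
      sc <- make_scenario("fig6", seed = s, n_trials = trial_counts[ti],
                          strength = strengths[si])
      res <- tryCatch(
        connectivity(sc$spikes, method, alpha = alpha, grid = grid),
        error = function(e) NULL)
      if (is.null(res)) next
      sig <- res$significant
      sig[is.na(sig)] <- FALSE
      d_runs <- c(d_runs, as.numeric(sig[1, 2]))
      f_runs <- c(f_runs, mean(sig[cbind(c(1, 2, 2), c(1, 1, 2))]))
      b <- if (benchmark)
        as.numeric(rate_benchmark(sc$spikes, test = benchmark_test) < alpha)
      else NA_real_
      b_runs <- c(b_runs, b)
      rows[[length(rows) + 1L]] <- data.frame(
        strength = strengths[si], n_trials = trial_counts[ti], run = r,
        detected = sig[1, 2], fp_fraction = mean(sig[cbind(c(1, 2, 2),
                                                           c(1, 1, 2))]),
        benchmark_detected = b)
    }
    det[si, ti] <- 100 * mean(d_runs)
    fp[si, ti] <- 100 * mean(f_runs)
    bench[si, ti] <- 100 * mean(b_runs)
  }
  structure(
    list(detection = det, fp = fp, benchmark = bench,
         grand_fp = mean(fp), runs = do.call(rbind, rows),
         config = list(strengths = strengths, trial_counts = trial_counts,
                       n_runs = n_runs, seed = seed, method = method,
                       alpha = alpha, grid = grid)),
    class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("sensitivity_grid: percent detected (strength x trials)\n")
  print(round(x$detection, 1))
  cat(sprintf("grand-average false positives: %.1f%%\n", x$grand_fp))
  invisible(x)
}

#' Naive firing-rate benchmark for a directed influence
#'
#' Tests, across trials, whether the target neuron's firing rate in the
#' active window is larger than in the baseline window (one-sided paired
#' test). This is the simple alternative to the model-based Granger test: it
#' requires knowing which neuron drives which, and only sees influences
#' strong enough to move the target's rate.
#'
#' @param spikes A [spike_train_set()].
#' @param active_window,baseline_window Half-open `[start, end)` windows in
#'   seconds; must not overlap.
#' @param target Target neuron; default 2.
#' @param test `"t"` (paired t-test) or `"wilcoxon"` (signed-rank).
#' @return The one-sided p-value.
#' @export
rate_benchmark <- function(spikes, active_window = c(0.8, 1.2),
                           baseline_window = c(1.8, 2.2), target = 2,
                           test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(spikes, "spike_train_set"),
            length(active_window) == 2, length(baseline_window) == 2,
            active_window[1] < active_window[2],
            baseline_window[1] < baseline_window[2])
  if (max(active_window[1], baseline_window[1]) <
      min(active_window[2], baseline_window[2]))
    stop("active and baseline windows must not overlap")
  if (any(c(active_window, baseline_window) < 0) ||
      any(c(active_window, baseline_window) > spikes$trial_duration))
    stop("windows must lie within the trial")
  if (spikes$n_trials < 2)
    stop("the rate benchmark needs at least 2 trials")
  count_in <- function(u, w) sum(u >= w[1] & u < w[2])
  act <- bas <- numeric(spikes$n_trials)
  for (p in seq_len(spikes$n_trials)) {
    u <- spikes$spikes[[target]][[p]]
    act[p] <- count_in(u, active_window) / diff(active_window)
    bas[p] <- count_in(u, baseline_window) / diff(baseline_window)
  }
  p <- tryCatch({
    if (test == "t")
      stats::t.test(act, bas, paired = TRUE,
                    alternative = "greater")$p.value
    else
      stats::wilcox.test(act, bas, paired = TRUE, alternative = "greater",
                         exact = FALSE)$p.value
  }, error = function(e) NA_real_)
  p
}
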