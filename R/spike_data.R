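#' Trial-structured spike train set
#'
#' The universal input container: spike times for `n_neurons` neurons recorded
#' over `n_trials` trials of common duration `trial_duration` (seconds).
#' Times are trial-relative, strictly greater than 0 and at most
#' `trial_duration`, and strictly increasing within each (neuron, trial).
#'
#' @param spikes A list of length `n_neurons`; element `i` is a list of length
#'   `n_trials` whose element `p` is a numeric vector of spike times (s) of
#'   neuron `i` in trial `p` (possibly empty).
#' @param trial_duration Trial duration T in seconds (> 0).
#' @param n_neurons,n_trials Optional; inferred from `spikes` when omitted.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, trial_duration,
                            n_neurons = length(spikes),
                            n_trials = length(spikes[[1]])) {
  stopifnot(is.list(spikes), is.numeric(trial_duration), trial_duration > 0,
            n_neurons >= 1L, n_trials >= 1L)
  if (length(spikes) != n_neurons)
    stop("`spikes` must have one element per neuron")
  for (i in seq_len(n_neurons)) {
    if (length(spikes[[i]]) != n_trials)
      stop(sprintf("neuron %d: expected %d trials, got %d",
                   i, n_trials, length(spikes[[i]])))
    for (p in seq_len(n_trials)) {
      u <- as.numeric(spikes[[i]][[p]])
      if (length(u)) {
        if (any(u <= 0) || any(u > trial_duration))
          stop(sprintf(
            "neuron %d, trial %d: spike times must lie in (0, %g]",
            i, p, trial_duration))
        if (is.unsorted(u, strictly = TRUE))
          stop(sprintf(
            "neuron %d, trial %d: spike times must be strictly increasing",
            i, p))
      }
      spikes[[i]][[p]] <- u
    }
  }
  structure(
    list(spikes = spikes, n_neurons = as.integer(n_neurons),
         n_trials = as.integer(n_trials),
         trial_duration = as.numeric(trial_duration)),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- sum(vapply(x$spikes, function(tr) sum(lengths(tr)), numeric(1)))
  cat(sprintf(
    "spike_train_set: %d neuron(s), %d trial(s) of %g s, %d spikes (%.2f Hz mean)\n",
    x$n_neurons, x$n_trials, x$trial_duration, n_sp,
    n_sp / (x$n_neurons * x$n_trials * x$trial_duration)))
  invisible(x)
}

#' Bin spike trains at the model's temporal granularity
#'
#' Discretizes each (neuron, trial) spike train into 0/1 occupancy over
#' half-open bins `[k*bin_width, (k+1)*bin_width)`, the Bernoulli response of
#' the binomial CIF models. Bins containing more than one spike are clamped to
#' 1 with a warning (the simulators never produce such collisions).
#'
#' @param x A [spike_train_set()].
#' @param bin_width Bin width in seconds; default 0.001 (1 ms). Must divide
#'   the trial duration to within floating tolerance.
#' @return An object of class `binned_spikes`: a list with `counts` (integer
#'   array `n_trials x n_neurons x n_bins`), `bin_width`, `n_bins`,
#'   `trial_duration`, `n_neurons`, `n_trials`.
#' @export
bin_spikes <- function(x, bin_width = 0.001) {
  stopifnot(inherits(x, "spike_train_set"), bin_width > 0)
  K <- x$trial_duration / bin_width
  if (abs(K - round(K)) > 1e-6)
    stop("`bin_width` must divide the trial duration")
  K <- as.integer(round(K))
  counts <- array(0L, dim = c(x$n_trials, x$n_neurons, K))
  collisions <- 0L
  for (i in seq_len(x$n_neurons)) {
    for (p in seq_len(x$n_trials)) {
      u <- x$spikes[[i]][[p]]
      if (!length(u)) next
      # (0, T] convention: a spike exactly on a bin edge belongs to the bin
      # it closes, so t = T lands in the last bin.
      b <- pmin(pmax(ceiling(u / bin_width), 1L), K)
      tb <- tabulate(b, nbins = K)
      collisions <- collisions + sum(tb > 1L)
      counts[p, i, ] <- as.integer(tb > 0L)
    }
  }
  if (collisions > 0L)
    warning(sprintf("%d bin(s) contained more than one spike; clamped to 1",
                    collisions))
  structure(
    list(counts = counts, bin_width = bin_width, n_bins = K,
         trial_duration = x$trial_duration, n_neurons = x$n_neurons,
         n_trials = x$n_trials),
    class = "binned_spikes")
}

#' Ensemble spiking-history covariates
#'
#' For every bin t of every trial, counts the spikes of each source neuron q
#' in each of `n_windows` non-overlapping rectangular lag windows of duration
#' `window_width` preceding t: window m covers `[t - m*W, t - (m-1)*W)`.
#' Counts use only spikes strictly before the bin (causality) and never cross
#' trial boundaries; windows extending before trial start are truncated.
#'
#' @param binned A [bin_spikes()] result.
#' @param window_width Lag window duration W in seconds (a multiple of the
#'   bin width).
#' @param n_windows Number of lag windows M (>= 1); `n_windows * window_width`
#'   must be smaller than the trial duration.
#' @return An object of class `history_covariates`: list with `R`, a numeric
#'   array `n_trials x n_bins x n_neurons x n_windows`, plus the
#'   configuration.
#' @export
history_covariates <- function(binned, window_width, n_windows) {
  stopifnot(inherits(binned, "binned_spikes"), window_width > 0, n_windows >= 1)
  w <- window_width / binned$bin_width
  if (abs(w - round(w)) > 1e-6)
    stop("`window_width` must be a multiple of the bin width")
  w <- as.integer(round(w))
  if (n_windows * window_width >= binned$trial_duration)
    stop("history span n_windows * window_width must be smaller than the trial duration")
  K <- binned$n_bins
  R <- array(0, dim = c(binned$n_trials, K, binned$n_neurons, n_windows))
  k <- seq_len(K)
  for (p in seq_len(binned$n_trials)) {
    for (q in seq_len(binned$n_neurons)) {
      cs <- c(0, cumsum(binned$counts[p, q, ]))  # cs[j+1] = spikes in bins 1..j
      for (m in seq_len(n_windows)) {
        hi <- pmax(k - 1L - (m - 1L) * w, 0L)    # last bin included, clamped
        lo <- pmax(k - 1L - m * w, 0L)           # bin before window start
        R[p, , q, m] <- cs[hi + 1L] - cs[lo + 1L]
      }
    }
  }
  structure(
    list(R = R, window_width = window_width, n_windows = as.integer(n_windows),
         bin_width = binned$bin_width, n_bins = K,
         n_neurons = binned$n_neurons, n_trials = binned$n_trials),
    class = "history_covariates")
}

#' Exogenous window index
#'
#' Maps a trial-relative time t in (0, T] to the index of the exogenous
#' window containing it when the trial is split into `n_windows` equal
#' non-overlapping windows: `ceiling(t * n_windows / T)`, in `1..n_windows`.
#'
#' @param t Time(s) in seconds, each in (0, T].
#' @param trial_duration Trial duration T (s).
#' @param n_windows Number of exogenous windows N (>= 1).
#' @return Integer vector of window indices.
#' @export
exo_window_index <- function(t, trial_duration, n_windows) {
  stopifnot(trial_duration > 0, n_windows >= 1)
  if (any(t <= 0 | t > trial_duration))
    stop("`t` must lie in (0, trial_duration]")
  pmin(as.integer(ceiling(t * n_windows / trial_duration)),
       as.integer(n_windows))
}

# Exogenous window index per bin (right bin edges lie in (0, T]).
bin_exo_index <- function(n_bins, bin_width, trial_duration, n_windows) {
  exo_window_index(seq_len(n_bins) * bin_width, trial_duration, n_windows)
}

# ---- interchange formats ----------------------------------------------------

#' Write / read spike trains in the CSV interchange format
#'
#' CSV with header `trial,neuron,spike_time_s` (1-based indices) plus a
#' companion JSON metadata file `{n_neurons, n_trials, trial_duration_s}`.
#' `write_spikes_json()` / `read_spikes_json()` provide a single-file JSON
#' variant embedding both.
#'
#' @param x A [spike_train_set()].
#' @param path Output CSV path.
#' @param meta_path Metadata JSON path; defaults to `path` with a `.json`
#'   extension appended.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [spike_train_set()].
#' @export
write_spikes_csv <- function(x, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(x, "spike_train_set"))
  rows <- list()
  for (i in seq_len(x$n_neurons))
    for (p in seq_len(x$n_trials)) {
      u <- x$spikes[[i]][[p]]
      if (length(u))
        rows[[length(rows) + 1L]] <-
          data.frame(trial = p, neuron = i, spike_time_s = u)
    }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), neuron = integer(), spike_time_s = numeric())
  df <- df[order(df$trial, df$neuron, df$spike_time_s), ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(n_neurons = x$n_neurons, n_trials = x$n_trials,
         trial_duration_s = x$trial_duration),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path, meta_path = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  stopifnot(all(c("trial", "neuron", "spike_time_s") %in% names(df)))
  meta <- jsonlite::read_json(meta_path)
  Q <- as.integer(meta$n_neurons); P <- as.integer(meta$n_trials)
  spikes <- lapply(seq_len(Q), function(i)
    lapply(seq_len(P), function(p)
      sort(df$spike_time_s[df$neuron == i & df$trial == p])))
  spike_train_set(spikes, as.numeric(meta$trial_duration_s), Q, P)
}

#' @rdname write_spikes_csv
#' @export
write_spikes_json <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  jsonlite::write_json(
    list(n_neurons = x$n_neurons, n_trials = x$n_trials,
         trial_duration_s = x$trial_duration,
         spikes = x$spikes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- as.integer(obj$n_neurons); P <- as.integer(obj$n_trials)
  sp <- obj$spikes
  spikes <- lapply(seq_len(Q), function(i)
    lapply(seq_len(P), function(p) as.numeric(unlist(sp[[i]][[p]]))))
  spike_train_set(spikes, as.numeric(obj$trial_duration_s), Q, P)
}

# Convert a binned 0/1 array back to spike times at bin centers (used by the
# simulators, which generate at most one spike per bin).
binned_to_spike_set <- function(counts, bin_width, trial_duration) {
  d <- dim(counts)  # trials x neurons x bins
  spikes <- lapply(seq_len(d[2]), function(i)
    lapply(seq_len(d[1]), function(p) {
      b <- which(counts[p, i, ] > 0L)
      (b - 0.5) * bin_width
    }))
  spike_train_set(spikes, trial_duration, d[2], d[1])
}
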