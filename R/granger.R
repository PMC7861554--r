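#' Deviance-difference Granger test for one directed pair
#'
#' Tests the influence j -> i by comparing the full CIF fit of target i with
#' the reduced fit that omits source j's M history terms. Under the null the
#' deviance difference is asymptotically chi-square with M degrees of
#' freedom.
#'
#' @param full A converged `fitted_cif` for the full model of target i.
#' @param reduced The same specification refit with one source excluded.
#' @return A list with `statistic` (deviance difference, clamped at 0), `df`
#'   and `p_value` (`NA` if either fit failed to converge).
#' @export
granger_test <- function(full, reduced) {
  stopifnot(inherits(full, "fitted_cif"), inherits(reduced, "fitted_cif"))
  same <- full$method == reduced$method && full$target == reduced$target &&
    isTRUE(all.equal(full$window_width, reduced$window_width)) &&
    full$n_history == reduced$n_history &&
    identical(full$n_exo, reduced$n_exo)
  if (!same || !is.null(full$exclude_source) ||
      is.null(reduced$exclude_source))
    stop("`reduced` must be the full model's spec minus one source's history terms")
  df <- full$n_history
  stat <- max(0, reduced$deviance - full$deviance)
  p <- if (full$converged && reduced$converged)
    stats::pchisq(stat, df = df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p)
}

#' Interaction function of a fitted CIF model
#'
#' The lag-resolved history coefficients `gamma[source, m]` of a target's
#' fit, with Wald standard errors and two-sided p-values, evaluated at the
#' lag-window midpoints `m * W - W / 2`.
#'
#' @param fit A `fitted_cif`.
#' @param source Source neuron index (must be included in the fit).
#' @return A data frame with columns `lag_mid`, `estimate`, `se`, `p_value`.
#' @export
interaction_function <- function(fit, source) {
  stopifnot(inherits(fit, "fitted_cif"))
  if (!is.null(fit$exclude_source) && fit$exclude_source == source)
    stop("source ", source, " is excluded from this fit")
  idx <- which(fit$col_role == "interaction" & fit$col_source == source)
  if (!length(idx)) stop("source ", source, " not present in this fit")
  idx <- idx[order(fit$col_lag[idx])]
  est <- unname(fit$coefficients[idx])
  se <- sqrt(diag(fit$vcov)[idx])
  z <- est / se
  data.frame(
    lag_mid = fit$col_lag[idx] * fit$window_width - fit$window_width / 2,
    estimate = est, se = unname(se),
    p_value = 2 * stats::pnorm(-abs(z)))
}

#' Exogenous component of a fitted CIF model
#'
#' Converts the fitted piecewise-constant exogenous terms to a rate curve in
#' spikes/s: `plogis(alpha_hat) / bin_width` per window (for G-ETMV, at the
#' mean-beta reference trial magnitude). Since `lambda * bin_width << 1`,
#' the logit of the bin probability approximates `log(lambda * bin_width)`.
#'
#' @param fit A `fitted_cif` with method `"getm"` or `"getmv"`.
#' @return A data frame with columns `window`, `t_start`, `t_end`, `rate`.
#' @export
exogenous_component <- function(fit) {
  stopifnot(inherits(fit, "fitted_cif"))
  if (fit$method == "kim")
    stop("the Kim baseline model has no exogenous terms")
  a <- unname(fit$coefficients[fit$col_role == "exogenous"])
  off <- 0
  if (fit$method == "getmv") {
    b <- fit$coefficients[fit$col_role == "trial"]
    P <- fit$n_trials
    beta <- if (fit$beta_mode == "sum_zero" && length(b) == P - 1)
      c(b, -sum(b)) else as.numeric(b)
    off <- mean(beta)
  }
  N <- fit$n_exo
  T_ <- fit$n_bins * fit$bin_width
  data.frame(
    window = seq_len(N),
    t_start = (seq_len(N) - 1) * T_ / N,
    t_end = seq_len(N) * T_ / N,
    rate = stats::plogis(a + off) / fit$bin_width)
}

#' Directed functional-connectivity analysis
#'
#' The full pipeline for one spike-train set: for each target neuron i,
#' AIC-selects the hyperparameters of the chosen CIF model, fits the full
#' model, refits Q reduced models (each omitting one source's history terms,
#' including the target itself: self-influence is a testable link), and runs
#' the deviance chi-square test for every ordered pair j -> i. A pair is
#' significant when its (optionally multiplicity-adjusted) p-value is below
#' `alpha`; the default is the raw per-connection threshold.
#'
#' @param spikes A [spike_train_set()].
#' @param method `"kim"`, `"getm"` or `"getmv"`.
#' @param alpha Significance level per connection; default 0.05.
#' @param grid Hyperparameter grid ([cif_grid()]).
#' @param bin_width Bin width (s); default 0.001.
#' @param beta_mode See [cif_spec()].
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (`"none"`, `"bonferroni"`, `"fdr"`, ...); default `"none"`.
#' @return An object of class `connectivity_result`: Q x Q matrices
#'   (`[source, target]`) `deviance`, `df`, `p_value`, `significant`;
#'   per-target interaction functions, exogenous rate curves
#'   (`"getm"`/`"getmv"`), trial magnitudes (`"getmv"`), and the selected
#'   per-target hyperparameters.
#' @export
connectivity <- function(spikes, method = c("getm", "kim", "getmv"),
                         alpha = 0.05, grid = cif_grid(), bin_width = 0.001,
                         beta_mode = "sum_zero", p_adjust = "none") {
  method <- match.arg(method)
  stopifnot(inherits(spikes, "spike_train_set"))
  binned <- bin_spikes(spikes, bin_width)
  Q <- binned$n_neurons
  mk <- function(v) matrix(v, Q, Q, dimnames = list(
    source = seq_len(Q), target = seq_len(Q)))
  D <- mk(NA_real_); df <- mk(NA_real_); pv <- mk(NA_real_)
  interactions <- vector("list", Q)
  exo <- vector("list", Q)
  tmag <- if (method == "getmv") matrix(NA_real_, Q, spikes$n_trials)
  specs <- vector("list", Q)
  failures <- character()

  for (i in seq_len(Q)) {
    sel <- tryCatch(
      select_cif_spec(binned, i, method, grid, beta_mode = beta_mode),
      error = function(e) e)
    if (inherits(sel, "error")) {
      failures <- c(failures, sprintf("target %d: %s", i, conditionMessage(sel)))
      next
    }
    full <- sel$fit
    specs[[i]] <- list(window_width = full$window_width,
                       n_history = full$n_history, n_exo = full$n_exo,
                       aic = full$aic)
    interactions[[i]] <- lapply(seq_len(Q), function(j)
      interaction_function(full, j))
    if (method != "kim") exo[[i]] <- exogenous_component(full)
    if (method == "getmv") tmag[i, ] <- trial_magnitudes(full)
    for (j in seq_len(Q)) {
      gt <- tryCatch(
        granger_test(full, fit_design(sel$design, exclude_source = j)),
        error = function(e) e)
      if (inherits(gt, "error")) {
        failures <- c(failures,
                      sprintf("pair %d->%d: %s", j, i, conditionMessage(gt)))
        next
      }
      D[j, i] <- gt$statistic; df[j, i] <- gt$df; pv[j, i] <- gt$p_value
    }
  }
  padj <- mk(stats::p.adjust(as.vector(pv), method = p_adjust))
  sig <- padj < alpha
  structure(
    list(method = method, alpha = alpha, p_adjust = p_adjust,
         deviance = D, df = df, p_value = pv, p_adjusted = padj,
         significant = sig, interactions = interactions,
         exogenous = exo, trial_magnitude = tmag, specs = specs,
         n_neurons = Q, failures = failures),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity_result [%s], alpha = %g (%s adjustment)\n",
              toupper(x$method), x$alpha, x$p_adjust))
  n_sig <- sum(x$significant, na.rm = TRUE)
  cat(sprintf("  %d significant link(s) of %d ordered pairs\n",
              n_sig, x$n_neurons^2))
  if (n_sig) {
    idx <- which(x$significant, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      cat(sprintf("    %d -> %d  (deviance diff %.1f, df %d, p = %.2e)\n",
                  idx[r, 1], idx[r, 2], x$deviance[idx[r, 1], idx[r, 2]],
                  x$df[idx[r, 1], idx[r, 2]],
                  x$p_value[idx[r, 1], idx[r, 2]]))
  }
  if (length(x$failures))
    cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Serialize a connectivity result to JSON
#'
#' @param x A `connectivity_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_connectivity_json <- function(x, path) {
  stopifnot(inherits(x, "connectivity_result"))
  obj <- list(
    method = x$method, alpha = x$alpha, p_adjust = x$p_adjust,
    n_neurons = x$n_neurons,
    deviance = x$deviance, df = x$df, p_value = x$p_value,
    significant = x$significant,
    specs = x$specs,
    exogenous = x$exogenous,
    trial_magnitude = x$trial_magnitude,
    interactions = x$interactions,
    failures = x$failures)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
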