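#' Conditional-intensity model specification
#'
#' Describes one of the three nested CIF models for a target neuron, all fit
#' as binomial GLMs with a logit link on 0/1 spike-occupancy bins:
#'
#' * `"kim"` — baseline point-process Granger model: an intercept plus
#'   ensemble spiking-history terms `gamma[q, m]`.
#' * `"getm"` — replaces the intercept by `n_exo` piecewise-constant
#'   exogenous temporal-modulation terms `alpha[c(t)]` (one per equal window
#'   of the trial).
#' * `"getmv"` — additionally includes per-trial response-magnitude terms
#'   `beta[p]`, with the alpha/beta translation degeneracy removed (see
#'   `beta_mode`).
#'
#' @param method `"kim"`, `"getm"` or `"getmv"`.
#' @param target Target neuron index i.
#' @param window_width History lag-window duration W (s).
#' @param n_history Number of history lag windows M per source neuron.
#' @param n_exo Number of exogenous windows N (`"getm"`/`"getmv"` only).
#' @param exclude_source Optional source neuron j whose history terms are
#'   omitted (the reduced model of the Granger test); j = i is allowed
#'   (self-influence is a testable link).
#' @param beta_mode How the alpha/beta gauge freedom of `"getmv"` is removed:
#'   `"sum_zero"` (hard sum-to-zero reparameterization of beta, the default)
#'   or `"penalty"` (two pseudo-observation rows shrinking +/- sum(beta)).
#' @return An object of class `cif_spec`.
#' @export
cif_spec <- function(method = c("getm", "kim", "getmv"), target,
                     window_width, n_history, n_exo = NULL,
                     exclude_source = NULL,
                     beta_mode = c("sum_zero", "penalty")) {
  method <- match.arg(method)
  beta_mode <- match.arg(beta_mode)
  stopifnot(target >= 1, window_width > 0, n_history >= 1)
  if (method == "kim") {
    n_exo <- NULL
  } else {
    if (is.null(n_exo) || n_exo < 1)
      stop(sprintf("`n_exo` required for method \"%s\"", method))
    n_exo <- as.integer(n_exo)
  }
  structure(
    list(method = method, target = as.integer(target),
         window_width = window_width, n_history = as.integer(n_history),
         n_exo = n_exo,
         exclude_source = if (!is.null(exclude_source))
           as.integer(exclude_source),
         beta_mode = beta_mode),
    class = "cif_spec")
}

#' Hyperparameter grid for AIC selection
#'
#' @param window_width Candidate history window widths W (s).
#' @param n_history Candidate history window counts M.
#' @param n_exo Candidate exogenous window counts N (ignored for `"kim"`).
#' @return A data frame of candidate (W, M, N) combinations.
#' @export
cif_grid <- function(window_width = c(0.002, 0.004, 0.008),
                     n_history = c(4, 6, 8, 10),
                     n_exo = c(5, 10, 15, 20, 30)) {
  expand.grid(window_width = window_width, n_history = n_history,
              n_exo = n_exo)
}

# Compact grid used by the Monte-Carlo experiments (documented in the
# methods vignette): fixed 4-ms windows, M = 4 lags, AIC choice over N.
mc_grid <- function() cif_grid(0.004, 4, c(12, 24))

# ---- row grouping -----------------------------------------------------------

# Combine integer key columns into group ids 1..G, packing as many columns
# as fit exactly into a double before hashing with match().
group_rows <- function(cols) {
  stopifnot(length(cols) >= 1)
  g <- NULL
  acc <- NULL
  accmax <- 1
  fold <- function(g, acc) {
    ids <- match(acc, unique(acc))
    if (is.null(g)) return(ids)
    key <- as.double(g) * (max(ids) + 1) + ids
    match(key, unique(key))
  }
  for (col in cols) {
    base <- max(col) + 1
    if (accmax * base < 2^52 && !is.null(acc)) {
      acc <- acc * base + col
      accmax <- accmax * base
    } else {
      if (!is.null(acc)) g <- fold(g, acc)
      acc <- as.double(col)
      accmax <- base
    }
  }
  fold(g, acc)
}

# ---- design matrices --------------------------------------------------------

#' Build the GLM design for a CIF model
#'
#' Stacks all trials (rows = trials x bins), builds the model's columns
#' (intercept for `"kim"`; one-hot exogenous-window indicators for
#' `"getm"`/`"getmv"`; trial terms for `"getmv"`; `Q * M` history spike
#' counts, minus the excluded source's `M` columns if any), and aggregates
#' identical covariate rows into binomial (successes, trials) groups — an
#' exact reformulation of the Bernoulli likelihood that the fitter exploits.
#'
#' @param binned A [bin_spikes()] result.
#' @param spec A [cif_spec()] **without** `exclude_source` (reduced designs
#'   are obtained by dropping columns; see [fit_cif()]).
#' @return An object of class `cif_design` with the aggregated model matrix
#'   `X`, successes `s`, group sizes `m`, and per-column role metadata.
#' @export
build_design <- function(binned, spec) {
  stopifnot(inherits(binned, "binned_spikes"), inherits(spec, "cif_spec"))
  Q <- binned$n_neurons; P <- binned$n_trials; K <- binned$n_bins
  if (spec$target > Q) stop("target neuron out of range")
  M <- spec$n_history; W <- spec$window_width
  hist <- history_covariates(binned, W, M)
  w_bins <- as.integer(round(W / binned$bin_width))

  # rows: trial index varies fastest, then bin
  H <- matrix(hist$R, nrow = P * K)  # columns ordered (q, m), q fastest
  colnames(H) <- paste0("g_", rep(seq_len(Q), M), "_",
                        rep(seq_len(M), each = Q))
  col_source_h <- rep(seq_len(Q), M)
  col_lag_h <- rep(seq_len(M), each = Q)
  y <- as.integer(binned$counts[, spec$target, ])
  trial_of_row <- rep(seq_len(P), K)

  keys <- lapply(seq_len(ncol(H)), function(j) as.integer(H[, j]))
  if (spec$method %in% c("getm", "getmv")) {
    exo <- bin_exo_index(K, binned$bin_width, binned$trial_duration,
                         spec$n_exo)[rep(seq_len(K), each = P)]
    keys <- c(list(exo), keys)
  }
  if (spec$method == "getmv") keys <- c(list(trial_of_row), keys)

  g <- group_rows(keys)
  s <- as.numeric(rowsum(as.numeric(y), g))
  m <- as.numeric(rowsum(rep(1, length(g)), g))
  rep_idx <- which(!duplicated(g))
  rep_idx <- rep_idx[order(g[rep_idx])]

  Ha <- H[rep_idx, , drop = FALSE]
  parts <- list(); roles <- character(); src <- integer(); lag <- integer()
  add <- function(X, role, source = NA_integer_, lg = NA_integer_) {
    parts[[length(parts) + 1L]] <<- X
    roles <<- c(roles, rep(role, ncol(X)))
    src <<- c(src, rep(source, ncol(X)))
    lag <<- c(lag, rep(lg, ncol(X)))
  }
  if (spec$method == "kim") {
    add(matrix(1, nrow(Ha), 1, dimnames = list(NULL, "(Intercept)")),
        "baseline")
  } else {
    ex <- exo[rep_idx]
    Xe <- matrix(0, nrow(Ha), spec$n_exo,
                 dimnames = list(NULL, paste0("exo_", seq_len(spec$n_exo))))
    Xe[cbind(seq_len(nrow(Ha)), ex)] <- 1
    add(Xe, "exogenous")
  }
  n_penalty <- 0L
  if (spec$method == "getmv" && P > 1) {
    tr <- trial_of_row[rep_idx]
    if (spec$beta_mode == "sum_zero") {
      # sum-to-zero contrasts: beta_P = -sum(beta_1..P-1)
      Xt <- matrix(0, nrow(Ha), P - 1,
                   dimnames = list(NULL, paste0("trial_", seq_len(P - 1))))
      for (p in seq_len(P - 1)) Xt[tr == p, p] <- 1
      Xt[tr == P, ] <- -1
      add(Xt, "trial")
    } else {
      Xt <- matrix(0, nrow(Ha), P,
                   dimnames = list(NULL, paste0("trial_", seq_len(P))))
      Xt[cbind(seq_len(nrow(Ha)), tr)] <- 1
      add(Xt, "trial")
      n_penalty <- 2L
    }
  }
  for (j in seq_len(ncol(Ha)))
    add(Ha[, j, drop = FALSE], "interaction", col_source_h[j], col_lag_h[j])
  X <- do.call(cbind, parts)

  if (n_penalty > 0L) {
    # two regularizer rows shrinking +sum(beta) and -sum(beta)
    pen <- matrix(0, 2, ncol(X))
    pen[, roles == "trial"] <- rbind(rep(1, P), rep(-1, P))
    X <- rbind(X, pen)
    s <- c(s, 100, 100)
    m <- c(m, 200, 200)
  }

  structure(
    list(X = X, s = s, m = m, col_role = roles, col_source = src,
         col_lag = lag, method = spec$method, target = spec$target,
         window_width = W, n_history = M, n_exo = spec$n_exo,
         beta_mode = spec$beta_mode, n_trials = P, n_bins = K,
         bin_width = binned$bin_width, trial_duration = binned$trial_duration,
         n_obs = P * K, n_penalty = n_penalty),
    class = "cif_design")
}

# ---- fitting ----------------------------------------------------------------

# Fit a (possibly source-reduced) CIF design by binomial IRLS via
# stats::glm.fit on the aggregated groups. Log-likelihood, deviance and AIC
# are computed on the Bernoulli scale (saturated log-likelihood 0), so they
# are invariant to the row grouping: deviance = -2 * loglik,
# AIC = deviance + 2 * rank.
fit_design <- function(design, exclude_source = NULL) {
  stopifnot(inherits(design, "cif_design"))
  keep <- rep(TRUE, ncol(design$X))
  if (!is.null(exclude_source))
    keep <- !(design$col_role == "interaction" &
                design$col_source == exclude_source)
  X <- design$X[, keep, drop = FALSE]
  keep_ll <- seq_len(length(design$s) - design$n_penalty)  # data rows only
  # a response with no spikes at all (or none missing) has no finite MLE
  degenerate <- sum(design$s[keep_ll]) == 0 ||
    sum(design$s[keep_ll]) == sum(design$m[keep_ll])
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, design$s / design$m, weights = design$m,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!degenerate && fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("design is rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  pr <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  ll <- sum(design$s[keep_ll] * log(pr[keep_ll]) +
              (design$m[keep_ll] - design$s[keep_ll]) * log(1 - pr[keep_ll]))
  k <- fit$rank
  # coefficient covariance from the weighted QR, as summary.glm does
  Vc <- tryCatch({
    covu <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
    piv <- fit$qr$pivot[seq_len(k)]
    V <- matrix(NA_real_, ncol(X), ncol(X),
                dimnames = list(colnames(X), colnames(X)))
    V[piv, piv] <- covu
    V
  }, error = function(e) matrix(NA_real_, ncol(X), ncol(X)))

  structure(
    list(coefficients = fit$coefficients, vcov = Vc,
         loglik = ll, deviance = -2 * ll, aic = -2 * ll + 2 * k, k = k,
         converged = isTRUE(fit$converged) && !degenerate,
         irls_converged = isTRUE(fit$converged), separation = separation,
         degenerate = degenerate,
         method = design$method, target = design$target,
         window_width = design$window_width, n_history = design$n_history,
         n_exo = design$n_exo, beta_mode = design$beta_mode,
         exclude_source = exclude_source,
         col_role = design$col_role[keep],
         col_source = design$col_source[keep],
         col_lag = design$col_lag[keep],
         n_trials = design$n_trials, n_bins = design$n_bins,
         bin_width = design$bin_width, n_obs = design$n_obs),
    class = "fitted_cif")
}

#' Fit a conditional-intensity model
#'
#' Builds the design for `spec` and fits it by iteratively reweighted
#' maximum likelihood (binomial family, logit link). Returns coefficients,
#' their covariance, the Bernoulli-scale log-likelihood and deviance
#' (`-2 * loglik`), `AIC = deviance + 2k`, and a convergence flag; fits that
#' hit complete separation are flagged non-converged and are treated as
#' missing downstream.
#'
#' @param binned A [bin_spikes()] result.
#' @param spec A [cif_spec()].
#' @return An object of class `fitted_cif`.
#' @export
fit_cif <- function(binned, spec) {
  excl <- spec$exclude_source
  spec$exclude_source <- NULL
  fit_design(build_design(binned, spec), exclude_source = excl)
}

#' @export
print.fitted_cif <- function(x, ...) {
  cat(sprintf(
    "fitted_cif [%s] target %d: W = %g s, M = %d%s%s\n  deviance %.1f, AIC %.1f, k = %d, %s\n",
    toupper(x$method), x$target, x$window_width, x$n_history,
    if (!is.null(x$n_exo)) sprintf(", N = %d", x$n_exo) else "",
    if (!is.null(x$exclude_source))
      sprintf(" (source %d excluded)", x$exclude_source) else "",
    x$deviance, x$aic, x$k,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-trial response magnitudes from a G-ETMV fit
#'
#' Returns `exp(beta_hat)` under the mean-zero convention (beta re-centered),
#' one value per trial, estimating the relative trial gains up to a common
#' scale.
#'
#' @param fit A `fitted_cif` with method `"getmv"`.
#' @return Numeric vector of length `n_trials`.
#' @export
trial_magnitudes <- function(fit) {
  stopifnot(inherits(fit, "fitted_cif"))
  if (fit$method != "getmv") stop("trial magnitudes require a G-ETMV fit")
  b <- fit$coefficients[fit$col_role == "trial"]
  P <- fit$n_trials
  beta <- if (fit$beta_mode == "sum_zero" && length(b) == P - 1)
    c(b, -sum(b)) else as.numeric(b)
  beta <- beta - mean(beta)
  unname(exp(beta))
}

#' AIC selection of CIF hyperparameters
#'
#' Fits the full model for every candidate in `grid` and returns the
#' AIC-minimizing specification (ties broken toward fewer parameters, then
#' smaller window width). Selection is per target neuron; reduced models of
#' the Granger test inherit the selected hyperparameters.
#'
#' @param binned A [bin_spikes()] result.
#' @param target Target neuron index.
#' @param method `"kim"`, `"getm"` or `"getmv"`.
#' @param grid A data frame from [cif_grid()].
#' @param beta_mode See [cif_spec()].
#' @return A list with `spec` (the winning [cif_spec()]), `fit` (its fitted
#'   full model), `design` (its [build_design()] result, reusable for the
#'   reduced fits) and `aic_table`.
#' @export
select_cif_spec <- function(binned, target, method, grid = cif_grid(),
                            beta_mode = "sum_zero") {
  stopifnot(nrow(grid) >= 1)
  if (method == "kim") {
    grid$n_exo <- NA
    grid <- unique(grid[, c("window_width", "n_history", "n_exo")])
  }
  best <- NULL
  tab <- grid
  tab$aic <- NA_real_; tab$k <- NA_integer_; tab$converged <- FALSE
  for (r in seq_len(nrow(grid))) {
    spec <- cif_spec(method, target, grid$window_width[r], grid$n_history[r],
                     n_exo = if (method == "kim") NULL else grid$n_exo[r],
                     beta_mode = beta_mode)
    res <- tryCatch({
      design <- build_design(binned, spec)
      list(design = design, fit = fit_design(design))
    }, error = function(e) NULL)
    if (is.null(res) || !res$fit$converged) next
    tab$aic[r] <- res$fit$aic; tab$k[r] <- res$fit$k; tab$converged[r] <- TRUE
    better <- is.null(best) ||
      res$fit$aic < best$fit$aic - 1e-9 ||
      (abs(res$fit$aic - best$fit$aic) <= 1e-9 &&
         (res$fit$k < best$fit$k ||
            (res$fit$k == best$fit$k &&
               spec$window_width < best$spec$window_width)))
    if (better) best <- list(spec = spec, fit = res$fit, design = res$design)
  }
  if (is.null(best))
    stop("no hyperparameter candidate produced a converged fit for target ",
         target)
  best$aic_table <- tab
  best
}
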