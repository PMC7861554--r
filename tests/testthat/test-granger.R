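stub_fit <- function(deviance, method = "getm", target = 1, W = 0.004,
                     M = 4, N = 12, excl = NULL, converged = TRUE) {
  structure(
    list(method = method, target = target, window_width = W, n_history = M,
         n_exo = N, deviance = deviance, converged = converged,
         exclude_source = excl),
    class = "fitted_cif")
}

test_that("the deviance test follows the chi-square reference", {
  # zero difference -> p = 1
  gt <- granger_test(stub_fit(100), stub_fit(100, excl = 2L))
  expect_equal(gt$p_value, 1)
  expect_equal(gt$df, 4)

  # the 5% critical value of chi-square(1)
  gt1 <- granger_test(stub_fit(100, M = 1), stub_fit(103.841, M = 1, excl = 2L))
  expect_equal(gt1$p_value, 0.05, tolerance = 1e-3)

  # float noise putting the full model above the reduced is clamped to 0
  gt2 <- granger_test(stub_fit(100 + 1e-7), stub_fit(100, excl = 2L))
  expect_equal(gt2$statistic, 0)
  expect_equal(gt2$p_value, 1)

  # non-converged fits report a missing p-value, never significance
  gt3 <- granger_test(stub_fit(100), stub_fit(200, excl = 2L,
                                              converged = FALSE))
  expect_true(is.na(gt3$p_value))

  # mismatched specs are rejected
  expect_error(granger_test(stub_fit(100), stub_fit(90, N = 24, excl = 2L)),
               "reduced")
  expect_error(granger_test(stub_fit(100), stub_fit(90)), "reduced")
})

test_that("a single strong link is found and only that link", {
  sc <- make_scenario("fig6", seed = 3, strength = 1.2)
  res <- connectivity(sc$spikes, "getm", grid = cif_grid(0.004, 4, c(12, 24)))
  sig <- res$significant
  expect_true(sig[1, 2])
  # the three non-links stay silent in this realization
  expect_equal(sum(sig), 1)
})

test_that("the modal fig1 outcome reproduces the model-mismatch contrast", {
  spurious_kim <- links_getm <- 0
  getm_zero_runs <- 0
  for (s in 1:4) {
    sc <- make_scenario("fig1", seed = 60 + s)
    k <- connectivity(sc$spikes, "kim", grid = cif_grid(0.004, 4))
    g <- connectivity(sc$spikes, "getm", grid = cif_grid(0.004, 4, c(12, 24)))
    spurious_kim <- spurious_kim + sum(k$significant, na.rm = TRUE)
    n_g <- sum(g$significant, na.rm = TRUE)
    links_getm <- links_getm + n_g
    getm_zero_runs <- getm_zero_runs + (n_g == 0)
  }
  expect_gt(spurious_kim, 0)      # the baseline model hallucinates links
  expect_gte(getm_zero_runs, 3)   # no-link is the modal G-ETM outcome
  expect_gt(spurious_kim, links_getm)
})

test_that("interaction functions carry lag midpoints and reject excluded sources", {
  set.seed(71)
  sp <- poisson_set(2, 6, 20, 2)
  b <- bin_quiet(sp)
  f <- fit_cif(b, cif_spec("getm", 1, 0.004, 3, n_exo = 5))
  fi <- interaction_function(f, 2)
  expect_equal(fi$lag_mid, c(0.002, 0.006, 0.010))
  expect_equal(nrow(fi), 3)
  expect_true(all(fi$p_value >= 0 & fi$p_value <= 1))

  fr <- fit_cif(b, cif_spec("getm", 1, 0.004, 3, n_exo = 5,
                            exclude_source = 2))
  expect_error(interaction_function(fr, 2), "excluded")
})

test_that("interaction signs track the generative weights", {
  agree <- 0
  for (s in 1:5) {
    w <- if (s %% 2) 0.8 else -0.8
    net <- network_spec(2, data.frame(source = 1L, target = 2L, lag = 1L,
                                      weight = w), baseline_rate = 15)
    sp <- simulate_network(net, 30, seed = 80 + s)
    f <- fit_cif(bin_quiet(sp), cif_spec("getm", 2, 0.004, 4, n_exo = 6))
    est <- interaction_function(f, 1)$estimate[1]
    agree <- agree + (sign(est) == sign(w))
  }
  expect_equal(agree, 5)
})

test_that("the exogenous component recovers homogeneous and bump profiles", {
  net <- network_spec(1, baseline_rate = 10)
  sp <- simulate_network(net, 60, seed = 91)
  f <- fit_cif(bin_quiet(sp), cif_spec("getm", 1, 0.004, 2, n_exo = 5))
  ex <- exogenous_component(f)
  expect_equal(nrow(ex), 5)
  a <- f$coefficients[f$col_role == "exogenous"]
  se <- sqrt(diag(f$vcov)[1:5])
  expect_true(all(abs(a - qlogis(10 * 0.001)) < 3 * se))

  # Gaussian-bump truth: recovered curve tracks the bump closely
  netb <- network_spec(1, baseline_rate = 10, bump_amplitude = 16,
                       bump_time = 1.4)
  spb <- simulate_network(netb, 60, seed = 92)
  fb <- fit_cif(bin_quiet(spb), cif_spec("getm", 1, 0.004, 2, n_exo = 30))
  exb <- exogenous_component(fb)
  tc <- (exb$t_start + exb$t_end) / 2
  truth <- 10 + 16 * exp(-(tc - 1.4)^2 / (2 * 0.2^2))
  expect_gt(stats::cor(exb$rate, truth), 0.9)

  kim <- fit_cif(bin_quiet(spb), cif_spec("kim", 1, 0.004, 2))
  expect_error(exogenous_component(kim), "no exogenous")
})

test_that("relabeling neurons permutes the connectivity outputs consistently", {
  sc <- make_scenario("fig6", seed = 5, strength = 1, n_trials = 25)
  sp <- sc$spikes
  swapped <- spike_train_set(list(sp$spikes[[2]], sp$spikes[[1]]),
                             sp$trial_duration)
  grid <- cif_grid(0.004, 4, 12)
  a <- connectivity(sp, "getm", grid = grid)
  b <- connectivity(swapped, "getm", grid = grid)
  perm <- c(2L, 1L)
  expect_equal(unname(a$p_value), unname(b$p_value[perm, perm]),
               tolerance = 1e-8)
  expect_equal(unname(a$deviance), unname(b$deviance[perm, perm]),
               tolerance = 1e-6)
})

test_that("connectivity JSON serialization writes the full result", {
  sc <- make_scenario("fig1", seed = 8, n_trials = 10)
  res <- connectivity(sc$spikes, "getm", grid = cif_grid(0.004, 4, 12))
  tmp <- tempfile(fileext = ".json")
  write_connectivity_json(res, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$method, "getm")
  expect_equal(dim(back$p_value), c(2, 2))
  expect_equal(back$p_value, unname(res$p_value), tolerance = 1e-12)
  unlink(tmp)
})
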