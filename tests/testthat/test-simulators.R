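test_that("simulation is byte-identical under a fixed seed", {
  net <- random_network(4, 6, seed = 5)
  net2 <- random_network(4, 6, seed = 5)
  expect_identical(net, net2)
  a <- simulate_network(net, 5, seed = 9)
  b <- simulate_network(net, 5, seed = 9)
  expect_identical(a, b)

  ifn <- random_if_network(4, 6, seed = 5)
  expect_identical(simulate_if_network(ifn, 3, seed = 9),
                   simulate_if_network(ifn, 3, seed = 9))
})

test_that("unconnected stationary units are Poisson at the nominal rate", {
  net <- network_spec(1, baseline_rate = 20)
  sp <- simulate_network(net, 200, seed = 11)
  counts <- lengths(sp$spikes[[1]])
  # mean spikes/trial ~ 60 within 3 MC standard errors
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / 200))
  # ISI distribution consistent with the exponential at 1% level
  isi <- unlist(lapply(sp$spikes[[1]][1:30], diff))
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", 1 / mean(isi)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the empirical PSTH tracks the Gaussian exogenous modulation", {
  net <- network_spec(1, baseline_rate = 10, bump_amplitude = 16,
                      bump_time = 1.3, bump_sd = 0.2)
  sp <- simulate_network(net, 300, seed = 13)
  b <- bin_spikes(sp)
  psth <- colMeans(b$counts[, 1, ]) / 0.001
  # peak location within ~bump sd of the true peak (100-ms smoothing)
  sm <- stats::filter(psth, rep(1 / 101, 101), sides = 2)
  expect_lt(abs(which.max(sm) / 1000 - 1.3), 0.2)
  # window-averaged rates match the intended profile within 3 MC SE
  tc <- (seq_len(3000) - 0.5) / 1000
  lam <- 10 + 16 * exp(-(tc - 1.3)^2 / (2 * 0.2^2))
  for (w in list(1:300, 1200:1400, 2700:3000)) {
    expect_lt(abs(mean(psth[w]) - mean(lam[w])),
              3 * sqrt(mean(lam[w]) / (0.001 * length(w) * 300)))
  }
})

test_that("shared trial gains correlate the units' per-trial spike counts", {
  sc <- make_scenario("fig8", seed = 17)
  expect_identical(sc$network$trial_gains[1, ], sc$network$trial_gains[2, ])
  n1 <- lengths(sc$spikes$spikes[[1]])
  n2 <- lengths(sc$spikes$spikes[[2]])
  expect_gt(stats::cor(n1, n2), 0.5)
})

test_that("interaction sign moves the conditional rate in the right direction", {
  mk <- function(w) network_spec(
    2, data.frame(source = 1L, target = 2L, lag = 1L, weight = w),
    baseline_rate = 15)
  post_rate <- function(sp) {
    b <- bin_spikes(sp)
    tot <- n <- 0
    for (p in seq_len(b$n_trials)) {
      s1 <- which(b$counts[p, 1, ] > 0)
      s1 <- s1[s1 < b$n_bins - 4]
      tot <- tot + sum(b$counts[p, 2, ][rep(s1, each = 4) + 1:4])
      n <- n + 4 * length(s1)
    }
    1000 * tot / n
  }
  exc <- post_rate(simulate_network(mk(0.8), 40, seed = 19))
  inh <- post_rate(simulate_network(mk(-0.8), 40, seed = 19))
  expect_gt(exc, 15 * 1.5)
  expect_lt(inh, 15 * 0.7)
})

test_that("random networks have the stated edge census and sampling law", {
  net <- random_network(4, 6, seed = 23)
  expect_equal(nrow(net$edges), 6L)
  expect_equal(nrow(unique(net$edges[, c("source", "target")])), 6L)
  expect_equal(16 - nrow(ppgranger:::truth_edges(net)), 10L)
  expect_true(all(abs(net$edges$weight) >= 0.35 &
                    abs(net$edges$weight) <= 1))
  expect_true(all(net$bump_time >= 1 & net$bump_time <= 2))

  # every ordered pair (self-pairs included) selected with frequency ~ 6/16
  hits <- matrix(0, 4, 4)
  for (s in 1:600) {
    e <- random_network(4, 6, seed = 10000 + s)$edges
    hits[cbind(e$target, e$source)] <- hits[cbind(e$target, e$source)] + 1
  }
  freq <- hits / 600
  se <- sqrt(6 / 16 * 10 / 16 / 600)
  expect_true(all(abs(freq - 6 / 16) < 4 * se))
})

test_that("rates exceeding the Bernoulli bound are rejected with a message", {
  # deterministic bound: baseline alone breaks rate * dt <= 0.5
  too_hot <- network_spec(1, baseline_rate = 600)
  expect_error(simulate_network(too_hot, 1, seed = 1), "0.5")
  # interaction-driven blow-up caught bin by bin
  runaway <- network_spec(
    1, data.frame(source = 1L, target = 1L, lag = 1L, weight = 4),
    baseline_rate = 40)
  expect_error(simulate_network(runaway, 30, seed = 1), "granularity")
})

test_that("exponential thresholds give Poisson-like, fixed thresholds clock-like ISIs", {
  pois <- if_network_spec(1, baseline_rate = 15)
  sp <- simulate_if_network(pois, 30, seed = 29)
  isi <- unlist(lapply(sp$spikes[[1]], diff))
  cv <- sd(isi) / mean(isi)
  expect_gt(cv, 0.8); expect_lt(cv, 1.2)
  rate <- length(unlist(lapply(sp$spikes[[1]], identity))) / (30 * 3)
  expect_gt(rate, 5); expect_lt(rate, 30)

  reg <- if_network_spec(1, baseline_rate = 15, threshold_mode = "fixed")
  spr <- simulate_if_network(reg, 10, seed = 29)
  isir <- unlist(lapply(spr$spikes[[1]], diff))
  expect_lt(sd(isir) / mean(isir), 0.1)

  expect_error(if_network_spec(1, threshold_mean = 0), "positive")
})

test_that("an excitatory IF synapse leaves a short-lag cross-correlogram peak", {
  W <- matrix(0, 2, 2); W[2, 1] <- 0.6
  net <- if_network_spec(2, W, baseline_rate = 15)
  sp <- simulate_if_network(net, 40, seed = 31)
  b <- bin_spikes(sp)
  short <- long <- 0
  for (p in 1:40) {
    s1 <- which(b$counts[p, 1, ] > 0)
    s1 <- s1[s1 < b$n_bins - 60]
    short <- short + sum(b$counts[p, 2, ][rep(s1, each = 5) + 1:5]) / 5
    long <- long + sum(b$counts[p, 2, ][rep(s1, each = 5) + 51:55]) / 5
  }
  expect_gt(short, 1.5 * long)  # elevated rate at 1-5 ms vs 51-55 ms lags
})

test_that("scenarios encode their documented structure", {
  sc1 <- make_scenario("fig1", seed = 37)
  expect_equal(sc1$spikes$n_neurons, 2L)
  expect_equal(sc1$spikes$n_trials, 40L)
  expect_equal(nrow(sc1$truth), 0L)

  sc4 <- make_scenario("fig4", seed = 37)
  expect_equal(nrow(sc4$truth), 6L)

  sc6 <- make_scenario("fig6", seed = 37, strength = 1.2, n_trials = 12)
  expect_equal(sc6$truth, data.frame(source = 1L, target = 2L),
               ignore_attr = TRUE)
  expect_equal(sc6$network$edges$weight, 1.2)
  expect_equal(sc6$network$bump_amplitude, c(16, 0))

  sc3 <- make_scenario("fig3", seed = 37, n_trials = 5)
  expect_equal(sc3$spikes$n_neurons, 9L)
  # disjoint subsets: no edge crosses the 1-3 / 4-9 boundary
  crosses <- xor(sc3$truth$source <= 3, sc3$truth$target <= 3)
  expect_false(any(crosses))

  expect_error(make_scenario("fig2", seed = 1), "arg")
})
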