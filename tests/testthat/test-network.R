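test_that("ramp recurrence follows its closed form and fixed point", {
  expect_equal(ramp_step(0, 1), 0.1)
  expect_equal(ramp_step(1, 1), 1)
  f <- 0
  for (n in 1:25) f <- ramp_step(f, 1)
  expect_equal(f, 1 - 0.9^25)
  # monotone non-decreasing, bounded above by the target
  f <- 0.3
  for (n in 1:50) {
    f2 <- ramp_step(f, 0.8)
    expect_gte(f2, f); expect_lte(f2, 0.8)
    f <- f2
  }
  expect_error(ramp_step(-0.1, 1), "non-negative")
})

test_that("external drive has the printed mean and mean-reverting dynamics", {
  expect_equal(external_drive_mu(1, 2.5, 100, 2), 0.5)
  # sigma = 0: exponential decay toward mu
  S <- 1; mu <- 0.5; tau <- 2; dt <- 0.01
  for (i in 1:1000) S <- external_drive_step(S, mu, 0, tau, dt, 0)
  expect_equal(S, mu + (1 - mu) * (1 - dt / tau)^1000, tolerance = 1e-12)
  expect_lt(abs(S - mu), 0.01)
  # long-run sample mean and sd match the stationary law
  set.seed(1)
  n <- 2e5
  draws <- rnorm(n)
  S <- numeric(n); s <- mu
  for (i in 1:n) s <- S[i] <- external_drive_step(s, mu, 0.2, tau, 0.1, draws[i])
  expect_equal(mean(S), mu, tolerance = 0.01)
  expect_equal(sd(S), 0.2, tolerance = 0.01)
  expect_error(external_drive_step(1, 0, 0, -1, 0.1, 0), "tau")
})

test_that("trials are bit-reproducible given the same network and seed", {
  net <- shared_network()
  t1 <- simulate_trial(net, seed = 11)
  t2 <- simulate_trial(net, seed = 11)
  expect_identical(t1$choice, t2$choice)
  expect_identical(t1$decision_time, t2$decision_time)
  expect_identical(t1$rate_traces, t2$rate_traces)
})

test_that("a strongly biased direct pathway wins the majority of trials", {
  net <- gen_toy_network(bias = 3, seed = 1)
  set.seed(2)
  ch <- vapply(1:40, function(i) simulate_trial(net)$choice, integer(1))
  expect_gt(mean(ch[ch > 0] == 1), 0.75)
})

test_that("disconnected cortical input yields timeouts", {
  ext <- cbgtpolicy:::default_external_drive()
  ext["Cx", "f_ext"] <- 0
  net <- build_network(network_params(external_drive = ext, f_target = 0,
                                      seed = 1))
  set.seed(3)
  expect_true(all(vapply(1:4, function(i) simulate_trial(net)$timeout,
                         logical(1))))
})

test_that("a symmetric naive network chooses fairly", {
  net <- shared_network()
  set.seed(5)
  ch <- vapply(1:200, function(i) simulate_trial(net)$choice, integer(1))
  ch <- ch[ch > 0]
  bt <- binom.test(sum(ch == 1), length(ch), p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("summarize_activity averages traces by region and channel", {
  net <- shared_network()
  tr <- fake_trial(net, list(Thal1 = 10, Thal2 = 10, Cx1 = 20))
  act <- summarize_activity(tr)
  expect_equal(act$rate[act$region == "Thal" & act$channel == 1],
               act$rate[act$region == "Thal" & act$channel == 2])
  expect_equal(act$rate[act$region == "Thal" & act$channel == 1], 10)
  expect_equal(act$rate[act$region == "Cx" & act$channel == 1], 20)
  expect_equal(act$rate[act$region == "Cx" & act$channel == 2], 0)
  expect_error(summarize_activity(list()), "empty")
})

test_that("known Poisson rates are recovered from binned spike counts", {
  net <- shared_network()
  set.seed(7)
  # emulate binned rate traces of a 10 Hz Poisson population
  n_bins <- 400; n_neu <- 20; bin_s <- net$bin_ms / 1000
  counts <- rpois(n_bins, 10 * n_neu * bin_s)
  trs <- fake_trial(net, list(), n_bins = n_bins)
  trs$rate_traces[, "GPe1"] <- counts / (n_neu * bin_s)
  act <- summarize_activity(trs)
  expect_equal(act$rate[act$region == "GPe" & act$channel == 1], 10,
               tolerance = 0.1)
})

test_that("network parameter validation rejects bad settings", {
  expect_error(network_params(efficacies = c(nonexistent = 1)), "unknown")
  expect_error(network_params(threshold_hz = 0))
  p <- network_params()
  p$population_sizes["Cx"] <- 0L
  expect_error(cbgtpolicy:::validate_network_params(p))
})
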