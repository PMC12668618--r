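pl <- plasticity_params()

test_that("spike traces decay exponentially and jump on their own spike", {
  st <- synapse_state(A_pre = 1)
  for (i in 1:100) st <- update_traces(st, FALSE, FALSE, 1, pl)
  expect_equal(st$A_pre, exp(-100 / pl$tau_pre))
  # single pre spike from rest jumps by d_pre / tau_pre (then decays)
  st <- update_traces(synapse_state(), TRUE, FALSE, 1, pl)
  expect_equal(st$A_pre, pl$d_pre / pl$tau_pre)
  # post spike leaves the presynaptic trace untouched
  st0 <- synapse_state(A_pre = 0.4)
  st1 <- update_traces(st0, FALSE, TRUE, 1, pl)
  expect_equal(st1$A_pre, st0$A_pre * exp(-1 / pl$tau_pre))
  expect_gt(st1$A_post, 0)
})

test_that("eligibility decays and moves with the printed sign convention", {
  st <- synapse_state(E = 2)
  for (i in 1:50) st <- update_eligibility(st, FALSE, FALSE, 1, pl)
  expect_equal(st$E, 2 * exp(-50 / pl$tau_e))
  # post spike while A_pre > 0: eligibility increases
  st <- synapse_state(A_pre = 0.5, A_post = 0)
  expect_gt(update_eligibility(st, FALSE, TRUE, 1, pl)$E, 0)
  # pre spike while A_post > 0: eligibility decreases
  st <- synapse_state(A_pre = 0, A_post = 0.5)
  expect_lt(update_eligibility(st, TRUE, FALSE, 1, pl)$E, 0)
})

test_that("conductance jumps by the weight and superposes exponentials", {
  st <- synapse_state(w = 0.5, g = 0.3)
  st1 <- conductance_step(st, FALSE, 1)
  expect_equal(st1$g, 0.3 * exp(-1 / 2))
  st2 <- conductance_step(synapse_state(w = 0.5), TRUE, 1)
  expect_equal(st2$g, 0.5)
  # two spikes dt apart: g = w * (1 + exp(-dt / tau)) just after the second
  g <- conductance_step(synapse_state(w = 0.5), TRUE, 1)
  for (i in 1:4) g <- conductance_step(g, FALSE, 1)
  g <- conductance_step(g, TRUE, 1)
  expect_equal(g$g, 0.5 * (1 + exp(-5 / 2)))
})

test_that("dopamine modulation factor matches its piecewise form", {
  expect_equal(f_kda(-2, "dSPN", gamma = 1, mu = 1), -1)
  expect_equal(f_kda(1, "dSPN", gamma = 1, mu = 1), 1)
  expect_equal(f_kda(3, "iSPN", gamma = 1, mu = 1, eps = 0.5), 0.5)
  # continuity at the break points
  eps_k <- 1e-9
  expect_equal(f_kda(-1 - eps_k, "dSPN"), f_kda(-1 + eps_k, "dSPN"),
               tolerance = 1e-6)
  expect_equal(f_kda(1 - eps_k, "iSPN"), f_kda(1 + eps_k, "iSPN"),
               tolerance = 1e-6)
  # dSPN unsaturated above, iSPN saturated above
  expect_equal(f_kda(5, "dSPN", gamma = 2, mu = 1), 10)
  expect_equal(f_kda(5, "iSPN", gamma = 2, mu = 1, eps = 0.5), 1)
  expect_error(f_kda(0, "GPe"))
})

test_that("weight updates respect the multiplicative bounds", {
  # at w_max with positive drive the update is zero
  st <- synapse_state(E = 1, w = pl$wmax_dspn)
  expect_equal(update_weight(st, 1, "dSPN", 1, pl)$w, pl$wmax_dspn)
  # at w_min with negative drive the update is zero
  st <- synapse_state(E = 1, w = pl$wmin_dspn)
  expect_equal(update_weight(st, -1, "dSPN", 1, pl)$w, pl$wmin_dspn)
  # positive eligibility and dopamine strengthen dSPN, weaken iSPN
  st <- synapse_state(E = 0.1, w = 0.04)
  expect_gt(update_weight(st, 0.5, "dSPN", 1, pl)$w, 0.04)
  expect_lt(update_weight(st, 0.5, "iSPN", 1, pl)$w, 0.04)
})

test_that("weights never leave their bounds over random event sequences", {
  set.seed(42)
  for (rep in 1:20) {
    st <- synapse_state(w = runif(1, pl$wmin_dspn, pl$wmax_dspn))
    target <- sample(c("dSPN", "iSPN"), 1)
    K <- 0
    for (step in 1:300) {
      pre <- runif(1) < 0.1; post <- runif(1) < 0.1
      if (runif(1) < 0.02) K <- K + runif(1, -1.5, 1.5)
      K <- K * exp(-1 / pl$tau_da)
      st <- update_traces(st, pre, post, 1, pl)
      st <- update_eligibility(st, pre, post, 1, pl)
      st <- conductance_step(st, pre, 1)
      st <- update_weight(st, K, target, 1, pl)
      expect_gte(st$w, pl$wmin_dspn)
      expect_lte(st$w, pl$wmax_dspn)
    }
  }
})

test_that("without dopamine the weights are frozen", {
  st <- synapse_state(w = 0.04)
  set.seed(1)
  for (step in 1:200) {
    pre <- runif(1) < 0.2; post <- runif(1) < 0.2
    st <- update_traces(st, pre, post, 1, pl)
    st <- update_eligibility(st, pre, post, 1, pl)
    st <- update_weight(st, 0, "dSPN", 1, pl)
  }
  expect_identical(st$w, 0.04)
})

test_that("reward events implement the prediction-error update", {
  dop <- plasticity_state(plasticity_params(alpha_q = 0.5), Q = c(0, 0))
  dop2 <- reward_event(dop, 1, 1)
  expect_equal(dop2$last_da_inc, 1)
  expect_equal(dop2$Q[1], 0.5)
  # zero prediction error changes nothing
  dop3 <- reward_event(dop2, 1, 0.5)
  expect_equal(dop3$last_da_inc, 0)
  expect_equal(dop3$Q[1], 0.5)
  # repeated rewards converge geometrically at rate (1 - alpha_q)
  q <- 0
  dop4 <- plasticity_state(plasticity_params(alpha_q = 0.3), Q = c(0, 0))
  for (i in 1:10) dop4 <- reward_event(dop4, 1, 1)
  expect_equal(dop4$Q[1], 1 - 0.7^10)
  expect_error(reward_event(dop, 1, 2), "range")
})

test_that("rewarding one channel moves its dSPN and iSPN weights oppositely", {
  # averaged over a few seeded learning sessions: channel-1 rewarded ->
  # channel-1 dSPN mean weight up, channel-1 iSPN mean weight down
  d_spn <- i_spn <- numeric(0)
  for (sd in 1:3) {
    net <- build_network(network_params(seed = sd))
    s <- run_session(net, plasticity_params(),
                     session_config(freeze_stages = 15L,
                                    probe_trials_per_stage = 2L,
                                    baseline_probe = TRUE, seed = 100 + sd))
    w <- s$weights
    w0 <- w[w$stage == 0, ]; w1 <- w[w$stage == 1, ]
    d_spn <- c(d_spn, w1$mean_w[w1$target == "dSPN" & w1$channel == 1] -
                 w0$mean_w[w0$target == "dSPN" & w0$channel == 1])
    i_spn <- c(i_spn, w1$mean_w[w1$target == "iSPN" & w1$channel == 1] -
                 w0$mean_w[w0$target == "iSPN" & w0$channel == 1])
  }
  expect_gt(mean(d_spn), 0)
  expect_lt(mean(i_spn), 0)
})
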