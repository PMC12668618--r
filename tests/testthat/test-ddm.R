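test_that("simulated absorption matches the closed form", {
  p <- ddm_params(v = 0.8, a = 1.2, t0 = 0.2, z = 0.5)
  b <- simulate_ddm(p, n = 8000, dt = 1e-4, seed = 1)
  p_cf <- ddm_upper_prob(p)
  expect_equal(mean(b$choice == "upper"), p_cf, tolerance = 0.02)
  # symmetric case: both the probability and the mean decision time
  p0 <- ddm_params(v = 0, a = 2, t0 = 0, z = 0.5)
  b0 <- simulate_ddm(p0, n = 8000, dt = 1e-4, seed = 2)
  expect_equal(mean(b0$choice == "upper"), 0.5, tolerance = 0.02)
  expect_equal(mean(b0$rt), p0$a^2 / 4, tolerance = 0.05)
})

test_that("the first-passage density integrates to the absorption mass", {
  p <- ddm_params(v = 1, a = 1.5, t0 = 0.3, z = 0.4)
  iu <- integrate(function(t) fpt_density(p, t, "upper"), p$t0, Inf,
                  rel.tol = 1e-10)$value
  il <- integrate(function(t) fpt_density(p, t, "lower"), p$t0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(iu, ddm_upper_prob(p), tolerance = 1e-6)
  expect_equal(iu + il, 1, tolerance = 1e-6)
  # symmetry at v = 0, z = 0.5
  ps <- ddm_params(v = 0, a = 1, t0 = 0.1, z = 0.5)
  tt <- seq(0.12, 2, by = 0.05)
  expect_equal(fpt_density(ps, tt, "upper"), fpt_density(ps, tt, "lower"))
  # non-negative everywhere, zero at or before the non-decision time
  expect_true(all(fpt_density(p, seq(0, 5, by = 0.01), "upper") >= 0))
  expect_equal(fpt_density(p, c(0.1, 0.3), "upper"), c(0, 0))
})

test_that("simulator and analytic density agree in distribution", {
  p <- ddm_params(v = 1, a = 1.5, t0 = 0.3, z = 0.5)
  b <- simulate_ddm(p, n = 10000, dt = 1e-4, seed = 3)
  rt_u <- sort(b$rt[b$choice == "upper"])
  mass <- integrate(function(t) fpt_density(p, t, "upper"), p$t0, Inf,
                    rel.tol = 1e-9)$value
  grid_t <- seq(p$t0 + 1e-4, max(rt_u) + 0.5, length.out = 400)
  dens <- fpt_density(p, grid_t, "upper")
  cdf_grid <- cumsum(dens) * diff(grid_t)[1] / mass
  cdf_at <- approx(grid_t, cdf_grid, xout = rt_u, rule = 2)$y
  ks <- max(abs(cdf_at - (seq_along(rt_u) - 0.5) / length(rt_u)))
  expect_lt(ks, 0.02)
})

test_that("MLE recovers generating parameters within 10%", {
  p <- ddm_params(v = 1.0, a = 1.5, t0 = 0.3, z = 0.5)
  b <- simulate_ddm(p, n = 1000, dt = 1e-4, seed = 4)
  set.seed(4)
  f <- fit_ddm_mle(b)
  expect_equal(f$params$v, 1.0, tolerance = 0.1)
  expect_equal(f$params$a, 1.5, tolerance = 0.1)
  expect_equal(f$params$t0, 0.3, tolerance = 0.1)
  expect_false(f$weak_identification)
})

test_that("shifting every reaction time shifts only the onset parameter", {
  p <- ddm_params(v = 1.0, a = 1.5, t0 = 0.3, z = 0.5)
  b <- simulate_ddm(p, n = 1000, dt = 1e-4, seed = 5)
  set.seed(5); f1 <- fit_ddm_mle(b)
  b2 <- b; b2$rt <- b2$rt + 0.1
  set.seed(5); f2 <- fit_ddm_mle(b2)
  expect_equal(f2$params$t0 - f1$params$t0, 0.1, tolerance = 0.03)
  expect_equal(f2$params$v, f1$params$v, tolerance = 0.1)
  expect_equal(f2$params$a, f1$params$a, tolerance = 0.1)
})

test_that("fits are invariant to a common rescaling of sigma, v and a", {
  p1 <- ddm_params(v = 1, a = 1.5, t0 = 0.3, z = 0.5, sigma = 1)
  p2 <- ddm_params(v = 0.1, a = 0.15, t0 = 0.3, z = 0.5, sigma = 0.1)
  b1 <- simulate_ddm(p1, n = 4000, dt = 1e-4, seed = 6)
  b2 <- simulate_ddm(p2, n = 4000, dt = 1e-4, seed = 6)
  expect_equal(mean(b1$choice == "upper"), mean(b2$choice == "upper"),
               tolerance = 0.02)
  expect_equal(mean(b1$rt), mean(b2$rt), tolerance = 0.02)
  # fitting at sigma = 0.1 recovers the scaled-down parameters
  set.seed(6)
  f <- fit_ddm_mle(b2, sigma = 0.1)
  expect_equal(f$params$v / 0.1, 1, tolerance = 0.15)
  expect_equal(f$params$a / 0.1, 1.5, tolerance = 0.15)
})

test_that("estimation error shrinks with sample size", {
  p <- ddm_params(v = 1.0, a = 1.5, t0 = 0.3, z = 0.5)
  err <- vapply(c(100, 1000), function(n) {
    es <- vapply(1:4, function(r) {
      b <- simulate_ddm(p, n = n, dt = 2e-4, seed = 100 * n + r)
      set.seed(100 * n + r)
      f <- fit_ddm_mle(b, n_starts = 3)
      sqrt(mean(c(f$params$v - 1, f$params$a - 1.5, f$params$t0 - 0.3)^2))
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("degenerate and undersized samples are flagged, not refused", {
  b <- data.frame(choice = rep("upper", 60), rt = runif(60, 0.3, 1))
  set.seed(7)
  f <- fit_ddm_mle(b)
  expect_true(f$weak_identification)
  b2 <- data.frame(choice = c("upper", "lower"), rt = c(0.5, 0.6))
  set.seed(7)
  expect_true(fit_ddm_mle(b2, n_starts = 2)$weak_identification)
})

test_that("qq agreement behaves at its fixed points", {
  set.seed(8)
  b <- simulate_ddm(ddm_params(1, 1.5, 0.3), n = 500, dt = 1e-3)
  expect_equal(qq_check(b, b)$r, 1)
  # sign reversal mirrors the percentile table: the reversed sample's
  # p-th percentile is minus the original's (1-p)-th percentile (both
  # percentile vectors stay nondecreasing, so their correlation stays
  # positive; only the table is mirrored)
  flip <- b
  flip$choice <- ifelse(b$choice == "upper", "lower", "upper")
  qq <- qq_check(b, flip)$table
  expect_equal(qq$generated, -rev(qq$actual), tolerance = 1e-10)
  expect_error(qq_check(b[0, ], b), "empty")
})
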