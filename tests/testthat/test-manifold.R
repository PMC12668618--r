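test_that("reward rate is accuracy over reaction time", {
  expect_equal(reward_rate(1.0, 2.0), 0.5)
  expect_equal(reward_rate(0.9, 0.5), 1.8)
  expect_equal(reward_rate(0, 1.3), 0)
  expect_error(reward_rate(0.5, 0), "positive")
})

test_that("cosine distance spans its range and ignores scale", {
  expect_equal(cosine_distance(c(1, 1), c(2, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 1)
  expect_equal(cosine_distance(c(1, 2), c(-1, -2)), 2)
  expect_equal(cosine_distance(c(0.3, -0.7), 100 * c(0.3, -0.7)), 0)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "nonzero")
})

# hand-built manifold object with analytic surfaces
analytic_manifold <- function(f, v = seq(-2, 2, 0.25), a = seq(0.5, 2, 0.1)) {
  acc <- outer(v, a, f)
  structure(list(v = v, a = a, rt = acc, accuracy = acc,
                 reward_rate = acc, t0 = 0.2, z = 0.5, sigma = 1),
            class = "cbgt_manifold")
}

test_that("gradients of analytic surfaces are recovered", {
  m <- analytic_manifold(function(v, a) v)
  g <- gradient_at(m, "accuracy", c(0.3, 1.1), smooth_k = 1)
  expect_equal(g, c(1, 0), tolerance = 1e-8)
  m2 <- analytic_manifold(function(v, a) v^2 + a^2)
  g2 <- gradient_at(m2, "accuracy", c(1, 1), smooth_k = 1)
  expect_equal(g2, c(2, 2), tolerance = 0.05)
  # sign convention: the RT gradient points toward faster responses
  g3 <- gradient_at(analytic_manifold(function(v, a) v), "rt", c(0.3, 1.1),
                    smooth_k = 1)
  expect_equal(g3, c(-1, 0), tolerance = 1e-8)
  expect_error(gradient_at(m, "accuracy", c(10, 1)), "hull")
})

test_that("simulated manifold nodes match closed-form absorption", {
  m <- build_manifold(c(0, 0.8, 1.6), c(0.8, 1.4), t0 = 0.2, seeds = 4,
                      trials = 300, dt = 1e-3, seed = 1)
  for (i in seq_along(m$v)) for (j in seq_along(m$a)) {
    expect_equal(m$accuracy[i, j],
                 ddm_upper_prob(ddm_params(m$v[i], m$a[j], 0.2)),
                 tolerance = 0.06)
  }
  # v = 0 nodes sit at chance
  expect_equal(m$accuracy[1, ], c(0.5, 0.5), tolerance = 0.05)
  # reward-rate surface is exactly accuracy / rt
  expect_equal(m$reward_rate, m$accuracy / m$rt)
  # larger boundary: higher accuracy and slower responses (v > 0 column)
  expect_gte(m$accuracy[3, 2] + 0.03, m$accuracy[3, 1])
  expect_gt(m$rt[3, 2], m$rt[3, 1])
})

test_that("the reward-rate gradient is orthogonal to its contours", {
  m <- build_manifold(seq(0, 2, length.out = 9), seq(0.6, 1.8, length.out = 9),
                      t0 = 0.2, seeds = 4, trials = 250, dt = 1e-3, seed = 2)
  # finite-difference contour tangent at an interior node: direction along
  # which the (smoothed) surface change is minimal
  pt <- c(1.0, 1.2)
  g <- gradient_at(m, "reward_rate", pt)
  tangent <- c(-g[2], g[1])
  s <- cbgtpolicy:::smooth_surface(m$reward_rate, 3)
  interp <- function(p) {
    i <- findInterval(p[1], m$v, all.inside = TRUE)
    j <- findInterval(p[2], m$a, all.inside = TRUE)
    fx <- (p[1] - m$v[i]) / diff(m$v[i:(i + 1)])
    fy <- (p[2] - m$a[j]) / diff(m$a[j:(j + 1)])
    (1 - fx) * (1 - fy) * s[i, j] + fx * (1 - fy) * s[i + 1, j] +
      (1 - fx) * fy * s[i, j + 1] + fx * fy * s[i + 1, j + 1]
  }
  h <- 0.05 * tangent / sqrt(sum(tangent^2))
  along_tangent <- abs(interp(pt + h) - interp(pt - h))
  h2 <- 0.05 * g / sqrt(sum(g^2))
  along_gradient <- abs(interp(pt + h2) - interp(pt - h2))
  expect_lt(along_tangent, 0.35 * along_gradient)
})

test_that("planted gradient-ascent trajectories rank reward rate first", {
  m <- build_manifold(seq(-0.5, 2.5, length.out = 10),
                      seq(0.6, 2.2, length.out = 10),
                      t0 = 0.25, seeds = 4, trials = 250, dt = 1e-3, seed = 3)
  set.seed(4)
  traj <- do.call(rbind, lapply(1:6, function(id) {
    v <- runif(1, 0, 1.2); a <- runif(1, 1, 1.8)
    rows <- data.frame(network = id, stage = 0, v = v, a = a)
    for (st in 1:3) {
      g <- gradient_at(m, "reward_rate", c(v, a))
      stp <- 0.12 * g / sqrt(sum(g^2))
      v <- min(max(v + stp[1], -0.4), 2.4)
      a <- min(max(a + stp[2], 0.65), 2.1)
      rows <- rbind(rows, data.frame(network = id, stage = st, v = v, a = a))
    }
    rows
  }))
  cmp <- compare_objectives(traj, m)
  expect_lt(cmp$means["reward_rate"], 0.1)
  expect_lt(cmp$means["reward_rate"], cmp$means["rt"])
  expect_lt(cmp$means["reward_rate"], cmp$means["accuracy"])
})

test_that("summary tests behave at their degenerate points", {
  # identical distances across objectives -> no condition effect, F = 0
  set.seed(9)
  subj <- rnorm(8, 0.7, 0.2)
  m <- matrix(rep(subj, 3), 8)
  an <- cbgtpolicy:::repeated_measures_anova(m)
  expect_equal(an$F, 0)
  # paired t on a 5-pair hand table matches the closed form
  x <- c(1.2, 0.9, 1.5, 1.1, 1.3); y <- c(1.0, 0.8, 1.1, 1.2, 0.9)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(unname(tt$statistic), t_hand)
  expect_equal(unname(tt$parameter), 4)
})
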