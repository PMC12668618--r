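test_that("principal components of planted changes behave as expected", {
  # rank-1 matrix: first PC explains everything
  set.seed(1)
  delta <- outer(rnorm(40), rnorm(16))
  pc <- pca_delta(delta, k = 3)
  expect_equal(pc$var_frac[1], 1, tolerance = 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(pc$V), diag(3), ignore_attr = TRUE,
               tolerance = 1e-10)
  # planted 5-factor structure: 5 PCs explain at least 90%
  L <- qr.Q(qr(matrix(rnorm(16 * 5), 16)))
  delta5 <- matrix(rnorm(200 * 5), 200) %*% t(L) +
    matrix(rnorm(200 * 16, sd = 0.15), 200)
  pc5 <- pca_delta(delta5, k = 5)
  expect_gt(sum(pc5$var_frac), 0.9)
  expect_error(pca_delta(delta5[1:4, ], k = 5))
})

test_that("projections are the stated linear maps", {
  dr <- gen_driver_cohort(n_networks = 50, seed = 2)
  pr <- project_delta(dr$delta, dr$V, dr$U)
  expect_equal(pr$P, dr$delta %*% dr$V)
  expect_equal(pr$C, dr$delta %*% dr$U)
  # zero input, zero projections
  z <- project_delta(matrix(0, 5, 16), dr$V, dr$U)
  expect_true(all(z$P == 0) && all(z$C == 0))
  # delta equal to one ensemble loading row-replicated: single nonzero C col
  d1 <- matrix(rep(dr$U[, 2], 6), 6, byrow = TRUE)
  C1 <- project_delta(d1, dr$V, dr$U)$C
  expect_equal(C1[, 2], rep(1, 6), tolerance = 1e-10)
  expect_equal(C1[, c(1, 3)], matrix(0, 6, 2), tolerance = 1e-10)
})

test_that("the normal equation recovers exact and orthonormal cases", {
  set.seed(3)
  C <- matrix(rnorm(60), 20, 3)
  S0 <- matrix(rnorm(15), 3, 5)
  S <- solve_drivers(C %*% S0, C)
  expect_equal(S, S0, ignore_attr = TRUE, tolerance = 1e-10)
  # orthonormal columns: S = C'P
  Co <- qr.Q(qr(C))
  P <- Co %*% S0
  expect_equal(solve_drivers(P, Co), crossprod(Co, P), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("least-squares optimality beats every perturbed solution", {
  set.seed(4)
  C <- matrix(rnorm(90), 30, 3)
  P <- C %*% matrix(rnorm(15), 3, 5) + matrix(rnorm(150, sd = 0.3), 30, 5)
  S <- solve_drivers(P, C)
  r0 <- sum((P - C %*% S)^2)
  for (i in 1:100) {
    Sp <- S + matrix(rnorm(15, sd = 0.05), 3, 5)
    expect_gte(sum((P - C %*% Sp)^2), r0)
  }
})

test_that("ill-conditioned gram matrices fall back to the pseudo-inverse", {
  C <- cbind(1:10, 2 * (1:10), rnorm(10))
  P <- matrix(rnorm(50), 10, 5)
  expect_warning(S <- solve_drivers(P, C), "ill-conditioned")
  expect_true(attr(S, "pseudo_inverse"))
  # the fallback is still a least-squares solution
  expect_equal(C %*% S, C %*% (MASS::ginv(C) %*% P), tolerance = 1e-6)
})

test_that("variance weighting combines driver columns linearly", {
  S <- matrix(1:15, 3, 5)
  expect_equal(weighted_driver(S[, 1, drop = FALSE], 1), S[, 1])
  expect_equal(weighted_driver(matrix(0, 3, 5), rep(0.2, 5)), rep(0, 3))
  S2 <- cbind(S[, 1], S[, 1], matrix(0, 3, 3))
  expect_equal(weighted_driver(S2, c(0.6, 0.3, 0, 0, 0)), 0.9 * S[, 1])
})

test_that("the projection pipeline is linear and noise-robust", {
  dr <- gen_driver_cohort(n_networks = 120, seed = 5)
  pr <- project_delta(dr$delta, dr$V, dr$U)
  S <- solve_drivers(pr$P, pr$C)
  expect_equal(S, dr$S0, ignore_attr = TRUE, tolerance = 1e-10)
  # scaling delta scales P and C together and leaves S unchanged
  pr2 <- project_delta(3 * dr$delta, dr$V, dr$U)
  expect_equal(pr2$P, 3 * pr$P)
  expect_equal(solve_drivers(pr2$P, pr2$C), S, ignore_attr = TRUE,
               tolerance = 1e-10)
  # estimator error decreases with cohort size under noise
  rmse_at <- function(n) {
    mean(vapply(1:5, function(r) {
      d <- gen_driver_cohort(n_networks = n, S0 = dr$S0, U = dr$U,
                             noise = 0.5, seed = 100 * n + r)
      p <- project_delta(d$delta, d$V, d$U)
      sqrt(mean((solve_drivers(p$P, p$C) - dr$S0)^2))
    }, numeric(1)))
  }
  expect_lt(rmse_at(300), rmse_at(30))
})

test_that("reconstruction quality is reported as a rank correlation", {
  dr <- gen_driver_cohort(n_networks = 80, noise = 0.2, seed = 6)
  res <- ensemble_drivers(dr$delta,
                          structure(list(u = dr$U, scale_F = rep(1, 16),
                                         labels = c("responsiveness",
                                                    "pliancy", "choice")),
                                    class = "cbgt_ensembles"), k = 5)
  expect_length(res$reconstruction_rho, 5)
  # leading PCs carry the planted structure and reconstruct well; trailing
  # PCs are noise-dominated and need not
  expect_true(all(res$reconstruction_rho[1:3] > 0.5))
  expect_named(res$weighted, c("responsiveness", "pliancy", "choice"))
})

test_that("outcome-sequence drivers recover planted sign reversals", {
  set.seed(7)
  U <- qr.Q(qr(matrix(rnorm(16 * 3), 16)))
  ens <- structure(list(u = U, scale_F = rep(1, 16),
                        labels = c("responsiveness", "pliancy", "choice")),
                   class = "cbgt_ensembles")
  n_per <- 20
  base <- matrix(rnorm(16), 1)[rep(1, n_per), ] * 0
  mk_group <- function(sign) {
    sign * matrix(rep(U[, 1] * 2 + U[, 2], n_per), n_per, byrow = TRUE) +
      matrix(rnorm(n_per * 16, sd = 0.05), n_per)
  }
  delta <- rbind(mk_group(+1), mk_group(-1))
  seqs <- rep(c("R-R", "U-U"), each = n_per)
  rr <- c(rnorm(n_per, 1, 0.1), rnorm(n_per, 0.1, 0.1))
  res <- sequence_drivers(delta, seqs, rr, ens, k = 5)
  expect_true(all(res$drivers[["R-R"]][1:2] * res$drivers[["U-U"]][1:2] < 0))
  # reward-rate change differs between groups
  expect_lt(res$pairwise_t[["U-U vs R-R"]]$p_value, 1e-6)
  # degenerate grouping: single-member groups flagged, not fitted
  res2 <- sequence_drivers(delta, rep(c("R-R", "U-R"), c(39, 1)), rr, ens,
                           k = 5)
  expect_true("U-R" %in% res2$flagged)
  # identical reward-rate changes across groups: no effect to test
  res3 <- sequence_drivers(delta, seqs, rep(0.5, 40), ens, k = 5)
  expect_null(res3$anova)
  expect_length(res3$pairwise_t, 0)
})
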