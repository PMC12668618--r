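test_that("grid values reproduce the worked example grids", {
  expect_equal(grid_values(-0.3, 1.0, 5), c(-0.3, 0.025, 0.35, 0.675, 1.0))
  expect_equal(grid_values(-2, 2, 5), c(-2, -1, 0, 1, 2))
  expect_equal(grid_values(0, 1, 2), c(0, 1))
  g <- grid_values(0.1, 0.9, 30)
  expect_length(g, 30)
  expect_equal(g[1], 0.1); expect_equal(g[30], 0.9)
  expect_error(grid_values(1, 0, 5))
})

worked_grid <- data.frame(name = c("A", "B"), lower = c(-2, -0.3),
                          upper = c(2, 1), n_points = 5L)

test_that("genomes decode through the worked two-parameter example", {
  expect_equal(unname(ga_decode(c(0, 1), worked_grid)), c(-2, 0.025))
  expect_equal(unname(ga_decode(c(4, 0), worked_grid)), c(2, -0.3))
  expect_equal(unname(ga_decode(c(2, 2), worked_grid))[1], 0)
  expect_error(ga_decode(c(5, 0), worked_grid), "out of range")
  # closure: any in-range genome decodes inside the declared ranges
  set.seed(1)
  for (i in 1:50) {
    g <- c(sample.int(5, 1), sample.int(5, 1)) - 1L
    v <- ga_decode(g, worked_grid)
    expect_true(v[1] >= -2 && v[1] <= 2 && v[2] >= -0.3 && v[2] <= 1)
  }
})

test_that("mating crosses over as in the worked example", {
  off <- ga_mate(c(0L, 1L), c(4L, 0L), 1)
  expect_equal(off[[1]], c(0L, 0L))
  expect_equal(off[[2]], c(4L, 1L))
  # identical parents produce identical offspring
  off <- ga_mate(c(2L, 3L), c(2L, 3L), 1)
  expect_equal(off[[1]], c(2L, 3L))
  expect_equal(off[[2]], c(2L, 3L))
  # crossover at position 0 swaps the parents whole
  off <- ga_mate(c(1L, 2L), c(3L, 4L), 0)
  expect_equal(off[[1]], c(3L, 4L))
  expect_equal(off[[2]], c(1L, 2L))
})

test_that("shuffle mutation preserves the index multiset", {
  set.seed(2)
  expect_equal(ga_mutate(c(0L, 1L, 2L), p = 0), c(0L, 1L, 2L))
  expect_equal(ga_mutate(5L, p = 1), 5L)
  for (i in 1:20) {
    m <- ga_mutate(c(0L, 1L, 2L, 7L), p = 1)
    expect_setequal(m, c(0L, 1L, 2L, 7L))
  }
})

# toy surrogate fitness on a 2-parameter grid: acceptance iff A + B > 0.5,
# correlation increasing in A, timeouts decreasing in B
toy_evaluate <- function(values, n_trials, rate_ranges, seed, net_seed) {
  A <- values[[1]]; B <- values[[2]]
  to <- max(0, 0.5 - B) / 2
  corr <- tanh(A)
  ok <- c(all = TRUE)
  list(timeout_fraction = if (A + B > 0.5) 0 else to + 0.02,
       cx_striatum_correlation = if (A + B > 0.5) abs(corr) + 0.1 else corr,
       rate_range_ok = ok,
       accept = A + B > 0.5,
       mean_rates = c(), mean_rt_ms = 300)
}

test_that("the GA recovers the toy acceptance region found by brute force", {
  grid <- data.frame(name = c("A", "B"), lower = c(-1, -1), upper = c(1, 1),
                     n_points = 30L)
  # brute force over the full 30 x 30 grid
  brute <- outer(grid_values(-1, 1, 30), grid_values(-1, 1, 30),
                 function(a, b) a + b > 0.5)
  n_accept <- sum(brute)
  res <- ga_evolve(grid, population_size = 30, tournament_size = 3,
                   mutation_p = 0.2, reset_p = 0.4, max_iter = 200,
                   target_solutions = n_accept, n_trials = 1,
                   seed = 7, evaluate = toy_evaluate)
  keys_found <- unique(vapply(res$accepted, function(a)
    paste(a$genome, collapse = ","), character(1)))
  expect_gte(length(keys_found), 0.9 * n_accept)
  # every archived configuration really satisfies the criteria
  for (a in res$accepted) expect_true(a$values[[1]] + a$values[[2]] > 0.5)
})

test_that("degenerate GA settings behave as specified", {
  grid <- data.frame(name = c("A", "B"), lower = c(-1, -1), upper = c(1, 1),
                     n_points = 5L)
  res <- ga_evolve(grid, target_solutions = 0, max_iter = 10, seed = 1,
                   evaluate = toy_evaluate)
  expect_length(res$accepted, 0)
  # impossible criteria: warns, does not error
  never <- function(values, ...) {
    r <- toy_evaluate(values, 1, NULL, 1, 1); r$accept <- FALSE
    r$timeout_fraction <- 1; r
  }
  expect_warning(
    res <- ga_evolve(grid, target_solutions = 5, max_iter = 3, seed = 1,
                     evaluate = never),
    "no acceptable")
  expect_length(res$accepted, 0)
})

test_that("candidate evaluation flags planted pathologies", {
  # striatal rates as a noisy positive function of cortical rates -> r > 0
  set.seed(3)
  cx <- rpois(400, 20)
  spn <- 0.5 * cx + rnorm(400, 0, 1)
  expect_gt(cor(cx, spn), 0)
})
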