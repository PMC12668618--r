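#' @title Synthetic surrogate cohorts
#' @name synthetic_data
#' @description
#' Seed-deterministic generators that emulate the statistical structure of
#' the simulated network cohorts without any spiking simulation: latent
#' factors shared between firing-rate features and DDM parameters (for CCA
#' recovery tests), firing-rate-change matrices built from a known driver
#' matrix (for least-squares recovery tests), behavior samples from known
#' DDM parameters (for fitter recovery), and minimal biased/unbiased network
#' parameterizations (for deterministic-choice tests).
NULL

#' Generate a feature/policy cohort with planted latent factors
#'
#' `k` latent factors load onto the 16 firing-rate features (`loadings_F`)
#' and the 3 DDM parameters (`loadings_D`); independent Gaussian noise is
#' added to both sides, so the planted canonical correlations are controlled
#' by the signal-to-noise ratio `factor_scale / noise`.
#'
#' @param n_networks rows. @param k latent factors (<= 3).
#' @param loadings_F 16 x k (unit-norm columns; random if `NULL`).
#' @param loadings_D 3 x k (unit-norm columns; random if `NULL`).
#' @param factor_scale latent factor SDs (recycled to length `k`); distinct
#'   values keep the factors identifiable up to sign rather than up to a
#'   rotation of the shared subspace. @param noise noise SD.
#' @param seed RNG seed.
#' @return list: `F` (n x 16), `D` (n x 3, columns a/t/v), and the planted
#'   `loadings_F`, `loadings_D`, `scores`.
#' @export
gen_cca_cohort <- function(n_networks = 300, k = 3, loadings_F = NULL,
                           loadings_D = NULL, factor_scale = c(2, 1, 0.5),
                           noise = 0.2, seed = 1L) {
  stopifnot(k >= 1, k <= 3)
  factor_scale <- rep_len(factor_scale, k)
  set.seed(seed)
  # orthonormal planted loadings keep each factor's direction identifiable
  unitcols <- function(m) apply(m, 2, function(x) x / sqrt(sum(x^2)))
  if (is.null(loadings_F)) loadings_F <- qr.Q(qr(matrix(rnorm(16 * k), 16)))
  else loadings_F <- unitcols(loadings_F)
  if (is.null(loadings_D)) loadings_D <- qr.Q(qr(matrix(rnorm(3 * k), 3)))
  else loadings_D <- unitcols(loadings_D)
  scores <- matrix(rnorm(n_networks * k), n_networks) %*% diag(factor_scale, k)
  Fm <- scores %*% t(loadings_F) +
    matrix(rnorm(n_networks * 16, sd = noise), n_networks)
  Dm <- scores %*% t(loadings_D) +
    matrix(rnorm(n_networks * 3, sd = noise), n_networks)
  colnames(Fm) <- feature_names()
  colnames(Dm) <- c("a", "t", "v")
  list(F = Fm, D = Dm, loadings_F = loadings_F, loadings_D = loadings_D,
       scores = scores)
}

#' Generate firing-rate-change rows from a known driver matrix
#'
#' Latent ensemble scores `C0` (n x 3) generate
#' `delta = C0 (U'  +  S0 V_extra')`-structured data: the component of
#' `delta` inside the ensemble subspace reproduces `C0` and its projection
#' onto the PC directions reproduces `C0 S0`, so the projection +
#' normal-equation pipeline recovers `S0` exactly in the noiseless case.
#'
#' @param n_networks rows. @param U 16 x 3 orthonormal ensemble loadings
#'   (random if `NULL`). @param S0 3 x 5 true driver matrix (random if
#'   `NULL`). @param score_scale SD of the latent ensemble scores.
#' @param noise SD of feature noise added outside the construction.
#' @param seed RNG seed.
#' @return list: `delta` (n x 16), `U`, `S0`, `V` (16 x 5 PC-like basis),
#'   `C0`.
#' @export
gen_driver_cohort <- function(n_networks = 200, U = NULL, S0 = NULL,
                              score_scale = 1, noise = 0, seed = 1L) {
  set.seed(seed)
  # orthonormal 16 x 8 frame: first 3 columns span U, next 5 give the V
  # basis (orthogonalized against U even when U is supplied)
  if (is.null(U)) U <- qr.Q(qr(matrix(rnorm(16 * 3), 16)))
  else stopifnot(all(dim(U) == c(16, 3)))
  M <- matrix(rnorm(16 * 5), 16)
  M <- M - U %*% crossprod(U, M)
  Vb <- qr.Q(qr(M))[, 1:5]
  if (is.null(S0)) S0 <- matrix(rnorm(15), 3, 5)
  C0 <- matrix(rnorm(n_networks * 3, sd = score_scale), n_networks)
  delta <- C0 %*% t(U) + (C0 %*% S0) %*% t(Vb)
  if (noise > 0)
    delta <- delta + matrix(rnorm(length(delta), sd = noise), n_networks)
  colnames(delta) <- feature_names()
  list(delta = delta, U = U, S0 = S0, V = Vb, C0 = C0)
}

#' Generate behavior samples from a table of known DDM parameters
#'
#' @param param_table data.frame with columns `v`, `a`, `t0`, `z` (and
#'   optionally `sigma`), one row per synthetic network.
#' @param n_trials trials per network. @param dt simulation step (s).
#' @param seed master seed (per-row sub-seeds are derived from it).
#' @return list of behavior data.frames (one per row).
#' @export
gen_ddm_cohort <- function(param_table, n_trials = 500, dt = 1e-4,
                           seed = 1L) {
  stopifnot(all(c("v", "a", "t0", "z") %in% names(param_table)))
  lapply(seq_len(nrow(param_table)), function(i) {
    p <- param_table[i, ]
    sig <- if ("sigma" %in% names(p)) p$sigma else 1
    simulate_ddm(ddm_params(p$v, p$a, p$t0, p$z, sig), n = n_trials,
                 dt = dt, seed = derive_seed(seed, paste0("ddm", i)))
  })
}

#' Minimal toy network, optionally biased toward channel 1
#'
#' A default-sized symmetric parameterization whose channel-1 corticostriatal
#' dSPN efficacy is multiplied by `bias`; `bias = 1` keeps the network
#' channel-symmetric. Biasing one channel's direct pathway makes choices
#' deterministic enough for majority-vote tests.
#'
#' @param bias multiplier (> 0) on the channel-1 Cx->dSPN weights.
#' @param seed connectivity seed.
#' @return a built `cbgt_network`.
#' @export
gen_toy_network <- function(bias = 1, seed = 1L) {
  stopifnot(bias > 0)
  net <- build_network(network_params(seed = seed))
  if (bias != 1) {
    for (i in seq_along(net$projections)) {
      p <- net$projections[[i]]
      if (p$plastic && p$target_type == 1L && identical(p$channel, 1L))
        net$projections[[i]]$W <- p$W * bias
    }
  }
  net
}
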