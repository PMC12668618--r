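#' @title Drift-diffusion model: simulation, likelihood, and fitting
#' @name ddm_engine
#' @description
#' Evidence `x(t)` starts at `z * a`, drifts at rate `v` with diffusion scale
#' `sigma`, and is absorbed at the boundaries `0` (lower) and `a` (upper);
#' the reaction time is the first-passage time plus the non-decision time
#' `t0`. Network decision times (ms) are converted to seconds at this module
#' boundary, and accuracy coding puts the rewarded channel at the upper
#' boundary. Fitting maximizes the exact first-passage-time likelihood
#' (small/large-time series) per network; `sigma` is fixed at 1 and `z` at
#' 0.5 unless bias fitting is enabled.
NULL

#' DDM parameter set
#'
#' @param v drift rate (evidence/s). @param a boundary separation.
#' @param t0 non-decision time (s). @param z starting fraction in (0,1).
#' @param sigma diffusion scale (fixed during fitting).
#' @export
ddm_params <- function(v, a, t0 = 0.25, z = 0.5, sigma = 1) {
  stopifnot(a > 0, t0 >= 0, z > 0, z < 1, sigma > 0)
  structure(list(v = v, a = a, t0 = t0, z = z, sigma = sigma),
            class = "cbgt_ddm_params")
}

#' Simulate choices and reaction times from a DDM
#'
#' Euler-Maruyama integration of `dx = v dt + sigma dW` from `x(0) = z*a`.
#' @param params [ddm_params()]. @param n number of trials.
#' @param dt integration step (s). @param seed optional seed.
#' @param max_t censoring time (s).
#' @return data.frame with `choice` (`"upper"`/`"lower"`) and `rt` (s);
#'   censored paths are dropped.
#' @export
simulate_ddm <- function(params, n, dt = 1e-4, seed = NULL, max_t = 20) {
  stopifnot(inherits(params, "cbgt_ddm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- simulate_ddm_cpp(n, params$v, params$a, params$t0, params$z,
                        params$sigma, dt, max_t)
  keep <- !is.na(r$choice)
  data.frame(choice = ifelse(r$choice[keep] == 1L, "upper", "lower"),
             rt = r$rt[keep], stringsAsFactors = FALSE)
}

#' Closed-form upper-boundary absorption probability
#'
#' `(1 - exp(-2 v z a / sigma^2)) / (1 - exp(-2 v a / sigma^2))`, with the
#' symmetric limit `z` as `v -> 0`.
#' @param params [ddm_params()].
#' @export
ddm_upper_prob <- function(params) {
  with(params, {
    if (abs(v) < 1e-12) return(z)
    k <- 2 * v / sigma^2
    (1 - exp(-k * z * a)) / (1 - exp(-k * a))
  })
}

#' First-passage-time density at one boundary
#'
#' Exact series density of absorption at `rt` (seconds, including the
#' non-decision time) at the given boundary; `rt <= t0` has density zero.
#' The density of each boundary integrates over time to that boundary's
#' absorption probability.
#' @param params [ddm_params()]. @param rt vector of reaction times (s).
#' @param boundary `"upper"` or `"lower"`. @param err series truncation error.
#' @export
fpt_density <- function(params, rt, boundary = c("upper", "lower"),
                        err = 1e-10) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "cbgt_ddm_params"))
  t_dec <- rt - params$t0
  # scale to unit diffusion
  v <- params$v / params$sigma
  a <- params$a / params$sigma
  if (boundary == "lower") wfpt_lower_cpp(t_dec, v, a, params$z, err)
  else wfpt_lower_cpp(t_dec, -v, a, 1 - params$z, err)
}

ddm_negloglik <- function(v, a, t0, rt, is_upper, z, sigma) {
  p <- ddm_params(v, a, t0, z, sigma)
  d <- numeric(length(rt))
  d[is_upper] <- fpt_density(p, rt[is_upper], "upper")
  d[!is_upper] <- fpt_density(p, rt[!is_upper], "lower")
  -sum(log(pmax(d, 1e-290)))
}

#' Maximum-likelihood DDM fit to one behavioral sample
#'
#' Fits `(v, a, t0)` by maximizing the summed log first-passage density over
#' trials. The onset time is profiled over a grid of candidate values below
#' the minimum observed RT, with `(v, a)` optimized at each candidate
#' (log-transformed `a` keeps it positive) and a final joint polish around
#' the best profile point; profiling avoids the flat, multimodal `t0`
#' direction that defeats joint 3-parameter simplex searches on short-RT
#' samples. Samples with fewer than `min_trials` trials or with only one
#' observed choice are flagged as weakly identified (the fit still runs).
#'
#' @param sample data.frame with columns `choice` (`"upper"`/`"lower"`) and
#'   `rt` (seconds), e.g. from [simulate_ddm()] or [behavior_from_session()].
#' @param z starting fraction (fixed; default 0.5). @param sigma diffusion
#'   scale (fixed; default 1). @param n_starts extra jittered `(v, a)`
#'   starts per onset candidate.
#' @param t0_grid number of onset-time candidates.
#' @param min_trials identification threshold.
#' @return a list: `params` ([ddm_params()]), `loglik`, `n_trials`,
#'   `converged`, `weak_identification`.
#' @export
fit_ddm_mle <- function(sample, z = 0.5, sigma = 1, n_starts = 2,
                        t0_grid = 12, min_trials = 50) {
  stopifnot(all(c("choice", "rt") %in% names(sample)))
  sample <- sample[is.finite(sample$rt) & sample$rt > 0, ]
  n <- nrow(sample)
  if (n == 0) stop("no usable trials")
  upper <- sample$choice == "upper"
  weak <- n < min_trials || length(unique(sample$choice)) < 2
  min_rt <- min(sample$rt)
  p_up <- max(min(mean(upper), 1 - 1e-3), 1e-3)
  v0 <- sigma * log(p_up / (1 - p_up))
  a0 <- max(0.5 * sigma, sigma * sqrt(max(mean(sample$rt) - min_rt, 0.05)))
  fit_va <- function(t0, start) {
    tryCatch(
      optim(start, function(th)
        ddm_negloglik(th[1], exp(th[2]), t0, sample$rt, upper, z, sigma),
        method = "Nelder-Mead",
        control = list(maxit = 1000, reltol = 1e-9)),
      error = function(e) NULL)
  }
  t0s <- min_rt * seq(0.02, 0.98, length.out = t0_grid)
  best <- NULL; best_t0 <- t0s[1]
  for (t0 in t0s) {
    starts <- list(c(v0, log(a0)))
    if (n_starts > 1)
      for (s in seq_len(n_starts - 1))
        starts[[s + 1]] <- c(v0, log(a0)) + rnorm(2, 0, c(0.7, 0.4))
    for (st in starts) {
      fit <- fit_va(t0, st)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit; best_t0 <- t0
      }
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  # joint polish with t0 on a logit scale bounded by the minimum RT
  th0 <- c(best$par, stats::qlogis(min(best_t0 / min_rt, 0.995)))
  polish <- tryCatch(
    optim(th0, function(th)
      ddm_negloglik(th[1], exp(th[2]),
                    min_rt * stats::plogis(th[3]),
                    sample$rt, upper, z, sigma),
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) {
    th <- polish$par
    out_par <- ddm_params(th[1], exp(th[2]), min_rt * stats::plogis(th[3]),
                          z, sigma)
    val <- polish$value; conv <- polish$convergence == 0
  } else {
    out_par <- ddm_params(best$par[1], exp(best$par[2]), best_t0, z, sigma)
    val <- best$value; conv <- best$convergence == 0
  }
  list(params = out_par, loglik = -val, n_trials = n,
       converged = conv, weak_identification = weak)
}

#' Convert probe trials of a session stage to a DDM behavior sample
#'
#' Accuracy coding: the rewarded channel maps to the upper boundary; decision
#' times are converted from ms to s; timeouts are dropped.
#' @param session a `cbgt_session`. @param stage stage id (0 = baseline).
#' @export
behavior_from_session <- function(session, stage) {
  tr <- session$trials
  tr <- tr[tr$phase == "probe" & tr$stage == stage & !tr$timeout, ]
  if (!nrow(tr)) stop("all probe trials timed out at stage ", stage,
                      ": fit-infeasible")
  data.frame(choice = ifelse(tr$choice == session$config$rewarded_channel,
                             "upper", "lower"),
             rt = tr$decision_time_ms / 1000, stringsAsFactors = FALSE)
}

#' Quantile-quantile agreement between two behavior samples
#'
#' Compares choice-signed RT percentiles (5, 10, ..., 95; upper-boundary RTs
#' positive, lower-boundary negative) between an observed and a generated
#' sample, as a posterior-predictive goodness-of-fit check.
#' @param actual,generated behavior data.frames (`choice`, `rt`).
#' @return list with `r` (Pearson correlation of the percentile vectors),
#'   `p_value`, and the percentile table.
#' @export
qq_check <- function(actual, generated) {
  signed <- function(d) ifelse(d$choice == "upper", d$rt, -d$rt)
  if (!nrow(actual) || !nrow(generated)) stop("empty behavior sample")
  probs <- seq(0.05, 0.95, by = 0.05)
  qa <- quantile(signed(actual), probs, names = FALSE)
  qg <- quantile(signed(generated), probs, names = FALSE)
  ct <- cor.test(qa, qg)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       table = data.frame(percentile = probs * 100, actual = qa,
                          generated = qg))
}
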