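#' @title Dopamine-dependent corticostriatal plasticity
#' @name plasticity
#' @description
#' Each corticostriatal AMPA synapse tracks pre-/post-synaptic spike traces
#' (`A_PRE`, `A_POST`), an eligibility variable `E` built from their pairings,
#' a weight `w` bounded in `[w_min, w_max]`, and a conductance `g` that jumps
#' by `w` at each presynaptic spike. After each rewarded or unrewarded
#' decision, the reward prediction error "reward minus expected reward" sets a phasic dopamine
#' increment; the available dopamine `K_DA` then gates weight change through a
#' piecewise-linear modulation factor `f(K_DA)` whose sign convention
#' strengthens eligible direct-pathway (dSPN) synapses and weakens eligible
#' indirect-pathway (iSPN) synapses under positive feedback. The weight update
#' is multiplicative (soft-bounded), so weights slow down near their limits
#' and never leave them.
#'
#' All numerical constants of the rule are configurable, with defaults
#' chosen so that learning in the default network saturates within roughly
#' 15 trials.
NULL

#' Plasticity constants
#'
#' @param tau_pre,tau_post decay (ms) of the pre-/post-synaptic spike traces.
#' @param d_pre,d_post trace increments (a spike adds `d/tau` to its trace).
#' @param tau_e eligibility decay (ms).
#' @param tau_da dopamine decay (ms).
#' @param c_scale fraction by which a feedback event moves `K_DA` toward the
#'   dopamine increment.
#' @param gamma,mu,eps positive constants of the dopamine modulation factor
#'   `f(K_DA)` (slope `gamma/mu`, saturation `gamma`, indirect-pathway scale
#'   `eps`).
#' @param alpha_dspn,alpha_ispn signed learning rates (1/ms); positive for
#'   dSPN targets and negative for iSPN targets.
#' @param wmin_dspn,wmax_dspn,wmin_ispn,wmax_ispn weight bounds (efficacy
#'   units).
#' @param alpha_q action-value learning rate in `[0,1]`.
#' @param feedback_ms post-decision window (ms) during which the phasic
#'   dopamine signal acts on eligible synapses.
#' @param iti_ms inter-trial interval (ms) over which `K_DA` decays between
#'   trials.
#' @export
plasticity_params <- function(tau_pre = 20, tau_post = 20,
                              d_pre = 15, d_post = 5,
                              tau_e = 150, tau_da = 200, c_scale = 1,
                              gamma = 1, mu = 1, eps = 0.5,
                              alpha_dspn = 0.2, alpha_ispn = -0.2,
                              wmin_dspn = 0, wmax_dspn = 0.08,
                              wmin_ispn = 0, wmax_ispn = 0.08,
                              alpha_q = 0.2, feedback_ms = 300,
                              iti_ms = 600) {
  stopifnot(tau_pre > 0, tau_post > 0, tau_e > 0, tau_da > 0,
            gamma > 0, mu > 0, eps > 0,
            alpha_dspn >= 0, alpha_ispn <= 0,
            wmax_dspn > wmin_dspn, wmax_ispn > wmin_ispn,
            alpha_q >= 0, alpha_q <= 1)
  p <- list(tau_pre = tau_pre, tau_post = tau_post, d_pre = d_pre,
            d_post = d_post, tau_e = tau_e, tau_da = tau_da,
            c_scale = c_scale, gamma = gamma, mu = mu, eps = eps,
            alpha_dspn = alpha_dspn, alpha_ispn = alpha_ispn,
            wmin_dspn = wmin_dspn, wmax_dspn = wmax_dspn,
            wmin_ispn = wmin_ispn, wmax_ispn = wmax_ispn,
            alpha_q = alpha_q, feedback_ms = feedback_ms, iti_ms = iti_ms)
  class(p) <- "cbgt_plasticity_params"
  p
}

#' Dopamine/value state carried across learning trials
#'
#' @param plast a `cbgt_plasticity_params` object.
#' @param rewarded_channel which channel (1 or 2) the task rewards.
#' @param p_opt,p_sub reward probabilities for the optimal / suboptimal
#'   choice.
#' @param K_da,Q initial dopamine level and action values (default 0.5: an
#'   uninformed prior midway between the possible rewards, so both early
#'   successes and early failures generate prediction errors).
#' @export
plasticity_state <- function(plast = plasticity_params(),
                             rewarded_channel = 1L,
                             p_opt = 1, p_sub = 0,
                             K_da = 0, Q = c(0.5, 0.5)) {
  stopifnot(inherits(plast, "cbgt_plasticity_params"),
            rewarded_channel %in% 1:2,
            p_opt >= 0, p_opt <= 1, p_sub >= 0, p_sub <= 1)
  s <- list(plast = unclass(plast), K_da = K_da, Q = Q,
            alpha_q = plast$alpha_q,
            rewarded_channel = as.integer(rewarded_channel),
            p_opt = p_opt, p_sub = p_sub,
            feedback_ms = plast$feedback_ms)
  class(s) <- "cbgt_plasticity_state"
  s
}

# ---------------------------------------------------------------------------
# Reference (pure-R) implementations of the per-step plasticity operators.
# The session simulator applies the identical equations in compiled code;
# these exported forms define the semantics and are cross-checked in tests.
# Operator ordering within a step: traces -> eligibility -> conductance ->
# weight. Delta-function terms are discrete jumps at spike times.
# ---------------------------------------------------------------------------

#' Synapse-local plasticity state
#'
#' @param A_pre,A_post spike-trace amplitudes. @param E eligibility.
#' @param w synaptic weight. @param g conductance.
#' @export
synapse_state <- function(A_pre = 0, A_post = 0, E = 0, w = 0.02, g = 0) {
  stopifnot(A_pre >= 0, A_post >= 0, g >= 0)
  structure(list(A_pre = A_pre, A_post = A_post, E = E, w = w, g = g),
            class = "cbgt_synapse_state")
}

#' Advance the pre-/post-synaptic spike traces by one step
#'
#' Traces decay exponentially and jump by `d/tau` on their own spike.
#' @param state a [synapse_state()]. @param pre_spike,post_spike logical.
#' @param dt step (ms). @param plast constants from [plasticity_params()].
#' @export
update_traces <- function(state, pre_spike, post_spike, dt,
                          plast = plasticity_params()) {
  stopifnot(dt > 0)
  state$A_pre <- state$A_pre * exp(-dt / plast$tau_pre) +
    if (pre_spike) plast$d_pre / plast$tau_pre else 0
  state$A_post <- state$A_post * exp(-dt / plast$tau_post) +
    if (post_spike) plast$d_post / plast$tau_post else 0
  state
}

#' Advance the eligibility trace by one step
#'
#' `dE/dt = (X_post * A_pre - X_pre * A_post - E)/tau_e`: a postsynaptic
#' spike arriving while the presynaptic trace is elevated pushes eligibility
#' up (post-after-pre), a presynaptic spike while the postsynaptic trace is
#' elevated pushes it down.
#' @inheritParams update_traces
#' @export
update_eligibility <- function(state, pre_spike, post_spike, dt,
                               plast = plasticity_params()) {
  stopifnot(dt > 0)
  state$E <- state$E * exp(-dt / plast$tau_e) +
    (if (post_spike) state$A_pre / plast$tau_e else 0) -
    (if (pre_spike) state$A_post / plast$tau_e else 0)
  state
}

#' Advance the synaptic conductance by one step
#'
#' The conductance decays with the AMPA time constant and jumps by the
#' current weight at each presynaptic spike.
#' @inheritParams update_traces
#' @param tau_ampa AMPA decay (ms).
#' @export
conductance_step <- function(state, pre_spike, dt, tau_ampa = 2) {
  stopifnot(dt > 0)
  state$g <- state$g * exp(-dt / tau_ampa) + if (pre_spike) state$w else 0
  state
}

#' Dopamine modulation factor
#'
#' Piecewise-linear gain translating available dopamine into the sign and
#' magnitude of plasticity: for dSPN targets, `-gamma` below `-mu` and
#' `(gamma/mu) * K_da` above; for iSPN targets, `eps*(gamma/mu)*K_da` below
#' `mu` saturating at `eps*gamma` above. Continuous at the break points.
#' @param K_da available dopamine. @param target `"dSPN"` or `"iSPN"`.
#' @param gamma,mu,eps positive constants.
#' @export
f_kda <- function(K_da, target = c("dSPN", "iSPN"),
                  gamma = 1, mu = 1, eps = 0.5) {
  target <- match.arg(target)
  stopifnot(gamma > 0, mu > 0, eps > 0)
  if (target == "dSPN") {
    ifelse(K_da < -mu, -gamma, (gamma / mu) * K_da)
  } else {
    ifelse(K_da < mu, eps * (gamma / mu) * K_da, eps * gamma)
  }
}

#' Soft-bounded weight update over one step
#'
#' `dw/dt = [alpha * E * f(K_da) * (wmax - w)]_+ + [alpha * E * f(K_da) *
#' (w - wmin)]_-`, integrated with an Euler step and clamped to the bounds.
#' @param state a [synapse_state()]. @param K_da available dopamine.
#' @param target `"dSPN"` or `"iSPN"`. @param dt step (ms).
#' @param plast constants from [plasticity_params()].
#' @export
update_weight <- function(state, K_da, target = c("dSPN", "iSPN"), dt,
                          plast = plasticity_params()) {
  target <- match.arg(target)
  alpha <- if (target == "dSPN") plast$alpha_dspn else plast$alpha_ispn
  wmin <- if (target == "dSPN") plast$wmin_dspn else plast$wmin_ispn
  wmax <- if (target == "dSPN") plast$wmax_dspn else plast$wmax_ispn
  d <- alpha * state$E * f_kda(K_da, target, plast$gamma, plast$mu, plast$eps)
  dw <- if (d > 0) d * (wmax - state$w) else d * (state$w - wmin)
  state$w <- min(wmax, max(wmin, state$w + dt * dw))
  state
}

#' Apply a feedback event to the dopamine system
#'
#' Computes the reward prediction error of the chosen action, updates the action
#' value with learning rate `alpha_q`, and moves available dopamine toward
#' the increment by fraction `c_scale` (the literal integral of the printed
#' impulse term).
#' @param dopamine a `cbgt_plasticity_state`. @param action chosen channel
#'   (1 or 2). @param reward reward value in `[0, 1]`.
#' @return the updated state, with the increment in `$last_da_inc`.
#' @export
reward_event <- function(dopamine, action, reward) {
  stopifnot(inherits(dopamine, "cbgt_plasticity_state"), action %in% 1:2)
  if (reward < 0 || reward > 1) stop("reward outside configured range [0, 1]")
  da_inc <- reward - dopamine$Q[action]
  dopamine$Q[action] <- dopamine$Q[action] + dopamine$alpha_q * da_inc
  dopamine$K_da <- dopamine$K_da + dopamine$plast$c_scale *
    (da_inc - dopamine$K_da)
  dopamine$last_da_inc <- da_inc
  dopamine
}

# decay the dopamine pool over the inter-trial interval
decay_dopamine <- function(dopamine, ms) {
  dopamine$K_da <- dopamine$K_da * exp(-ms / dopamine$plast$tau_da)
  dopamine
}
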