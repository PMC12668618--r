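#' @title Two-channel spiking CBGT network
#' @name cbgt_network
#' @description
#' The network comprises nine cell types: excitatory cortex (Cx), inhibitory
#' cortex (CxI), striatal fast-spiking interneurons (FSI), direct- and
#' indirect-pathway spiny projection neurons (dSPN, iSPN), external and
#' internal globus pallidus (GPe, GPi), subthalamic nucleus (STN) and thalamus
#' (Thal). Every type except CxI and FSI is duplicated into two action
#' channels. Neurons are conductance-based leaky integrate-and-fire units with
#' exponential AMPA (2 ms) and GABA (5 ms) synapses; every population receives
#' an Ornstein-Uhlenbeck external conductance whose mean tracks a Poisson
#' bombardment of rate `f_ext` per connection. On each trial the two cortical
#' populations additionally receive a ramping input (equal for both channels,
#' so any choice asymmetry arises downstream), and a choice is registered when
#' the smoothed firing-rate estimate of either thalamic population first
#' reaches the decision threshold (30 Hz by default).
NULL

.regions <- c("Cx", "CxI", "FSI", "dSPN", "iSPN", "GPe", "STN", "GPi", "Thal")
.channel_split <- c(Cx = TRUE, CxI = FALSE, FSI = FALSE, dSPN = TRUE,
                    iSPN = TRUE, GPe = TRUE, STN = TRUE, GPi = TRUE,
                    Thal = TRUE)

default_population_sizes <- function() {
  c(Cx = 40L, CxI = 20L, FSI = 10L, dSPN = 20L, iSPN = 20L,
    GPe = 20L, STN = 10L, GPi = 20L, Thal = 20L)
}

# per-region membrane constants: tau_m, V_L, V_th, V_reset, V_E, V_I, t_ref
default_neuron_constants <- function() {
  m <- rbind(
    Cx   = c(20, -70, -50, -55, 0, -80, 2),
    CxI  = c(10, -70, -50, -55, 0, -80, 1),
    FSI  = c(10, -70, -50, -55, 0, -80, 1),
    dSPN = c(15, -80, -50, -55, 0, -80, 2),
    iSPN = c(15, -80, -50, -55, 0, -80, 2),
    GPe  = c(10, -70, -50, -55, 0, -80, 1),
    STN  = c(10, -70, -50, -55, 0, -80, 1),
    GPi  = c(10, -70, -50, -55, 0, -80, 1),
    Thal = c(15, -70, -50, -55, 0, -80, 2))
  colnames(m) <- c("tau_m", "V_L", "V_th", "V_reset", "V_E", "V_I", "t_ref")
  m
}

# per-region external drive: efficacy, connection count, AMPA decay, rate (Hz)
default_external_drive <- function() {
  m <- rbind(
    Cx   = c(0.475, 100, 2, 2.5),   # rate is baseline; ramp adds f_ramp(t)
    CxI  = c(0.468, 100, 2, 2.2),
    FSI  = c(0.472, 100, 2, 2.4),
    dSPN = c(0.697, 100, 2, 1.8),
    iSPN = c(0.687, 100, 2, 1.8),
    GPe  = c(0.427, 100, 2, 4.0),
    STN  = c(0.463, 100, 2, 3.0),
    GPi  = c(0.456, 100, 2, 4.5),
    Thal = c(0.600, 100, 2, 2.5))
  colnames(m) <- c("E_ext", "N_ext", "tau_x", "f_ext")
  m
}

# projection table: efficacy per connection, connection probability, receptor.
# `diffuse` projections reach both channels; all others stay within channel
# (or fan out from/to the shared CxI and FSI pools).
default_projection_efficacies <- function() {
  data.frame(
    name = c("cx_dspn", "cx_ispn", "cx_fsi", "cx_thal", "cx_cxi", "cx_stn",
             "cxi_cx", "cxi_cxi", "fsi_dspn", "fsi_ispn", "fsi_fsi",
             "dspn_gpi", "ispn_gpe", "gpe_stn", "gpe_gpi", "gpe_gpe",
             "stn_gpe", "stn_gpi", "gpi_thal", "thal_cx", "thal_dspn",
             "thal_ispn"),
    src  = c("Cx", "Cx", "Cx", "Cx", "Cx", "Cx",
             "CxI", "CxI", "FSI", "FSI", "FSI",
             "dSPN", "iSPN", "GPe", "GPe", "GPe",
             "STN", "STN", "GPi", "Thal", "Thal", "Thal"),
    dst  = c("dSPN", "iSPN", "FSI", "Thal", "CxI", "STN",
             "Cx", "CxI", "dSPN", "iSPN", "FSI",
             "GPi", "GPe", "STN", "GPi", "GPe",
             "GPe", "GPi", "Thal", "Cx", "dSPN", "iSPN"),
    receptor = c("AMPA", "AMPA", "AMPA", "AMPA", "AMPA", "AMPA",
                 "GABA", "GABA", "GABA", "GABA", "GABA",
                 "GABA", "GABA", "GABA", "GABA", "GABA",
                 "AMPA", "AMPA", "GABA", "AMPA", "AMPA", "AMPA"),
    efficacy = c(0.040, 0.040, 0.012, 0.015, 0.015, 0.030,
                 0.040, 0.020, 0.040, 0.040, 0.020,
                 0.400, 0.250, 0.050, 0.050, 0.010,
                 0.050, 0.060, 0.120, 0.080, 0.180, 0.030),
    p_connect = c(1, 1, 0.5, 0.5, 0.5, 0.5,
                  0.5, 0.5, 0.5, 0.5, 0.5,
                  0.5, 0.5, 0.5, 0.5, 0.25,
                  0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    plastic = c(TRUE, TRUE, rep(FALSE, 20)),
    diffuse = c(rep(FALSE, 17), TRUE, rep(FALSE, 4)),
    stringsAsFactors = FALSE)
}

#' Construct the full parameterization of one CBGT network instance
#'
#' @param efficacies named numeric vector overriding entries of the default
#'   projection-efficacy table (this is the surface the genetic algorithm
#'   samples); both channels always share all efficacies, so networks are
#'   channel-symmetric before learning.
#' @param population_sizes named integer vector (per region; channel-split
#'   regions get one population of this size per channel).
#' @param external_drive matrix of per-region external-drive settings (efficacy, connection count, decay, rate).
#' @param f_target asymptotic value of the dimensionless cortical ramp.
#' @param ramp_rate relaxation fraction of the ramp recurrence, applied once
#'   per millisecond of simulated time.
#' @param onset_ms input-onset latency (ms): the delay between trial start
#'   and the arrival of the ramping stimulus input in cortex, standing in for
#'   upstream sensory processing and propagation; reaction times are measured
#'   from trial start and therefore include it.
#' @param threshold_hz thalamic decision threshold (Hz).
#' @param max_ms trial timeout (ms).
#' @param tau_smooth time constant (ms) of the exponential firing-rate
#'   estimator used by the decision rule (wide enough that a 30 Hz crossing
#'   reflects sustained thalamic activation rather than estimator noise).
#' @param dt integration step (ms); warmup_ms of stationary baseline is
#'   simulated before the ramp starts.
#' @param warmup_ms pre-trial settling time (ms).
#' @param bin_ms width of the firing-rate trace bins (ms).
#' @param seed integer seed fixing the connectivity masks (channel-mirrored,
#'   so the wiring itself is symmetric across channels).
#' @return an object of class `cbgt_network_params`.
#' @export
network_params <- function(efficacies = NULL,
                           population_sizes = default_population_sizes(),
                           external_drive = default_external_drive(),
                           f_target = 1.0, ramp_rate = 0.1,
                           onset_ms = 150,
                           threshold_hz = 30, max_ms = 1000,
                           tau_smooth = 25, dt = 0.1, warmup_ms = 200,
                           bin_ms = 5, seed = 1L) {
  proj <- default_projection_efficacies()
  if (!is.null(efficacies)) {
    stopifnot(!is.null(names(efficacies)))
    unknown <- setdiff(names(efficacies), proj$name)
    if (length(unknown))
      stop("unknown projection(s): ", paste(unknown, collapse = ", "))
    proj$efficacy[match(names(efficacies), proj$name)] <- unname(efficacies)
  }
  p <- list(population_sizes = population_sizes,
            neuron_constants = default_neuron_constants(),
            projections = proj,
            external_drive = external_drive,
            f_target = f_target, ramp_rate = ramp_rate,
            onset_ms = onset_ms,
            threshold_hz = threshold_hz, max_ms = max_ms,
            tau_smooth = tau_smooth, dt = dt, warmup_ms = warmup_ms,
            bin_ms = bin_ms, tau_ampa = 2, tau_gaba = 5,
            f_baseline_mean = 2.5, f_baseline_sd = 0.06,
            seed = as.integer(seed))
  class(p) <- "cbgt_network_params"
  validate_network_params(p)
  p
}

#' @export
print.cbgt_network_params <- function(x, ...) {
  cat("CBGT network parameters:",
      sum(ifelse(.channel_split[names(x$population_sizes)], 2L, 1L) *
            x$population_sizes), "neurons,",
      nrow(x$projections), "projection types, seed", x$seed, "\n")
  invisible(x)
}

validate_network_params <- function(p) {
  stopifnot(all(p$population_sizes >= 1),
            all(p$external_drive[, "f_ext"] >= 0),
            all(p$projections$efficacy >= 0),
            p$f_target >= 0, p$threshold_hz > 0, p$max_ms > 0,
            p$dt > 0, p$tau_smooth > 0)
  invisible(p)
}

#' One step of the cortical ramp recurrence
#'
#' `f_ramp` relaxes toward `f_target` by a fixed fraction (`rate`) of the
#' remaining gap on every integrator step, giving `1 - (1-rate)^n` after `n`
#' steps from zero.
#' @param f_ramp_prev current ramp value (dimensionless, in `[0, f_target]`).
#' @param f_target asymptote.
#' @param rate relaxation fraction per step.
#' @export
ramp_step <- function(f_ramp_prev, f_target, rate = 0.1) {
  if (any(f_ramp_prev < 0) || any(f_target < 0))
    stop("ramp values must be non-negative")
  f_ramp_prev + rate * (f_target - f_ramp_prev)
}

#' Stationary mean of the external-drive conductance
#'
#' For Poisson bombardment at `f_ext` Hz over `N_ext` connections of efficacy
#' `E_ext` decaying with `tau` ms, the mean conductance is
#' `0.001 * E_ext * f_ext * N_ext * tau`.
#' @export
external_drive_mu <- function(E_ext, f_ext, N_ext, tau) {
  0.001 * E_ext * f_ext * N_ext * tau
}

#' One Euler-Maruyama step of the mean-reverting external drive
#'
#' `dS = (mu - S)/tau dt + sigma * sqrt(2/tau) dW`, whose stationary law is
#' Normal(mu, sigma^2). With `sigma = 0` the state decays exponentially
#' toward `mu`.
#' @param S current conductance state.
#' @param mu stationary mean (see [external_drive_mu()]).
#' @param sigma stationary standard deviation.
#' @param tau decay time constant (ms), positive.
#' @param dt step (ms), positive.
#' @param noise_draw standard-normal draw(s).
#' @export
external_drive_step <- function(S, mu, sigma, tau, dt, noise_draw) {
  if (tau <= 0) stop("tau must be positive")
  if (dt <= 0) stop("dt must be positive")
  S + (mu - S) / tau * dt + sigma * sqrt(2 * dt / tau) * noise_draw
}

# ---------------------------------------------------------------------------
# build: expand params into the slot/projection representation the C++
# integrator consumes. Connectivity masks are drawn once from params$seed and
# mirrored across channels, so the wiring is exactly channel-symmetric.
# ---------------------------------------------------------------------------

slot_table <- function(sizes) {
  rows <- list()
  for (r in .regions) {
    if (.channel_split[[r]]) {
      rows[[length(rows) + 1L]] <- data.frame(region = r, channel = 1L,
                                              n = sizes[[r]])
      rows[[length(rows) + 1L]] <- data.frame(region = r, channel = 2L,
                                              n = sizes[[r]])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(region = r, channel = NA_integer_,
                                              n = sizes[[r]])
    }
  }
  st <- do.call(rbind, rows)
  st$label <- ifelse(is.na(st$channel), st$region,
                     paste0(st$region, st$channel))
  st
}

#' Build a simulable network from its parameters
#'
#' Expands the parameter set into explicit per-channel populations and
#' per-projection weight matrices (efficacy on connected pairs, 0 elsewhere).
#' @param params a `cbgt_network_params` object.
#' @return an object of class `cbgt_network` holding the integrator state;
#'   plastic corticostriatal weight matrices live in `$projections` and are
#'   updated in place by learning trials.
#' @export
build_network <- function(params) {
  validate_network_params(params)
  st <- slot_table(params$population_sizes)
  slot_of <- function(region, channel = NA) {
    which(st$region == region &
            (is.na(channel) | st$channel %in% channel | is.na(st$channel)))
  }
  nc <- params$neuron_constants[st$region, , drop = FALSE]
  ex <- params$external_drive[st$region, , drop = FALSE]

  projections <- list()
  with_seed(params$seed, {
    for (k in seq_len(nrow(params$projections))) {
      pj <- params$projections[k, ]
      src_split <- .channel_split[[pj$src]]
      dst_split <- .channel_split[[pj$dst]]
      n_src <- params$population_sizes[[pj$src]]
      n_dst <- params$population_sizes[[pj$dst]]
      # one mask per (projection, target-channel-pattern), reused for the
      # mirrored channel so channels are interchangeable before learning
      mask_same <- matrix(runif(n_dst * n_src) < pj$p_connect, n_dst, n_src)
      mask_cross <- if (pj$diffuse)
        matrix(runif(n_dst * n_src) < pj$p_connect, n_dst, n_src)
      W_of <- function(mask) {
        W <- matrix(0, n_dst, n_src)
        W[mask] <- pj$efficacy
        W
      }
      add <- function(s_slot, d_slot, mask) {
        projections[[length(projections) + 1L]] <<- list(
          name = pj$name,
          src = s_slot - 1L, dst = d_slot - 1L,
          src_label = st$label[s_slot], dst_label = st$label[d_slot],
          receptor = if (pj$receptor == "AMPA") 0L else 1L,
          W = W_of(mask), plastic = pj$plastic,
          target_type = if (!pj$plastic) 0L
                        else if (pj$dst == "dSPN") 1L else 2L,
          channel = if (src_split) st$channel[s_slot]
                    else if (dst_split) st$channel[d_slot] else NA_integer_)
      }
      if (src_split && dst_split) {
        for (ch in 1:2) {
          add(slot_of(pj$src, ch), slot_of(pj$dst, ch), mask_same)
          if (pj$diffuse)
            add(slot_of(pj$src, ch), slot_of(pj$dst, 3 - ch), mask_cross)
        }
      } else if (src_split && !dst_split) {
        for (ch in 1:2) add(slot_of(pj$src, ch), slot_of(pj$dst), mask_same)
      } else if (!src_split && dst_split) {
        for (ch in 1:2) add(slot_of(pj$src), slot_of(pj$dst, ch), mask_same)
      } else {
        add(slot_of(pj$src), slot_of(pj$dst), mask_same)
      }
    }
  })

  net <- list(
    slot_size = as.integer(st$n), slot_label = st$label,
    slot_region = st$region, slot_channel = st$channel,
    neuron = unname(nc), ext = unname(ex),
    is_ctx = st$region == "Cx",
    projections = projections,
    tau_ampa = params$tau_ampa, tau_gaba = params$tau_gaba,
    dt = params$dt, warmup_ms = params$warmup_ms, max_ms = params$max_ms,
    bin_ms = params$bin_ms, threshold_hz = params$threshold_hz,
    tau_smooth = params$tau_smooth,
    thal_slot1 = which(st$label == "Thal1") - 1L,
    thal_slot2 = which(st$label == "Thal2") - 1L,
    f_target = params$f_target, ramp_rate = params$ramp_rate,
    onset_ms = params$onset_ms,
    params = params)
  class(net) <- "cbgt_network"
  net
}

#' @export
print.cbgt_network <- function(x, ...) {
  cat("CBGT network:", sum(x$slot_size), "neurons in", length(x$slot_size),
      "populations;", length(x$projections), "projections\n")
  invisible(x)
}

#' Simulate one trial of the two-choice task
#'
#' Runs the network from a warmed-up baseline with the cortical ramp on and
#' declares the choice of the first channel whose smoothed thalamic rate
#' crosses the threshold; a trial with no crossing within the window is a
#' timeout. When `learn` is supplied (see [plasticity_state()]), the reward
#' outcome triggers a phasic dopamine signal and corticostriatal weights are
#' updated during a post-decision feedback window; the network's plastic
#' weight matrices are updated in place.
#'
#' @param network a `cbgt_network` from [build_network()].
#' @param seed optional integer; when given, the trial is bit-reproducible.
#' @param learn `NULL` for a probe (plasticity-off) trial, otherwise a
#'   `cbgt_plasticity_state`.
#' @param f_baseline optional fixed baseline input rate (Hz); by default it is
#'   drawn per trial from Normal(2.5, 0.06) clipped at zero.
#' @return a list of class `cbgt_trial`: `choice` (1, 2, or 0 for timeout),
#'   `decision_time` (ms), `timeout`, `reward`, `rate_traces` (bins x
#'   populations, Hz), `final_thalamic_rates`, and the updated `learn` state.
#' @export
simulate_trial <- function(network, seed = NULL, learn = NULL,
                           f_baseline = NULL) {
  stopifnot(inherits(network, "cbgt_network"))
  if (!is.null(seed)) set.seed(seed)
  p <- network$params
  if (is.null(f_baseline))
    f_baseline <- max(0, rnorm(1, p$f_baseline_mean, p$f_baseline_sd))
  learn_arg <- if (is.null(learn)) list(enabled = FALSE) else {
    stopifnot(inherits(learn, "cbgt_plasticity_state"))
    c(list(enabled = TRUE), unclass(learn))
  }
  res <- run_trial_cpp(network, f_baseline, learn_arg)
  # write updated plastic weights back into the network (reference semantics
  # via the enclosing environment of the caller is avoided: return the net)
  if (!is.null(learn)) {
    for (i in seq_along(network$projections))
      if (network$projections[[i]]$plastic)
        network$projections[[i]]$W <- res$W[[i]]
    learn$K_da <- res$K_da
    learn$Q <- res$Q
  }
  rates <- res$rates
  colnames(rates) <- network$slot_label
  thal_final <- c(NA_real_, NA_real_)
  bu <- res$bins_used
  if (bu >= 1) {
    thal_final <- c(rates[bu, "Thal1"], rates[bu, "Thal2"])
  }
  structure(list(
    choice = res$choice, decision_time = res$decision_ms,
    timeout = res$timeout, reward = res$reward, da_inc = res$da_inc,
    feedback_rates = setNames(as.numeric(res$feedback_rates),
                              network$slot_label),
    rate_traces = rates[seq_len(bu), , drop = FALSE],
    final_thalamic_rates = thal_final,
    f_baseline = f_baseline,
    network = network, learn = learn), class = "cbgt_trial")
}

#' Average population activity over a set of trials
#'
#' @param trials a list of `cbgt_trial` results (or a single one).
#' @param window optional `c(from, to)` ms interval (relative to ramp onset)
#'   over which to average; default is each trial's whole pre-decision span.
#' @return a data.frame (class `cbgt_activity`) with columns `region`,
#'   `channel` (NA for the shared CxI/FSI pools) and `rate` (Hz), averaged
#'   across trials. Timeout trials still contribute their rate traces.
#' @export
summarize_activity <- function(trials, window = NULL) {
  if (inherits(trials, "cbgt_trial")) trials <- list(trials)
  if (!length(trials)) stop("empty trial collection")
  net <- trials[[1L]]$network
  per_trial <- lapply(trials, function(tr) {
    rt <- tr$rate_traces
    if (!is.null(window)) {
      tmid <- (seq_len(nrow(rt)) - 0.5) * net$bin_ms
      rt <- rt[tmid >= window[1] & tmid <= window[2], , drop = FALSE]
    }
    if (!nrow(rt)) return(rep(NA_real_, ncol(rt)))
    colMeans(rt, na.rm = TRUE)
  })
  m <- colMeans(do.call(rbind, per_trial), na.rm = TRUE)
  out <- data.frame(region = net$slot_region, channel = net$slot_channel,
                    rate = unname(m))
  class(out) <- c("cbgt_activity", "data.frame")
  out
}

# mean weight of each plastic projection, by target type and channel
# (corticostriatal projections are all-to-all, so every entry is a synapse)
mean_plastic_weights <- function(network) {
  pls <- Filter(function(p) p$plastic, network$projections)
  do.call(rbind, lapply(pls, function(p) {
    data.frame(projection = p$name, channel = p$channel,
               target = if (p$target_type == 1L) "dSPN" else "iSPN",
               mean_w = mean(p$W))
  }))
}

# full per-synapse snapshot of the plastic weights (one row per synapse)
plastic_weight_snapshot <- function(network) {
  pls <- Filter(function(p) p$plastic, network$projections)
  do.call(rbind, lapply(pls, function(p) {
    data.frame(projection = p$name, channel = p$channel,
               target = if (p$target_type == 1L) "dSPN" else "iSPN",
               pre = rep(seq_len(ncol(p$W)), each = nrow(p$W)),
               post = rep(seq_len(nrow(p$W)), times = ncol(p$W)),
               w = as.vector(p$W))
  }))
}
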