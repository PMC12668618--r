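#' @title Two-armed bandit sessions with staged freezing
#' @name task_protocol
#' @description
#' A session alternates learning blocks (plasticity on, reward drawn from the
#' chosen option's Bernoulli probability) with frozen probe blocks: at each
#' configured stage the plasticity is suspended and a block of probe trials is
#' run from the frozen weight state to measure the network's current policy.
#' A baseline probe block (stage 0) precedes any learning.
NULL

#' Session configuration
#'
#' @param n_learning_trials total learning trials (default 15).
#' @param freeze_stages strictly increasing learning-trial counts after which
#'   the network is frozen and probed (default 2, 4, 6, 15).
#' @param probe_trials_per_stage probe-block size (default 300; reduce for
#'   desk-scale runs).
#' @param baseline_probe whether to run a stage-0 probe block before any
#'   learning.
#' @param reward_prob_optimal,reward_prob_suboptimal Bernoulli reward
#'   probabilities.
#' @param rewarded_channel 1 or 2.
#' @param seed session seed (all trials derive from one stream).
#' @export
session_config <- function(n_learning_trials = 15L,
                           freeze_stages = c(2L, 4L, 6L, 15L),
                           probe_trials_per_stage = 300L,
                           baseline_probe = TRUE,
                           reward_prob_optimal = 1,
                           reward_prob_suboptimal = 0,
                           rewarded_channel = 1L,
                           seed = 1L) {
  stopifnot(all(diff(freeze_stages) > 0),
            all(freeze_stages <= n_learning_trials),
            reward_prob_optimal >= 0, reward_prob_optimal <= 1,
            reward_prob_suboptimal >= 0, reward_prob_suboptimal <= 1,
            rewarded_channel %in% 1:2)
  structure(list(n_learning_trials = as.integer(n_learning_trials),
                 freeze_stages = as.integer(freeze_stages),
                 probe_trials_per_stage = as.integer(probe_trials_per_stage),
                 baseline_probe = isTRUE(baseline_probe),
                 reward_prob_optimal = reward_prob_optimal,
                 reward_prob_suboptimal = reward_prob_suboptimal,
                 rewarded_channel = as.integer(rewarded_channel),
                 seed = as.integer(seed)),
            class = "cbgt_session_config")
}

#' Run one learning session with staged probes
#'
#' @param network a built `cbgt_network` (naive weights).
#' @param plast plasticity constants ([plasticity_params()]).
#' @param config a [session_config()].
#' @return a `cbgt_session` list: `trials` (one row per trial: trial index,
#'   phase, stage, choice, decision_time_ms, reward, timeout), `activity`
#'   (per-stage probe-averaged [summarize_activity()] tables), `weights`
#'   (per-stage mean plastic weights), `config`, and the final network state.
#' @export
run_session <- function(network, plast = plasticity_params(),
                        config = session_config()) {
  stopifnot(inherits(network, "cbgt_network"),
            inherits(config, "cbgt_session_config"))
  set.seed(config$seed)
  dop <- plasticity_state(plast,
                          rewarded_channel = config$rewarded_channel,
                          p_opt = config$reward_prob_optimal,
                          p_sub = config$reward_prob_suboptimal)
  trials <- list(); activity <- list(); weights <- list()
  trial_idx <- 0L

  probe_block <- function(stage_id) {
    probes <- vector("list", config$probe_trials_per_stage)
    for (i in seq_len(config$probe_trials_per_stage)) {
      tr <- simulate_trial(network, learn = NULL)
      trial_idx <<- trial_idx + 1L
      trials[[length(trials) + 1L]] <<- data.frame(
        trial = trial_idx, phase = "probe", stage = stage_id,
        choice = tr$choice, decision_time_ms = tr$decision_time,
        reward = NA_real_, timeout = tr$timeout)
      probes[[i]] <- tr
    }
    activity[[as.character(stage_id)]] <<- summarize_activity(probes)
    weights[[as.character(stage_id)]] <<- mean_plastic_weights(network)
  }

  if (config$baseline_probe) probe_block(0L)

  stages <- config$freeze_stages
  done <- 0L
  for (s in seq_along(stages)) {
    for (k in seq_len(stages[s] - done)) {
      tr <- simulate_trial(network, learn = dop)
      network <- tr$network          # plastic weights updated
      dop <- decay_dopamine(tr$learn, plast$iti_ms)
      trial_idx <- trial_idx + 1L
      trials[[length(trials) + 1L]] <- data.frame(
        trial = trial_idx, phase = "learning", stage = s,
        choice = tr$choice, decision_time_ms = tr$decision_time,
        reward = tr$reward, timeout = tr$timeout)
    }
    done <- stages[s]
    probe_block(s)
  }

  structure(list(trials = do.call(rbind, trials), activity = activity,
                 weights = do.call(rbind, lapply(names(weights), function(n)
                   cbind(stage = as.integer(n), weights[[n]]))),
                 config = config, network = network, dopamine = dop),
            class = "cbgt_session")
}

#' Probe accuracy, mean RT and reward rate per stage of a session
#'
#' Accuracy is the fraction of non-timeout probe trials choosing the rewarded
#' channel; reward rate is accuracy divided by mean probe RT (in seconds).
#' @param session a `cbgt_session`.
#' @export
session_stage_summary <- function(session) {
  tr <- session$trials[session$trials$phase == "probe" &
                         !session$trials$timeout, ]
  if (!nrow(tr)) stop("all probe trials timed out: fit-infeasible session")
  agg <- lapply(split(tr, tr$stage), function(d) {
    acc <- mean(d$choice == session$config$rewarded_channel)
    rt_s <- mean(d$decision_time_ms) / 1000
    data.frame(stage = d$stage[1], n = nrow(d), accuracy = acc,
               mean_rt_s = rt_s, reward_rate = acc / rt_s)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$stage), ]
}

#' Tertile speed classification of a network cohort
#'
#' Splits networks into equal-count fast / intermediate / slow classes from
#' their baseline (pre-plasticity) mean reaction times; ties are broken by
#' position in the input order.
#' @param baseline_rts numeric vector of per-network mean baseline RTs (ms).
#' @return factor with levels `fast`, `intermediate`, `slow` and attribute
#'   `bounds` (the tertile boundaries in ms).
#' @export
classify_speed <- function(baseline_rts) {
  n <- length(baseline_rts)
  if (n < 3) stop("need at least 3 networks for a tertile split")
  ord <- order(baseline_rts)             # stable: ties keep input order
  counts <- diff(round(seq(0, n, length.out = 4)))
  lab <- rep(c("fast", "intermediate", "slow"), times = counts)
  cls <- character(n)
  cls[ord] <- lab
  bounds <- quantile(baseline_rts, c(1 / 3, 2 / 3), names = FALSE)
  structure(factor(cls, levels = c("fast", "intermediate", "slow")),
            bounds = bounds)
}

#' Outcome-sequence label of the first k learning trials
#'
#' @param session a `cbgt_session` (or its `trials` data.frame).
#' @param k number of leading learning trials (default 2).
#' @return a label such as `"U-R"` (Unrewarded then Rewarded).
#' @export
outcome_sequence <- function(session, k = 2L) {
  tr <- if (inherits(session, "cbgt_session")) session$trials else session
  lt <- tr[tr$phase == "learning", ]
  if (nrow(lt) < k) stop("fewer than k learning trials in log")
  r <- lt$reward[seq_len(k)]
  # a timed-out learning trial delivers no reward and counts as unrewarded
  paste(ifelse(!is.na(r) & r > 0, "R", "U"), collapse = "-")
}
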