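#' @title End-to-end study orchestration
#' @name study
#' @description
#' Runs the full pipeline — GA sampling of network configurations, staged
#' learning sessions, per-stage DDM fits, policy-manifold alignment,
#' baseline CCA control ensembles, and the driver decomposition — from one
#' configuration with a single master seed, writing every intermediate
#' artifact as plain CSV/JSON (plus an RDS checkpoint per stage for
#' resumption). A completed stage is not recomputed on rerun.
NULL

#' Study configuration
#'
#' @param n_networks cohort size. @param ga_trials probe trials per GA
#'   evaluation. @param probe_trials probe-block size per stage.
#' @param freeze_stages learning-trial counts at which to freeze and probe.
#' @param manifold_n nodes per manifold axis. @param manifold_seeds,
#'   manifold_trials averaging at each node. @param cca_shuffles null
#'   permutations. @param out_dir output directory. @param seed master seed
#'   (every stage derives a recorded sub-seed).
#' @export
study_config <- function(n_networks = 10, ga_trials = 40,
                         probe_trials = 80, freeze_stages = c(2, 4, 6, 15),
                         manifold_n = 12, manifold_seeds = 5,
                         manifold_trials = 200, cca_shuffles = 50,
                         out_dir = "results/study", seed = 1L) {
  structure(list(n_networks = n_networks, ga_trials = ga_trials,
                 probe_trials = probe_trials, freeze_stages = freeze_stages,
                 manifold_n = manifold_n, manifold_seeds = manifold_seeds,
                 manifold_trials = manifold_trials,
                 cca_shuffles = cca_shuffles,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "cbgt_study_config")
}

checkpoint_path <- function(cfg, stage) file.path(cfg$out_dir,
                                                  paste0(stage, ".rds"))

run_stage <- function(cfg, stage, compute) {
  path <- checkpoint_path(cfg, stage)
  if (file.exists(path)) {
    message("stage '", stage, "': reusing ", path)
    return(readRDS(path))
  }
  message("stage '", stage, "': computing")
  value <- compute()
  saveRDS(value, path)
  value
}

activity_long <- function(activities, ids) {
  do.call(rbind, lapply(seq_along(activities), function(i)
    cbind(network = ids[i], as.data.frame(activities[[i]]))))
}

#' Run the full study
#'
#' @param config a [study_config()].
#' @return the study report: cohort table, per-stage behavior and DDM fits,
#'   cosine-distance summary, control ensembles, driver matrices, and
#'   outcome-sequence results.
#' @export
run_study <- function(config = study_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage 1: GA-sampled cohort --------------------------------------
  cohort <- run_stage(cfg, "01_networks", function() {
    ga <- ga_evolve(target_solutions = cfg$n_networks,
                    n_trials = cfg$ga_trials, max_iter = 400,
                    seed = derive_seed(cfg$seed, "ga"))
    if (length(ga$accepted) < cfg$n_networks)
      warning("only ", length(ga$accepted), " networks accepted")
    ga$accepted
  })
  eff_tab <- do.call(rbind, lapply(seq_along(cohort), function(i)
    data.frame(network = i, t(cohort[[i]]$values),
               net_seed = cohort[[i]]$net_seed)))
  write.csv(eff_tab, file.path(cfg$out_dir, "networks.csv"),
            row.names = FALSE)

  # --- stage 2: learning sessions --------------------------------------
  sessions <- run_stage(cfg, "02_sessions", function() {
    lapply(seq_along(cohort), function(i) {
      net <- build_network(network_params(
        efficacies = cohort[[i]]$values, seed = cohort[[i]]$net_seed))
      s <- run_session(net, plasticity_params(),
                       session_config(freeze_stages = cfg$freeze_stages,
                                      probe_trials_per_stage =
                                        cfg$probe_trials,
                                      seed = derive_seed(cfg$seed,
                                                         paste0("sess", i))))
      s$network <- NULL          # drop heavy state from the checkpoint
      s
    })
  })
  trials_all <- do.call(rbind, lapply(seq_along(sessions), function(i)
    cbind(network = i, sessions[[i]]$trials)))
  write.csv(trials_all, file.path(cfg$out_dir, "trials.csv"),
            row.names = FALSE)
  stage_ids <- c(0L, seq_along(cfg$freeze_stages))
  act_long <- do.call(rbind, lapply(stage_ids, function(st)
    cbind(stage = st, activity_long(
      lapply(sessions, function(s) s$activity[[as.character(st)]]),
      seq_along(sessions)))))
  write.csv(act_long, file.path(cfg$out_dir, "rates.csv"), row.names = FALSE)

  # --- stage 3: DDM fits per (network, stage) ---------------------------
  fits <- run_stage(cfg, "03_ddm_fits", function() {
    set.seed(derive_seed(cfg$seed, "ddmfit"))
    out <- list()
    for (i in seq_along(sessions)) for (st in stage_ids) {
      beh <- behavior_from_session(sessions[[i]], st)
      f <- fit_ddm_mle(beh)
      gen <- simulate_ddm(f$params, n = max(500, nrow(beh)), dt = 1e-3)
      out[[length(out) + 1L]] <- data.frame(
        network = i, stage = st, v = f$params$v, a = f$params$a,
        t0 = f$params$t0, z = f$params$z, loglik = f$loglik,
        n_trials = f$n_trials, qq_r = qq_check(beh, gen)$r,
        weak = f$weak_identification)
    }
    do.call(rbind, out)
  })
  write.csv(fits, file.path(cfg$out_dir, "ddm_fits.csv"), row.names = FALSE)

  # --- stage 4: manifold + gradient alignment ---------------------------
  base <- fits[fits$stage == 0, ]
  manifold <- run_stage(cfg, "04_manifold", function() {
    pad <- function(x) c(min(x) - 0.3 * diff(range(x)) - 0.1,
                         max(x) + 0.3 * diff(range(x)) + 0.1)
    vr <- pad(fits$v); ar <- pad(fits$a)
    ar[1] <- max(ar[1], 0.2)
    build_manifold(seq(vr[1], vr[2], length.out = cfg$manifold_n),
                   seq(ar[1], ar[2], length.out = cfg$manifold_n),
                   t0 = mean(base$t0), z = 0.5,
                   seeds = cfg$manifold_seeds,
                   trials = cfg$manifold_trials,
                   seed = derive_seed(cfg$seed, "manifold"))
  })
  grid_df <- expand.grid(v = manifold$v, a = manifold$a)
  grid_df$rt <- as.vector(manifold$rt)
  grid_df$accuracy <- as.vector(manifold$accuracy)
  grid_df$reward_rate <- as.vector(manifold$reward_rate)
  write.csv(grid_df, file.path(cfg$out_dir, "manifold.csv"),
            row.names = FALSE)
  alignment <- compare_objectives(fits[, c("network", "stage", "v", "a")],
                                  manifold)
  write.csv(alignment$distances, file.path(cfg$out_dir, "distances.csv"),
            row.names = FALSE)

  # --- stage 5: baseline control ensembles ------------------------------
  base_act <- lapply(sessions, function(s) s$activity[["0"]])
  F_base <- build_features(base_act)
  D_base <- as.matrix(base[order(base$network), c("a", "t0", "v")])
  colnames(D_base) <- c("a", "t", "v")
  ensembles <- run_stage(cfg, "05_cca", function()
    fit_cca(F_base, D_base, k_folds = 4, n_shuffles = cfg$cca_shuffles,
            seed = derive_seed(cfg$seed, "cca")))
  load_df <- data.frame(feature = feature_names(), ensembles$u)
  write.csv(load_df, file.path(cfg$out_dir, "cca_loadings.csv"),
            row.names = FALSE)

  # --- stage 6: drivers (full cohort + outcome sequences) ---------------
  last <- as.character(length(cfg$freeze_stages))
  post_act <- lapply(sessions, function(s) s$activity[[last]])
  rewarded <- vapply(sessions, function(s) s$config$rewarded_channel,
                     integer(1))
  dF <- delta_features(build_features(post_act, rewarded),
                       build_features(base_act, rewarded), ensembles)
  k_pc <- min(5, nrow(dF) - 1)
  drv <- ensemble_drivers(dF, ensembles, k = k_pc)
  # outcome sequences from the first two learning trials; stage-1 freeze
  seqs <- vapply(sessions, outcome_sequence, character(1))
  act2 <- lapply(sessions, function(s) s$activity[["1"]])
  dF2 <- delta_features(build_features(act2, rewarded),
                        build_features(base_act, rewarded), ensembles)
  summ <- lapply(sessions, session_stage_summary)
  rr_of <- function(s, st) {
    d <- summ[[s]]; d$reward_rate[d$stage == st]
  }
  delta_rr <- vapply(seq_along(sessions), function(s)
    rr_of(s, 1) - rr_of(s, 0), numeric(1))
  speed <- classify_speed(vapply(seq_along(sessions), function(s) {
    d <- summ[[s]]; d$mean_rt_s[d$stage == 0] * 1000
  }, numeric(1)))
  seq_res <- sequence_drivers(dF2, seqs, delta_rr, ensembles,
                              speed_class = speed, k = k_pc)

  report <- list(config = cfg, cohort = eff_tab, fits = fits,
                 stage_summaries = summ, alignment = alignment,
                 ensembles = ensembles, drivers = drv,
                 sequences = seqs, speed_class = speed,
                 sequence_drivers = seq_res)
  saveRDS(report, file.path(cfg$out_dir, "report.rds"))
  report
}

#' Summary statistics tables for a study report
#'
#' @param alignment output of [compare_objectives()].
#' @param drivers output of [ensemble_drivers()] (full cohort).
#' @param sequence_result output of [sequence_drivers()].
#' @return list of compact summary tables (objective means and tests,
#'   weighted drivers, per-sequence reward-rate changes).
#' @export
report_stats <- function(alignment, drivers, sequence_result) {
  list(objective_means = alignment$means,
       objective_anova = alignment$anova,
       objective_pairwise = alignment$pairwise,
       weighted_drivers = drivers$weighted,
       sequence_delta_rr = sequence_result$delta_rr_summary,
       sequence_drivers = sequence_result$drivers)
}
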