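#!/usr/bin/env Rscript
# Run the staged two-armed-bandit learning sessions for every network in
# results/cohort/networks.csv: 15 learning trials with dopamine-dependent
# plasticity, frozen probe blocks after 0, 2, 4, 6 and 15 trials.
# Writes results/sessions/{trials.csv, rates.csv, weights.csv, stages.csv}.

library(cbgtpolicy)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
probe_trials <- 150L

cohort <- read.csv("results/cohort/networks.csv")
dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)

free <- setdiff(names(cohort),
                c("network", "net_seed", "timeout_fraction",
                  "cx_striatum_r", "mean_rt_ms"))
trials <- rates <- weights <- stages <- list()
for (i in cohort$network) {
  row <- cohort[cohort$network == i, ]
  eff <- unlist(row[free])
  net <- build_network(network_params(efficacies = eff,
                                      seed = row$net_seed))
  s <- run_session(net, plasticity_params(),
                   session_config(probe_trials_per_stage = probe_trials,
                                  seed = seed * 1000L + i))
  trials[[i]] <- cbind(network = i, s$trials)
  weights[[i]] <- cbind(network = i, s$weights)
  for (st in names(s$activity))
    rates[[paste(i, st)]] <- cbind(network = i, stage = as.integer(st),
                                   as.data.frame(s$activity[[st]]))
  ss <- session_stage_summary(s)
  stages[[i]] <- cbind(network = i, ss,
                       sequence = outcome_sequence(s))
  cat(sprintf("network %d: baseline acc %.2f -> final acc %.2f, RT %.0f -> %.0f ms (%s)\n",
              i, ss$accuracy[1], ss$accuracy[nrow(ss)],
              1000 * ss$mean_rt_s[1], 1000 * ss$mean_rt_s[nrow(ss)],
              outcome_sequence(s)))
}
write.csv(do.call(rbind, trials), "results/sessions/trials.csv", row.names = FALSE)
write.csv(do.call(rbind, rates), "results/sessions/rates.csv", row.names = FALSE)
write.csv(do.call(rbind, weights), "results/sessions/weights.csv", row.names = FALSE)
write.csv(do.call(rbind, stages), "results/sessions/stages.csv", row.names = FALSE)
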