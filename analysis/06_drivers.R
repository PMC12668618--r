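#!/usr/bin/env Rscript
# Decompose learning-induced firing-rate changes into control-ensemble
# drivers (least squares, normal equation) for the full cohort and for the
# four two-trial outcome sequences; summarize reward-rate changes per
# sequence. Writes results/drivers/*.csv.

library(cbgtpolicy)

rates <- read.csv("results/sessions/rates.csv")
stages <- read.csv("results/sessions/stages.csv")
cc <- readRDS("results/ensembles/ensembles.rds")
dir.create("results/drivers", recursive = TRUE, showWarnings = FALSE)

act_of <- function(df) {
  a <- df[, c("region", "channel", "rate")]
  class(a) <- c("cbgt_activity", "data.frame")
  a
}
ids <- sort(unique(rates$network))
last <- max(rates$stage)
get_F <- function(st) build_features(
  lapply(ids, function(i) act_of(rates[rates$network == i &
                                         rates$stage == st, ])),
  rewarded_channel = 1)

dF <- delta_features(get_F(last), get_F(0), cc)
k <- min(5, nrow(dF) - 1)
drv <- ensemble_drivers(dF, cc, k = k)
cat("variance explained by the", k, "PCs:",
    round(sum(drv$var_frac), 3), "\n")
cat("variance-weighted drivers:\n"); print(round(drv$weighted, 3))
write.csv(data.frame(ensemble = cc$labels, drv$S),
          "results/drivers/S_all.csv", row.names = FALSE)
write.csv(data.frame(ensemble = names(drv$weighted),
                     weighted = drv$weighted),
          "results/drivers/weighted_all.csv", row.names = FALSE)

# outcome-sequence analysis at the first freeze (after 2 trials)
dF2 <- delta_features(get_F(1), get_F(0), cc)
seqs <- stages$sequence[match(ids, stages$network)]
rr0 <- stages$reward_rate[stages$stage == 0][match(ids, stages$network[stages$stage == 0])]
rr1 <- stages$reward_rate[stages$stage == 1][match(ids, stages$network[stages$stage == 1])]
speed <- classify_speed(1000 * stages$mean_rt_s[stages$stage == 0])
sq <- sequence_drivers(dF2, seqs, rr1 - rr0, cc, speed_class = speed,
                       k = k, min_group = 3)
print(sq$delta_rr_summary)
write.csv(sq$delta_rr_summary, "results/drivers/sequence_delta_rr.csv",
          row.names = FALSE)
if (length(sq$drivers))
  write.csv(do.call(rbind, lapply(names(sq$drivers), function(nm)
    data.frame(sequence = nm, ensemble = names(sq$drivers[[nm]]),
               weighted = sq$drivers[[nm]]))),
    "results/drivers/sequence_drivers.csv", row.names = FALSE)
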