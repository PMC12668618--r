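#!/usr/bin/env Rscript
# Build RT / accuracy / reward-rate surfaces over the fitted (v, a) range and
# score each network's learning trajectory against the gradient of each
# objective. Writes results/manifold/{manifold.csv, distances.csv,
# summary.json}.

library(cbgtpolicy)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

fits <- read.csv("results/ddm/fits.csv")
dir.create("results/manifold", recursive = TRUE, showWarnings = FALSE)

pad <- function(x) c(min(x) - 0.3 * diff(range(x)) - 0.1,
                     max(x) + 0.3 * diff(range(x)) + 0.1)
vr <- pad(fits$v); ar <- pad(fits$a); ar[1] <- max(ar[1], 0.2)
m <- build_manifold(seq(vr[1], vr[2], length.out = 12),
                    seq(ar[1], ar[2], length.out = 12),
                    t0 = mean(fits$t0[fits$stage == 0]),
                    seeds = 5, trials = 200, dt = 1e-3, seed = seed)
grid_df <- expand.grid(v = m$v, a = m$a)
grid_df$rt <- as.vector(m$rt)
grid_df$accuracy <- as.vector(m$accuracy)
grid_df$reward_rate <- as.vector(m$reward_rate)
write.csv(grid_df, "results/manifold/manifold.csv", row.names = FALSE)

cmp <- compare_objectives(fits[, c("network", "stage", "v", "a")], m)
write.csv(cmp$distances, "results/manifold/distances.csv", row.names = FALSE)
cat("mean cosine distance per objective:\n")
print(round(cmp$means, 3))
cat(sprintf("repeated-measures F(%d, %d) = %.1f, p = %.2g\n",
            cmp$anova$df1, cmp$anova$df2, cmp$anova$F, cmp$anova$p_value))
jsonlite::write_json(
  list(means = as.list(cmp$means), anova = cmp$anova,
       pairwise = cmp$pairwise),
  "results/manifold/summary.json", auto_unbox = TRUE, digits = NA)
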