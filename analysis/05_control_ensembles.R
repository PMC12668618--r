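#!/usr/bin/env Rscript
# Identify the control ensembles: canonical correlation between baseline
# firing-rate features (16 columns) and fitted DDM parameters (a, t, v),
# with k-fold validation and a shuffle null. NOTE: at the desk-scale cohort
# size (~10 networks) the CCA is under-determined and the loadings are
# illustrative; the estimator itself is validated on synthetic cohorts of
# 300 rows in the test suite. Writes results/ensembles/loadings.csv.

library(cbgtpolicy)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

rates <- read.csv("results/sessions/rates.csv")
fits <- read.csv("results/ddm/fits.csv")
dir.create("results/ensembles", recursive = TRUE, showWarnings = FALSE)

act_of <- function(df) {
  a <- df[, c("region", "channel", "rate")]
  class(a) <- c("cbgt_activity", "data.frame")
  a
}
ids <- sort(unique(rates$network))
base_act <- lapply(ids, function(i)
  act_of(rates[rates$network == i & rates$stage == 0, ]))
F_base <- build_features(base_act)
base <- fits[fits$stage == 0, ]
D_base <- as.matrix(base[order(base$network), c("a", "t0", "v")])
colnames(D_base) <- c("a", "t", "v")

cc <- fit_cca(F_base, D_base, k_folds = 4, n_shuffles = 50, seed = seed)
print(cc)
write.csv(data.frame(feature = feature_names(), cc$u),
          "results/ensembles/loadings.csv", row.names = FALSE)
saveRDS(cc, "results/ensembles/ensembles.rds")
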