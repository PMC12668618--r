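# Shared fixtures built in code at test time.

# A fake trial object with known rate traces, for summarize_activity tests
# without running the spiking simulator.
fake_trial <- function(net, rates_by_label, n_bins = 20) {
  m <- matrix(0, n_bins, length(net$slot_label),
              dimnames = list(NULL, net$slot_label))
  for (lab in names(rates_by_label)) m[, lab] <- rates_by_label[[lab]]
  structure(list(rate_traces = m, network = net, choice = 1L,
                 decision_time = n_bins * net$bin_ms, timeout = FALSE),
            class = "cbgt_trial")
}

# Activity table with specified per-(region, channel) rates, for
# build_features tests.
fake_activity <- function(rates) {
  regions <- c("Cx", "CxI", "FSI", "dSPN", "iSPN", "GPe", "STN", "GPi",
               "Thal")
  split_r <- setdiff(regions, c("CxI", "FSI"))
  df <- rbind(
    data.frame(region = rep(split_r, each = 2), channel = rep(1:2, 7)),
    data.frame(region = c("CxI", "FSI"), channel = NA_integer_))
  df$rate <- 0
  for (nm in names(rates)) {
    parts <- strsplit(nm, "\\.")[[1]]
    ch <- if (length(parts) == 2) as.integer(parts[2]) else NA_integer_
    sel <- df$region == parts[1] &
      (is.na(ch) | (!is.na(df$channel) & df$channel == ch))
    df$rate[sel] <- rates[[nm]]
  }
  class(df) <- c("cbgt_activity", "data.frame")
  df
}

# The default network is moderately expensive to build; share one per run.
shared_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(network_params(seed = 3))
    net
  }
})
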