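#' @title Genetic-algorithm sampling of network configurations
#' @name ga_search
#' @description
#' Free synaptic-efficacy parameters are discretized onto endpoint-inclusive
#' grids (30 points by default); a genome is the vector of grid indices, so
#' mating and mutation can never leave the declared ranges. Candidates are
#' simulated with plasticity off and accepted when (a) fewer than 1% of
#' trials time out and (b) the Pearson correlation between summed excitatory
#' cortical activity and summed SPN activity is positive (the network is
#' basal-ganglia driven, not cortico-thalamic driven); firing-rate range
#' checks against a configurable physiological table are recorded alongside.
NULL

#' Evenly spaced grid over a closed parameter range
#'
#' @param lower,upper range endpoints (`lower < upper`).
#' @param n_points number of grid values including both endpoints.
#' @export
grid_values <- function(lower, upper, n_points = 30L) {
  stopifnot(lower < upper, n_points >= 2)
  seq(lower, upper, length.out = n_points)
}

#' Default free-parameter grid for the GA
#'
#' The free subset covers the corticostriatal, striatopallidal,
#' pallido-subthalamic, subthalamo-pallidal, pallido-nigral and
#' thalamocortical efficacies, each spanning a multiplicative band around the
#' default efficacy table.
#' @param n_points grid points per parameter.
#' @param span multiplicative half-band (range = default * (1 -/+ span)).
#' @export
default_parameter_grid <- function(n_points = 30L, span = 0.3) {
  free <- c("cx_dspn", "cx_ispn", "ispn_gpe", "dspn_gpi", "gpe_stn",
            "stn_gpe", "stn_gpi", "gpe_gpi", "thal_cx")
  proj <- default_projection_efficacies()
  base <- proj$efficacy[match(free, proj$name)]
  g <- data.frame(name = free, lower = base * (1 - span),
                  upper = base * (1 + span), n_points = as.integer(n_points))
  class(g) <- c("cbgt_parameter_grid", "data.frame")
  g
}

#' Decode a genome of grid indices into parameter values
#'
#' @param genome integer indices, one per grid row, each in
#'   `[0, n_points - 1]` (0-based, as bin pointers).
#' @param grid a data.frame with `name`, `lower`, `upper`, `n_points`.
#' @export
ga_decode <- function(genome, grid) {
  stopifnot(length(genome) == nrow(grid))
  vals <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (genome[i] < 0 || genome[i] > grid$n_points[i] - 1 ||
        genome[i] != round(genome[i]))
      stop("index out of range for parameter ", grid$name[i])
    vals[i] <- grid_values(grid$lower[i], grid$upper[i],
                           grid$n_points[i])[genome[i] + 1L]
  }
  names(vals) <- grid$name
  vals
}

#' One-point crossover of two genomes
#'
#' Offspring exchange the segments after `point` (`point = 0` swaps whole
#' genomes); in the evolutionary loop offspring overwrite their parents.
#' @param parent1,parent2 integer genomes. @param point crossover position in
#'   `0:(length - 1)`.
#' @return list of two offspring.
#' @export
ga_mate <- function(parent1, parent2, point) {
  stopifnot(length(parent1) == length(parent2),
            point >= 0, point <= length(parent1))
  if (point == 0 || point == length(parent1))
    return(list(parent2, parent1))
  head1 <- seq_len(point)
  list(c(parent1[head1], parent2[-head1]),
       c(parent2[head1], parent1[-head1]))
}

#' Genome mutation: index shuffling plus occasional value resets
#'
#' With probability `p` the genome's index positions are randomly permuted
#' (values stay valid grid indices because only positions move). In
#' addition, each locus is reset to a uniform random grid index with
#' probability `reset_p`: shuffling alone can never introduce an index value
#' absent from the founding population, so a sampler that must keep
#' discovering new configurations needs a value-level exploration operator
#' (the role played by the blending crossover in other implementations).
#' @param genome integer genome. @param p shuffle probability.
#' @param reset_p per-locus uniform reset probability.
#' @param n_points grid sizes per locus (required when `reset_p > 0`).
#' @export
ga_mutate <- function(genome, p = 0.2, reset_p = 0, n_points = NULL) {
  if (length(genome) > 1 && runif(1) < p)
    genome <- genome[sample.int(length(genome))]
  if (reset_p > 0) {
    stopifnot(length(n_points) == length(genome))
    hit <- runif(length(genome)) < reset_p
    if (any(hit))
      genome[hit] <- vapply(n_points[hit], function(np)
        sample.int(np, 1) - 1L, integer(1))
  }
  genome
}

#' Default physiological firing-rate ranges (Hz) per region
#'
#' Reconstructed acceptance bands for trial-averaged rates; configurable.
#' @export
default_rate_ranges <- function() {
  rbind(Cx = c(0.5, 40), CxI = c(0.5, 50), FSI = c(1, 60),
        dSPN = c(0.1, 40), iSPN = c(0.1, 40), GPe = c(10, 120),
        STN = c(2, 60), GPi = c(20, 150), Thal = c(0.5, 60))
}

#' Evaluate one candidate configuration
#'
#' Simulates probe trials with plasticity off and scores the candidate on
#' timeout fraction, corticostriatal correlation (Pearson r between binned
#' summed excitatory cortical rate and binned summed dSPN+iSPN rate, pooled
#' over trials), and per-region rate-range checks.
#' @param efficacies named vector of free-parameter values ([ga_decode()]).
#' @param n_trials probe-trial budget.
#' @param rate_ranges matrix as [default_rate_ranges()].
#' @param seed evaluation seed.
#' @param net_seed connectivity seed for the candidate network.
#' @return list: `timeout_fraction`, `cx_striatum_correlation`,
#'   `rate_range_ok` (per region), `accept`, `mean_rates`, `mean_rt_ms`.
#' @export
ga_evaluate <- function(efficacies, n_trials = 40,
                        rate_ranges = default_rate_ranges(),
                        seed = 1L, net_seed = 1L) {
  params <- network_params(efficacies = efficacies, seed = net_seed)
  net <- build_network(params)
  set.seed(seed)
  trials <- vector("list", n_trials)
  cx <- spn <- list()
  for (i in seq_len(n_trials)) {
    tr <- simulate_trial(net)
    trials[[i]] <- tr
    rt <- tr$rate_traces
    cx[[i]] <- rowSums(rt[, c("Cx1", "Cx2"), drop = FALSE])
    spn[[i]] <- rowSums(rt[, c("dSPN1", "dSPN2", "iSPN1", "iSPN2"),
                           drop = FALSE])
  }
  timeouts <- vapply(trials, function(t) t$timeout, logical(1))
  cxv <- unlist(cx); spnv <- unlist(spn)
  corr <- if (sd(cxv) == 0 || sd(spnv) == 0) 0 else cor(cxv, spnv)
  act <- summarize_activity(trials)
  # per-region rate averaged over channels
  reg_rate <- tapply(act$rate, act$region, mean)
  ok <- vapply(rownames(rate_ranges), function(r) {
    rr <- reg_rate[[r]]
    is.finite(rr) && rr >= rate_ranges[r, 1] && rr <= rate_ranges[r, 2]
  }, logical(1))
  rts <- vapply(trials, function(t)
    if (t$timeout) NA_real_ else t$decision_time, numeric(1))
  list(timeout_fraction = mean(timeouts),
       cx_striatum_correlation = corr,
       rate_range_ok = ok,
       accept = mean(timeouts) < 0.01 && corr > 0 && all(ok),
       mean_rates = reg_rate,
       mean_rt_ms = mean(rts, na.rm = TRUE))
}

#' Evolve a population of genomes and archive acceptable configurations
#'
#' Tournament selection (best of `tournament_size` by lexicographic fitness:
#' lower timeout fraction first, then higher corticostriatal correlation)
#' builds each generation; selected genomes are then mated pairwise by
#' one-point crossover (offspring overwrite parents) and mutated by index
#' shuffling. Every evaluated candidate meeting the acceptance criteria is
#' archived; evolution stops at `target_solutions` accepted networks or
#' `max_iter` generations, whichever comes first.
#'
#' @param grid parameter grid ([default_parameter_grid()]).
#' @param population_size genomes per generation. @param tournament_size
#'   tournament draw. @param mutation_p shuffle probability. @param reset_p
#'   per-locus value-reset probability (see [ga_mutate()]). @param cx_p
#'   crossover probability per adjacent pair.
#' @param max_iter generation cap. @param target_solutions archive size goal.
#' @param n_trials probe trials per evaluation.
#' @param rate_ranges physiological table. @param seed master seed.
#' @param evaluate evaluation function (swappable for surrogate fitness in
#'   tests); must accept `(values, n_trials, rate_ranges, seed, net_seed)`
#'   and return a [ga_evaluate()]-shaped list.
#' @return list: `accepted` (list of named efficacy vectors with fitness
#'   records and the seeds to rebuild each network), `n_generations`,
#'   `n_evaluated`.
#' @export
ga_evolve <- function(grid = default_parameter_grid(),
                      population_size = 10, tournament_size = 3,
                      mutation_p = 0.2, reset_p = 0.1, cx_p = 0.5,
                      max_iter = 2000, target_solutions = 300,
                      n_trials = 40, rate_ranges = default_rate_ranges(),
                      seed = 1L, evaluate = ga_evaluate) {
  set.seed(seed)
  npar <- nrow(grid)
  pop <- lapply(seq_len(population_size), function(i)
    vapply(grid$n_points, function(np) sample.int(np, 1) - 1L, integer(1)))
  accepted <- list()
  n_eval <- 0L
  gen <- 0L
  seen <- new.env(hash = TRUE)
  while (gen < max_iter && length(accepted) < target_solutions) {
    gen <- gen + 1L
    fits <- vector("list", population_size)
    for (i in seq_len(population_size)) {
      key <- paste(pop[[i]], collapse = ",")
      ev_seed <- derive_seed(seed, paste0("eval", gen, "_", i))
      fits[[i]] <- evaluate(ga_decode(pop[[i]], grid), n_trials,
                            rate_ranges, seed = ev_seed,
                            net_seed = derive_seed(seed, key))
      n_eval <- n_eval + 1L
      if (isTRUE(fits[[i]]$accept) && is.null(seen[[key]]) &&
          length(accepted) < target_solutions) {
        seen[[key]] <- TRUE
        accepted[[length(accepted) + 1L]] <- list(
          genome = pop[[i]], values = ga_decode(pop[[i]], grid),
          fitness = fits[[i]], net_seed = derive_seed(seed, key))
      }
    }
    if (length(accepted) >= target_solutions) break
    # lexicographic tournament selection
    better <- function(i, j) {
      if (fits[[i]]$timeout_fraction != fits[[j]]$timeout_fraction)
        fits[[i]]$timeout_fraction < fits[[j]]$timeout_fraction
      else fits[[i]]$cx_striatum_correlation >
        fits[[j]]$cx_striatum_correlation
    }
    newpop <- vector("list", population_size)
    for (i in seq_len(population_size)) {
      cand <- sample.int(population_size, tournament_size, replace = TRUE)
      bi <- cand[1]
      for (ci in cand[-1]) if (better(ci, bi)) bi <- ci
      newpop[[i]] <- pop[[bi]]
    }
    # pairwise one-point crossover; offspring overwrite parents
    for (i in seq(1, population_size - 1, by = 2)) {
      if (runif(1) < cx_p) {
        off <- ga_mate(newpop[[i]], newpop[[i + 1]],
                       sample.int(npar, 1) - 1L)
        newpop[[i]] <- off[[1]]; newpop[[i + 1]] <- off[[2]]
      }
    }
    pop <- lapply(newpop, ga_mutate, p = mutation_p, reset_p = reset_p,
                  n_points = grid$n_points)
  }
  if (!length(accepted) && target_solutions > 0)
    warning("no acceptable configuration found within max_iter generations")
  list(accepted = accepted, n_generations = gen, n_evaluated = n_eval)
}
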