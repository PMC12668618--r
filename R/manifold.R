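#' @title Decision-policy manifolds and gradient alignment
#' @name policy_manifold
#' @description
#' Surfaces of mean RT, accuracy, and reward rate over a grid of drift rates
#' `v` and boundary heights `a` (with `t0` and `z` fixed, typically at cohort
#' baseline means), used to ask which behavioral objective the learning
#' trajectories of fitted `(v, a)` points align with. Alignment is scored as
#' the cosine distance between each observed per-stage displacement and the
#' local gradient of each objective.
NULL

#' Reward rate from accuracy and mean reaction time
#'
#' `RR = (1 - p(err)) / RT`, with RT the mean reaction time (decision time
#' plus non-decision time) in seconds.
#' @param accuracy fraction correct. @param rt mean RT (s), positive.
#' @export
reward_rate <- function(accuracy, rt) {
  if (any(rt <= 0)) stop("rt must be positive")
  accuracy / rt
}

#' Build RT / accuracy / reward-rate surfaces over a (v, a) grid
#'
#' Each node is estimated by DDM simulation averaged over `seeds` independent
#' replicates of `trials` trials.
#' @param v_grid,a_grid ordered grid values.
#' @param t0,z,sigma fixed DDM parameters for all nodes.
#' @param seeds replicates per node. @param trials trials per replicate.
#' @param dt simulation step (s). @param seed master seed.
#' @return a `cbgt_manifold`: matrices `rt`, `accuracy`, `reward_rate`
#'   (rows = v, cols = a) plus the grids.
#' @export
build_manifold <- function(v_grid, a_grid, t0 = 0.25, z = 0.5, sigma = 1,
                           seeds = 15, trials = 200, dt = 1e-3, seed = 1L) {
  stopifnot(!is.unsorted(v_grid), !is.unsorted(a_grid))
  nv <- length(v_grid); na <- length(a_grid)
  rt <- acc <- matrix(NA_real_, nv, na)
  set.seed(seed)
  for (i in seq_len(nv)) for (j in seq_len(na)) {
    accs <- rts <- numeric(seeds)
    for (s in seq_len(seeds)) {
      b <- simulate_ddm(ddm_params(v_grid[i], a_grid[j], t0, z, sigma),
                        n = trials, dt = dt)
      accs[s] <- mean(b$choice == "upper")
      rts[s] <- mean(b$rt)
    }
    acc[i, j] <- mean(accs); rt[i, j] <- mean(rts)
  }
  structure(list(v = v_grid, a = a_grid, rt = rt, accuracy = acc,
                 reward_rate = acc / rt,
                 t0 = t0, z = z, sigma = sigma),
            class = "cbgt_manifold")
}

# moving-average smoothing of a surface with a k x k box kernel (edge-padded)
smooth_surface <- function(m, k = 3) {
  if (k <= 1) return(m)
  half <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    rj <- max(1, j - half):min(nc, j + half)
    out[i, j] <- mean(m[ri, rj], na.rm = TRUE)
  }
  out
}

#' Gradient of a manifold objective at a point
#'
#' Central finite differences on the (optionally smoothed) surface, bilinearly
#' interpolated to the query point. The sign convention points in the
#' direction of objective improvement, so the RT gradient is negated (faster
#' responses are better).
#' @param manifold a `cbgt_manifold`.
#' @param objective `"rt"`, `"accuracy"` or `"reward_rate"`.
#' @param point `c(v, a)` inside the grid hull.
#' @param smooth_k box-kernel width in nodes (default 3).
#' @return length-2 gradient `(d/dv, d/da)`.
#' @export
gradient_at <- function(manifold, objective = c("reward_rate", "accuracy",
                                                "rt"),
                        point, smooth_k = 3) {
  objective <- match.arg(objective)
  v <- manifold$v; a <- manifold$a
  if (point[1] < min(v) || point[1] > max(v) ||
      point[2] < min(a) || point[2] > max(a))
    stop("point outside the grid hull")
  s <- smooth_surface(manifold[[objective]], smooth_k)
  nv <- length(v); na <- length(a)
  # node-wise central differences
  gv <- matrix(NA_real_, nv, na); ga <- matrix(NA_real_, nv, na)
  for (i in seq_len(nv)) {
    i0 <- max(1, i - 1); i1 <- min(nv, i + 1)
    gv[i, ] <- (s[i1, ] - s[i0, ]) / (v[i1] - v[i0])
  }
  for (j in seq_len(na)) {
    j0 <- max(1, j - 1); j1 <- min(na, j + 1)
    ga[, j] <- (s[, j1] - s[, j0]) / (a[j1] - a[j0])
  }
  interp <- function(m) {
    i <- findInterval(point[1], v, all.inside = TRUE)
    j <- findInterval(point[2], a, all.inside = TRUE)
    fx <- (point[1] - v[i]) / (v[i + 1] - v[i])
    fy <- (point[2] - a[j]) / (a[j + 1] - a[j])
    (1 - fx) * (1 - fy) * m[i, j] + fx * (1 - fy) * m[i + 1, j] +
      (1 - fx) * fy * m[i, j + 1] + fx * fy * m[i + 1, j + 1]
  }
  g <- c(interp(gv), interp(ga))
  if (objective == "rt") -g else g
}

#' Cosine distance between an observed step and a reference direction
#'
#' `1 - cos(angle)`, in `[0, 2]`; invariant to positive rescaling of either
#' vector (the reference is conventionally rescaled to the observed step
#' length for display, which does not change the distance).
#' @param step,reference nonzero 2-vectors.
#' @export
cosine_distance <- function(step, reference) {
  ns <- sqrt(sum(step^2)); nr <- sqrt(sum(reference^2))
  if (ns == 0 || nr == 0) stop("vectors must be nonzero")
  1 - sum(step * reference) / (ns * nr)
}

#' Score learning trajectories against each behavioral objective
#'
#' For every network and consecutive stage pair, computes the cosine distance
#' between the observed `(v, a)` displacement and the gradient (at the step's
#' start point) of each objective surface, then summarizes with a one-way
#' repeated-measures F-test across objectives and paired t-tests between
#' objective pairs.
#'
#' @param trajectories data.frame with columns `network`, `stage`, `v`, `a`
#'   (one row per fitted stage, stages ordered within network).
#' @param manifold a `cbgt_manifold` covering the fitted range.
#' @param smooth_k smoothing width passed to [gradient_at()].
#' @return list: `distances` (long data.frame network/stage/objective/
#'   distance), `anova` (repeated-measures F over the three objectives),
#'   `pairwise` (paired t-tests), `means` (per-objective mean distance).
#' @export
compare_objectives <- function(trajectories, manifold, smooth_k = 3) {
  stopifnot(all(c("network", "stage", "v", "a") %in% names(trajectories)))
  objs <- c("rt", "accuracy", "reward_rate")
  rows <- list()
  for (id in unique(trajectories$network)) {
    tj <- trajectories[trajectories$network == id, ]
    tj <- tj[order(tj$stage), ]
    if (nrow(tj) < 2) next
    for (k in seq_len(nrow(tj) - 1)) {
      step <- c(tj$v[k + 1] - tj$v[k], tj$a[k + 1] - tj$a[k])
      if (all(step == 0)) next
      start <- c(tj$v[k], tj$a[k])
      # clamp the evaluation point into the grid hull
      start[1] <- min(max(start[1], min(manifold$v)), max(manifold$v))
      start[2] <- min(max(start[2], min(manifold$a)), max(manifold$a))
      for (ob in objs) {
        g <- gradient_at(manifold, ob, start, smooth_k)
        if (all(g == 0)) next
        rows[[length(rows) + 1L]] <- data.frame(
          network = id, stage = tj$stage[k + 1], objective = ob,
          distance = cosine_distance(step, g))
      }
    }
  }
  if (!length(rows)) stop("no usable trajectory steps")
  d <- do.call(rbind, rows)
  d$objective <- factor(d$objective, levels = objs)
  # pool steps: one observation per (network, stage, objective)
  d$unit <- interaction(d$network, d$stage)
  wide <- stats::reshape(d[, c("unit", "objective", "distance")],
                         idvar = "unit", timevar = "objective",
                         direction = "wide")
  wide <- wide[complete.cases(wide), ]
  an <- repeated_measures_anova(as.matrix(wide[, -1]))
  pw <- list()
  combs <- utils::combn(objs, 2, simplify = FALSE)
  for (cmb in combs) {
    x <- wide[[paste0("distance.", cmb[1])]]
    y <- wide[[paste0("distance.", cmb[2])]]
    tt <- t.test(x, y, paired = TRUE)
    pw[[paste(cmb, collapse = "_vs_")]] <-
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, mean_diff = unname(tt$estimate))
  }
  means <- tapply(d$distance, d$objective, mean)
  list(distances = d[, c("network", "stage", "objective", "distance")],
       anova = an, pairwise = pw, means = means)
}

# one-way repeated-measures ANOVA from closed-form sums of squares;
# rows = subjects (network-steps), cols = conditions (objectives)
repeated_measures_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  # a literally zero condition effect gives 0/0; define F = 0 there
  f <- if (ss_cond <= 1e-12 * max(ss_tot, .Machine$double.xmin)) 0
       else (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}
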