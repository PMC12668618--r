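#' @title Drivers of control-ensemble modulation during learning
#' @name driver_analysis
#' @description
#' Learning-induced firing-rate changes `dF` (post- minus pre-learning
#' feature rows, expressed in the standardized baseline feature space) are
#' summarized by their top principal components `V`; `dF` is projected both
#' onto the PCs (`P = dF V`) and onto the baseline control-ensemble feature
#' loadings (`C = dF U`). The driver matrix `S = (C'C)^-1 C'P` is the least
#' squares expression of each firing-rate PC as a combination of
#' control-ensemble adjustments; the per-ensemble net effect is the sum of
#' the columns of `S` weighted by each PC's explained-variance fraction.
NULL

#' Standardize firing-rate-change rows into the baseline feature space
#'
#' @param post,pre feature matrices (networks x 16) on the raw Hz scale.
#' @param ensembles the baseline `cbgt_ensembles` (provides the recorded
#'   standardization scales; changes are divided by the baseline feature
#'   scale so all stages share one basis).
#' @export
delta_features <- function(post, pre, ensembles) {
  stopifnot(all(dim(post) == dim(pre)))
  sweep(post - pre, 2, ensembles$scale_F, "/")
}

#' Top-k principal components of the firing-rate changes
#'
#' @param delta networks x features matrix. @param k components (default 5).
#' @return list: `V` (features x k orthonormal loadings, each oriented so
#'   the cohort's mean change projects non-negatively onto it), `var_frac`
#'   (explained-variance fractions).
#' @export
pca_delta <- function(delta, k = 5) {
  stopifnot(nrow(delta) > k)
  pc <- prcomp(delta, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  # fix the sign ambiguity of each PC by aligning it with the cohort's mean
  # change (falling back to a largest-loading convention when orthogonal),
  # so driver signs are comparable across cohorts and outcome groups
  m <- colMeans(delta)
  for (j in seq_len(k)) {
    s_j <- sum(m * V[, j])
    if (abs(s_j) < 1e-12) s_j <- V[which.max(abs(V[, j])), j]
    if (s_j < 0) V[, j] <- -V[, j]
  }
  list(V = V, var_frac = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Project firing-rate changes onto PCs and control ensembles
#'
#' @param delta networks x 16 matrix. @param V 16 x k PC loadings.
#' @param U 16 x 3 baseline control-ensemble feature loadings.
#' @return list `P` (networks x k) and `C` (networks x 3).
#' @export
project_delta <- function(delta, V, U) {
  stopifnot(ncol(delta) == nrow(V), ncol(delta) == nrow(U))
  list(P = delta %*% V, C = delta %*% U)
}

#' Least-squares driver matrix from the normal equation
#'
#' `S = (C'C)^-1 C'P`: `C S` is the closest point to `P` in the range of
#' `C`. An ill-conditioned Gram matrix (condition number above `max_kappa`)
#' triggers a flagged pseudo-inverse fallback.
#' @param P networks x k PC projections. @param C networks x 3 ensemble
#'   projections. @param max_kappa condition-number threshold.
#' @return 3 x k matrix with attributes `kappa` and `pseudo_inverse`.
#' @export
solve_drivers <- function(P, C, max_kappa = 1e10) {
  stopifnot(nrow(P) == nrow(C))
  G <- crossprod(C)
  kap <- kappa(G, exact = TRUE)
  if (kap > max_kappa) {
    warning("ill-conditioned C'C (condition number ", format(kap),
            "); using pseudo-inverse")
    sv <- svd(C)
    pos <- sv$d > max(sv$d) * 1e-12
    S <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% P) / sv$d[pos])
  } else {
    S <- solve(G, crossprod(C, P))
  }
  attr(S, "kappa") <- kap
  attr(S, "pseudo_inverse") <- kap > max_kappa
  S
}

#' Variance-weighted net driver per control ensemble
#'
#' Sums the columns of `S`, each scaled by its PC's explained-variance
#' fraction.
#' @param S 3 x k driver matrix. @param var_frac length-k fractions.
#' @export
weighted_driver <- function(S, var_frac) {
  stopifnot(ncol(S) == length(var_frac))
  drop(S %*% var_frac)
}

#' Rank-correlation reconstruction check of the driver solution
#'
#' Reconstructs the PC projections as `C S` and reports the Spearman rank
#' correlation between actual and reconstructed projections, per PC.
#' @param P,C,S as in [solve_drivers()].
#' @export
driver_reconstruction <- function(P, C, S) {
  Phat <- C %*% S
  vapply(seq_len(ncol(P)), function(j)
    suppressWarnings(cor(P[, j], Phat[, j], method = "spearman")),
    numeric(1))
}

#' Full driver decomposition for one cohort (optionally class-restricted)
#'
#' @param delta networks x 16 firing-rate-change matrix (standardized
#'   baseline space, [delta_features()]).
#' @param ensembles baseline `cbgt_ensembles` fit on the full cohort (its
#'   feature loadings `U` are used even for class-restricted cohorts).
#' @param k PCs to keep (always 5 by convention, for comparability across
#'   classes).
#' @return list: `S`, `V`, `var_frac`, `P`, `C`, `weighted`
#'   (per-ensemble net driver), `reconstruction_rho`.
#' @export
ensemble_drivers <- function(delta, ensembles, k = 5) {
  pc <- pca_delta(delta, k)
  pr <- project_delta(delta, pc$V, ensembles$u)
  S <- solve_drivers(pr$P, pr$C)
  w <- weighted_driver(S, pc$var_frac)
  names(w) <- ensembles$labels %||% paste0("ens", seq_len(ncol(ensembles$u)))
  list(S = S, V = pc$V, var_frac = pc$var_frac, P = pr$P, C = pr$C,
       weighted = w, reconstruction_rho = driver_reconstruction(pr$P, pr$C, S))
}

#' Drivers and reward-rate changes grouped by two-trial outcome sequence
#'
#' Groups networks by the outcome labels of their first two learning trials
#' (U-U, U-R, R-U, R-R), recomputes the driver decomposition per group from
#' the stage-2 firing-rate changes, and summarizes the change in reward rate
#' from the naive baseline with a two-way ANOVA (sequence x speed class) and
#' pairwise t-tests.
#'
#' @param delta networks x 16 change matrix (baseline to the 2-trial freeze).
#' @param sequences character vector of outcome labels per network.
#' @param delta_rr per-network reward-rate change (post-freeze minus
#'   baseline).
#' @param ensembles baseline `cbgt_ensembles`.
#' @param speed_class optional factor (fast/intermediate/slow) per network.
#' @param k PCs per group. @param min_group minimum group size (smaller
#'   groups are flagged and skipped).
#' @return list: per-sequence `drivers` (weighted 3-vectors), `flagged`
#'   (undersized groups), `delta_rr_summary`, `anova`, `pairwise_t`.
#' @export
sequence_drivers <- function(delta, sequences, delta_rr, ensembles,
                             speed_class = NULL, k = 5, min_group = 5) {
  stopifnot(nrow(delta) == length(sequences),
            length(delta_rr) == length(sequences))
  seq_levels <- c("U-U", "U-R", "R-U", "R-R")
  drivers <- list(); flagged <- character(0)
  for (sq in seq_levels) {
    idx <- sequences == sq
    if (sum(idx) < max(min_group, k + 2)) {
      if (sum(idx) > 0) flagged <- c(flagged, sq)
      next
    }
    drivers[[sq]] <- ensemble_drivers(delta[idx, , drop = FALSE],
                                      ensembles, k)$weighted
  }
  rrs <- split(delta_rr, factor(sequences, levels = seq_levels))
  rr_summary <- data.frame(
    sequence = seq_levels,
    n = vapply(rrs, length, integer(1)),
    mean_delta_rr = vapply(rrs, function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1)),
    sd_delta_rr = vapply(rrs, function(x)
      if (length(x) > 1) sd(x) else NA_real_, numeric(1)))
  an <- NULL
  present <- sequences %in% seq_levels
  if (length(unique(sequences[present])) > 1 &&
      stats::var(delta_rr[present]) > 1e-20) {
    df <- data.frame(rr = delta_rr[present],
                     sequence = factor(sequences[present]))
    if (!is.null(speed_class)) {
      df$speed <- factor(speed_class[present])
      if (nlevels(droplevels(df$speed)) > 1)
        an <- summary(aov(rr ~ sequence * speed, data = df))
      else an <- summary(aov(rr ~ sequence, data = df))
    } else an <- summary(aov(rr ~ sequence, data = df))
  }
  pw <- list()
  for (i in seq_along(seq_levels)) for (j in seq_along(seq_levels)) {
    if (j <= i) next
    x <- rrs[[seq_levels[i]]]; y <- rrs[[seq_levels[j]]]
    if (length(x) > 1 && length(y) > 1 &&
        (stats::var(x) + stats::var(y)) > 1e-20) {
      tt <- t.test(x, y)
      pw[[paste(seq_levels[i], "vs", seq_levels[j])]] <-
        list(t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
    }
  }
  list(drivers = drivers, flagged = flagged, delta_rr_summary = rr_summary,
       anova = an, pairwise_t = pw)
}
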