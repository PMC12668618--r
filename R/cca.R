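#' @title Control ensembles via canonical correlation analysis
#' @name control_ensembles
#' @description
#' For a cohort of baseline networks, a 16-column firing-rate feature matrix
#' `F` (channel sums and aligned channel differences of the seven
#' channel-split regions, plus the shared CxI and FSI rates) is related to
#' the fitted DDM parameter matrix `D = (a, t, v)` by canonical correlation
#' analysis. The canonical components are the *control ensembles*:
#' `responsiveness` (boundary and onset loadings of the same sign),
#' `pliancy` (opposing boundary/onset loadings) and `choice` (dominated by
#' drift rate). Component count is selected by comparing held-out
#' correlations from k-fold validation against a row-shuffle null.
NULL

.feature_regions <- c("Cx", "dSPN", "iSPN", "GPe", "STN", "GPi", "Thal")

#' Canonical feature order of the 16-column firing-rate matrix
#' @export
feature_names <- function() {
  c(paste0(.feature_regions, "_sum"), paste0(.feature_regions, "_diff"),
    "CxI", "FSI")
}

#' Build the firing-rate feature matrix for a cohort
#'
#' Sums are `rate(ch1) + rate(ch2)`; differences are aligned as rewarded
#' minus unrewarded channel when `rewarded_channel` is given (the convention
#' for post-learning features) and `ch1 - ch2` otherwise (baseline).
#' @param activities list of [summarize_activity()] tables, one per network.
#' @param rewarded_channel optional integer (1/2) per network or scalar.
#' @return matrix networks x 16 with [feature_names()] columns.
#' @export
build_features <- function(activities, rewarded_channel = NULL) {
  if (inherits(activities, "cbgt_activity")) activities <- list(activities)
  n <- length(activities)
  if (!is.null(rewarded_channel) && length(rewarded_channel) == 1)
    rewarded_channel <- rep(rewarded_channel, n)
  out <- matrix(NA_real_, n, 16, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    act <- activities[[i]]
    for (r in .feature_regions) {
      r1 <- act$rate[act$region == r & act$channel == 1]
      r2 <- act$rate[act$region == r & act$channel == 2]
      sgn <- if (is.null(rewarded_channel) || rewarded_channel[i] == 1) 1 else -1
      out[i, paste0(r, "_sum")] <- r1 + r2
      out[i, paste0(r, "_diff")] <- sgn * (r1 - r2)
    }
    out[i, "CxI"] <- act$rate[act$region == "CxI"]
    out[i, "FSI"] <- act$rate[act$region == "FSI"]
  }
  out
}

# standardize columns, recording means/scales; zero-variance columns scale 1
standardize <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2, sd)
    scale[scale == 0] <- 1
  }
  structure(sweep(sweep(m, 2, center), 2, scale, "/"),
            center = center, scale = scale)
}

# Canonical correlation returning both the weight vectors (used to form
# canonical variates, e.g. on held-out rows) and the structure loadings
# (feature-variate correlations; the displayed/projected ensemble patterns,
# much more stable than the weights because no covariance inverse is
# involved). Columns are unit-norm; signs are fixed so the
# largest-|loading| feature entry of each component is positive.
# `reduce`: optional 16 x r projection applied to the feature block before
# cancor (PCA reduction for cohorts with fewer rows than features); weights
# are mapped back to the full feature space, structure loadings are always
# computed against the full features.
cca_core <- function(Fm, Dm, ncomp = min(ncol(Fm), ncol(Dm)),
                     reduce = NULL) {
  Fr <- if (is.null(reduce)) Fm else Fm %*% reduce
  cc <- cancor(Fr, Dm, xcenter = FALSE, ycenter = FALSE)
  k <- min(ncomp, ncol(cc$xcoef), ncol(cc$ycoef), length(cc$cor))
  uw <- cc$xcoef[seq_len(ncol(Fr)), seq_len(k), drop = FALSE]
  if (!is.null(reduce)) uw <- reduce %*% uw
  vw <- cc$ycoef[, seq_len(k), drop = FALSE]
  unit <- function(x) x / sqrt(sum(x^2))
  u <- matrix(NA_real_, ncol(Fm), k, dimnames = list(colnames(Fm), NULL))
  v <- matrix(NA_real_, ncol(Dm), k, dimnames = list(colnames(Dm), NULL))
  for (j in seq_len(k)) {
    uw[, j] <- unit(uw[, j]); vw[, j] <- unit(vw[, j])
    u[, j] <- unit(suppressWarnings(cor(Fm, Fm %*% uw[, j])))
    v[, j] <- unit(suppressWarnings(cor(Dm, Dm %*% vw[, j])))
    u[is.na(u[, j]), j] <- 0; v[is.na(v[, j]), j] <- 0
    if (u[which.max(abs(u[, j])), j] < 0) {
      u[, j] <- -u[, j]; uw[, j] <- -uw[, j]
      v[, j] <- -v[, j]; vw[, j] <- -vw[, j]
    }
  }
  list(u = u, v = v, u_weights = uw, v_weights = vw,
       rho = cc$cor[seq_len(k)])
}

# mean held-out canonical correlations over k folds
cca_holdout_rho <- function(Fm, Dm, k_folds, ncomp, fold_id,
                            reduce = NULL) {
  rhos <- matrix(NA_real_, k_folds, ncomp)
  r_eff <- if (is.null(reduce)) ncol(Fm) else ncol(reduce)
  for (f in seq_len(k_folds)) {
    tr <- fold_id != f
    if (sum(tr) <= r_eff + ncol(Dm)) next
    cc <- cca_core(Fm[tr, , drop = FALSE], Dm[tr, , drop = FALSE], ncomp,
                   reduce = reduce)
    pf <- Fm[!tr, , drop = FALSE] %*% cc$u_weights
    pd <- Dm[!tr, , drop = FALSE] %*% cc$v_weights
    for (j in seq_len(ncol(pf)))
      rhos[f, j] <- abs(cor(pf[, j], pd[, j]))
  }
  colMeans(rhos, na.rm = TRUE)
}

#' Fit the control-ensemble CCA with k-fold and shuffle-null validation
#'
#' Columns of both matrices are standardized (means/scales recorded for
#' reuse when projecting firing-rate changes). Held-out canonical
#' correlations from `k_folds`-fold validation are compared against a null
#' built by permuting the rows of `D`; components whose mean held-out
#' correlation exceeds the null mean + 2 SD are retained.
#'
#' @param F_mat networks x 16 feature matrix ([build_features()]).
#' @param D_mat networks x 3 policy matrix, columns `(a, t, v)`.
#' @param k_folds validation folds. @param n_shuffles null permutations.
#' @param seed RNG seed for folds and shuffles.
#' @return a `cbgt_ensembles` list: `u` (16 x k feature structure loadings:
#'   correlations between features and the canonical variate, unit-norm),
#'   `v` (3 x k policy structure loadings), `u_weights`/`v_weights` (the
#'   underlying canonical weight vectors), `rho`, `holdout_rho`,
#'   `null_mean`, `null_sd`,
#'   `n_selected`, standardization records, and `labels`
#'   (via [label_ensembles()] when 3 components are retained).
#' @export
fit_cca <- function(F_mat, D_mat, k_folds = 4, n_shuffles = 100, seed = 1L) {
  stopifnot(nrow(F_mat) == nrow(D_mat))
  if (is.null(colnames(D_mat))) colnames(D_mat) <- c("a", "t", "v")
  n <- nrow(F_mat)
  Fs <- standardize(F_mat); Ds <- standardize(D_mat)
  qrF <- qr(Fs)
  if (qrF$rank < ncol(F_mat)) {
    bad <- colnames(F_mat)[-qrF$pivot[seq_len(qrF$rank)]]
    warning("feature matrix is rank deficient (columns: ",
            paste(bad, collapse = ", "),
            "); components limited to its rank")
  }
  ncomp <- min(ncol(D_mat), qrF$rank)
  # small cohorts: reduce the feature block to leading PCs so each training
  # fold still has more rows than fitted dimensions
  r_max <- min(qrF$rank,
               floor(n * (k_folds - 1) / k_folds) - ncol(D_mat) - 2)
  r_max <- max(r_max, ncol(D_mat))
  reduce <- NULL
  if (r_max < ncol(F_mat)) {
    warning("cohort small relative to feature count; CCA fitted on the ",
            "leading ", r_max, " feature principal components")
    reduce <- prcomp(Fs, center = FALSE)$rotation[, seq_len(r_max),
                                                  drop = FALSE]
  }
  full <- cca_core(Fs, Ds, ncomp, reduce = reduce)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k_folds), length.out = n))
  hr <- cca_holdout_rho(Fs, Ds, k_folds, ncomp, fold_id, reduce = reduce)
  null_r <- matrix(NA_real_, n_shuffles, ncomp)
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(n)
    null_r[s, ] <- cca_holdout_rho(Fs, Ds[perm, , drop = FALSE],
                                   k_folds, ncomp, fold_id, reduce = reduce)
  }
  null_mean <- colMeans(null_r); null_sd <- apply(null_r, 2, sd)
  selected <- hr > null_mean + 2 * null_sd
  out <- list(u = full$u, v = full$v, u_weights = full$u_weights,
              v_weights = full$v_weights, rho = full$rho,
              holdout_rho = hr, null_mean = null_mean, null_sd = null_sd,
              selected = selected, n_selected = sum(selected),
              center_F = attr(Fs, "center"), scale_F = attr(Fs, "scale"),
              center_D = attr(Ds, "center"), scale_D = attr(Ds, "scale"))
  class(out) <- "cbgt_ensembles"
  if (ncomp == 3) out <- label_ensembles(out)
  out
}

#' Label canonical components as responsiveness / pliancy / choice
#'
#' `responsiveness`: boundary (`a`) and onset (`t`) policy loadings share
#' sign and dominate; `pliancy`: `a` and `t` loadings oppose in sign;
#' `choice`: the component is dominated by drift rate `v`. A component whose
#' pattern matches none of these is flagged `"unresolved"` rather than
#' forced.
#' @param ensembles a `cbgt_ensembles` with 3 components.
#' @export
label_ensembles <- function(ensembles) {
  v <- ensembles$v
  stopifnot(ncol(v) == 3)
  rn <- rownames(v) %||% c("a", "t", "v")
  a_l <- v[match("a", rn), ]; t_l <- v[match("t", rn), ]
  v_l <- v[match("v", rn), ]
  labs <- character(3)
  for (j in 1:3) {
    if (abs(v_l[j]) >= max(abs(a_l[j]), abs(t_l[j]))) labs[j] <- "choice"
    else if (sign(a_l[j]) == sign(t_l[j]) && a_l[j] != 0)
      labs[j] <- "responsiveness"
    else if (sign(a_l[j]) * sign(t_l[j]) < 0) labs[j] <- "pliancy"
    else labs[j] <- "unresolved"
  }
  ensembles$labels <- labs
  ensembles
}

#' @export
print.cbgt_ensembles <- function(x, ...) {
  cat("Control ensembles:", ncol(x$u), "components; canonical rho:",
      paste(round(x$rho, 3), collapse = ", "), "\n")
  if (!is.null(x$labels)) cat("labels:", paste(x$labels, collapse = ", "), "\n")
  cat("held-out rho:", paste(round(x$holdout_rho, 3), collapse = ", "),
      "| null mean + 2sd:",
      paste(round(x$null_mean + 2 * x$null_sd, 3), collapse = ", "), "\n")
  invisible(x)
}
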