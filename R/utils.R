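#' @useDynLib cbgtpolicy, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom cor sd prcomp cancor quantile optim
#'   aov t.test cor.test pt setNames integrate complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Used wherever a derived sub-seed must not
# perturb the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed derived from a master seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 1103515245 + h * 12345) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
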