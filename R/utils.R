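#' @importFrom rlang abort %||%
#' @importFrom stats pnorm sd var rnorm predict glm binomial coef quantile
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Ties in the scores are handled by midranks, giving the standard
#' trapezoidal AUC.
#'
#' @param scores numeric vector of predicted scores or probabilities.
#' @param labels binary vector (0/1 or logical) of true classes.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC needs both classes present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
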