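#' Derive a reproducible integer seed from labels
#'
#' Stable 32-bit polynomial hash of its arguments (coerced to character and
#' joined), used to give every draw, fit and fold in a sweep its own seed
#' without any seed bookkeeping files. The result is always in
#' `[0, 2^31 - 2]`.
#'
#' @param ... Values identifying the task (e.g. master seed, strategy, n,
#'   iteration). Coerced to character.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, "representative", 50, 3)
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population variance (divisor n), used for SMSE/EV per the package's
# evaluation conventions.
var_pop <- function(x) mean((x - mean(x))^2)

#' Area under the ROC curve from decision scores
#'
#' Rank-based (Mann-Whitney) AUC; ties receive midranks.
#'
#' @param scores Numeric decision scores, larger = more likely positive.
#' @param labels Logical or 0/1 vector, `TRUE`/1 for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
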