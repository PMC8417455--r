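#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Rank-based AUC (probability a positive outranks a negative).
#'
#' Equivalent to the Mann-Whitney U statistic divided by n1*n0; ties get
#' half credit.  Used for discrimination summaries of channel scores.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector, same length.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  keep <- is.finite(scores)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("rank_auc needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
assert_scalar_num <- function(x, name, lo = -Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lo && x <= lo)
    stop(sprintf("'%s' must be > %g (got %g)", name, lo, x), call. = FALSE)
  if (!strict_lo && x < lo)
    stop(sprintf("'%s' must be >= %g (got %g)", name, lo, x), call. = FALSE)
  invisible(x)
}
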