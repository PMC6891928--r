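#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' One global seed expands into per-test child seeds through a counter
#' scheme, so any single permutation test can be re-run independently.
#' Results stay below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param i counter (1, 2, ...).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483629)
}

#' Permutation p-value with the add-one convention
#'
#' `p = (#\{null at least as extreme as observed\} + 1) / (n_perm + 1)`,
#' which is never zero and respects the `1/(n_perm+1)` floor. The
#' two-sided value is `2 * min(lower, upper)`, capped at 1.
#'
#' @param observed observed statistic.
#' @param null_values vector of null statistics.
#' @param tail `"lower"`, `"upper"`, or `"two_sided"`.
#' @return p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(observed, null_values,
                        tail = c("lower", "upper", "two_sided")) {
  tail <- match.arg(tail)
  if (!length(null_values)) stop("`null_values` is empty")
  if (anyNA(null_values)) stop("`null_values` contains NA/NaN")
  n <- length(null_values)
  lo <- (sum(null_values <= observed) + 1) / (n + 1)
  up <- (sum(null_values >= observed) + 1) / (n + 1)
  switch(tail,
         lower = lo,
         upper = up,
         two_sided = min(1, 2 * min(lo, up)))
}

perm_result <- function(observed, null_values, tail, n_perm, seed,
                        statistic = "statistic", extra = list()) {
  res <- c(list(
    statistic = statistic,
    observed = observed,
    null_values = null_values,
    null_mean = mean(null_values),
    null_sd = stats::sd(null_values),
    p_value = perm_pvalue(observed, null_values, tail),
    tail = tail,
    n_perm = n_perm,
    seed = seed), extra)
  class(res) <- "perm_result"
  res
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s tail): observed = %.4g, null %.4g +/- %.4g, p = %.4g (n_perm = %d)\n",
              x$statistic, x$tail, x$observed, x$null_mean,
              ifelse(is.na(x$null_sd), 0, x$null_sd), x$p_value, x$n_perm))
  invisible(x)
}

#' Random re-splits of pooled samples
#'
#' Pools the two groups' sample identifiers and repeatedly re-partitions
#' them uniformly at random (without replacement) into groups of the
#' original sizes. This is the sample-reshuffling engine behind every
#' permutated-network and permutated-cohort null in the package.
#'
#' @param samplesA,samplesB identifier vectors for the two groups.
#' @param k number of re-splits.
#' @param seed integer seed.
#' @return List of `k` elements, each `list(A = ..., B = ...)`.
#' @export
resplit <- function(samplesA, samplesB, k, seed = NULL) {
  if (!length(samplesA) || !length(samplesB))
    stop("both groups must be non-empty")
  pool <- c(samplesA, samplesB)
  nA <- length(samplesA)
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      idx <- sample.int(length(pool), nA)
      list(A = pool[idx], B = pool[-idx])
    })
  })
}
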