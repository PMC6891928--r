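#' Variance-mean points for the power-law extensions
#'
#' Builds the `(m, V)` point cloud of the two community-level Taylor
#' power-law extensions:
#' * **Type I** (interindividual community heterogeneity): one point per
#'   sample; `m` is the mean abundance per taxon within the sample and `V`
#'   the variance of taxon abundances within the sample.
#' * **Type III** (heterogeneity of the mixed-species population): one
#'   point per taxon; `m` and `V` are the taxon's mean and variance across
#'   samples.
#'
#' Variances use the unbiased (n-1) denominator. Points with `m <= 0` or
#' `V <= 0` cannot enter a log-log fit; they are dropped and counted in
#' the `n_excluded` attribute.
#'
#' @param table counts-mode [otu_table()].
#' @param model_type `"I"` or `"III"`.
#' @return data.frame with columns `m`, `V` and attribute `n_excluded`.
#' @export
ple_points <- function(table, model_type = c("I", "III")) {
  model_type <- match.arg(model_type)
  stopifnot_counts(table, "ple_points")
  m0 <- table$counts
  if (model_type == "I") {
    if (ncol(m0) < 3) stop("Type-I PLE needs at least 3 samples")
    mu <- colMeans(m0)
    v <- (colSums(m0^2) - nrow(m0) * mu^2) / (nrow(m0) - 1)
    pts <- data.frame(m = mu, V = pmax(v, 0))
  } else {
    if (nrow(m0) < 3 || ncol(m0) < 2)
      stop("Type-III PLE needs at least 3 taxa and 2 samples")
    mu <- rowMeans(m0)
    v <- (rowSums(m0^2) - ncol(m0) * mu^2) / (ncol(m0) - 1)
    pts <- data.frame(m = mu, V = pmax(v, 0))
  }
  keep <- pts$m > 0 & pts$V > 0
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 3)
    stop("fewer than 3 usable (m > 0, V > 0) points remain")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# slope/intercept of log10(V) ~ log10(m) by least squares; fast path used
# inside permutation loops.
loglog_fit <- function(m, V) {
  x <- log10(m); y <- log10(V)
  vx <- sum((x - mean(x))^2)
  if (vx <= 0) stop("singular design: all m values identical")
  b <- sum((x - mean(x)) * (y - mean(y))) / vx
  a0 <- mean(y) - b * mean(x)
  res <- y - (a0 + b * x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 1 else 1 - sum(res^2) / tss
  list(intercept = a0, slope = b, r_squared = r2)
}

#' Fit a power law V = a * m^b
#'
#' Ordinary least squares of `log10(V)` on `log10(m)`; `a` is the
#' back-transformed intercept and `b` the slope (the heterogeneity
#' scaling parameter of the power-law extensions).
#'
#' @param points data.frame with columns `m`, `V` (positive), at least 3
#'   rows, e.g. from [ple_points()] or [generate_power_law_points()].
#' @param model_type label stored on the fit (`"I"` or `"III"`).
#' @return Object of class `ple_fit`: `a`, `b`, `r_squared`,
#'   `model_type`, `points`.
#' @export
fit_power_law <- function(points, model_type = "I") {
  pts <- points[points$m > 0 & points$V > 0, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points with m > 0 and V > 0")
  f <- loglog_fit(pts$m, pts$V)
  structure(list(a = 10^f$intercept, b = f$slope, r_squared = f$r_squared,
                 model_type = model_type, points = pts),
            class = "ple_fit")
}

#' @export
print.ple_fit <- function(x, ...) {
  cat(sprintf("Type-%s PLE fit: V = %.4g * m^%.4g  (R^2 = %.4f, n = %d)\n",
              x$model_type, x$a, x$b, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Permutation test for a between-cohort scaling-parameter difference
#'
#' The observed statistic is `|param(A) - param(B)|`. The null pools the
#' two cohorts' samples, re-splits them into groups of the original sizes
#' and refits; the p-value is the upper-tail add-one permutation p.
#'
#' @param tableA,tableB counts-mode cohort tables.
#' @param param_extractor function(table) -> numeric scalar; defaults to
#'   the Type-I PLE `b`. See [ple_b_extractor()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param max_fail_frac maximum tolerated fraction of permutations whose
#'   refit fails before the test aborts.
#' @return A `perm_result` with extra fields `paramA`, `paramB`,
#'   `n_failed`.
#' @export
compare_scaling_param <- function(tableA, tableB,
                                  param_extractor = ple_b_extractor("I"),
                                  n_perm = 1000, seed = 1L,
                                  max_fail_frac = 0.05) {
  stopifnot_counts(tableA, "compare_scaling_param")
  stopifnot_counts(tableB, "compare_scaling_param")
  pA <- param_extractor(tableA)
  pB <- param_extractor(tableB)
  observed <- abs(pA - pB)
  pooled <- cbind(tableA$counts, tableB$counts)
  colnames(pooled) <- make.unique(colnames(pooled))
  nA <- ncol(tableA$counts)
  n <- ncol(pooled)
  sub <- function(idx) otu_table(pooled[, idx, drop = FALSE], mode = "counts")
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n, nA)
      tryCatch(abs(param_extractor(sub(idx)) - param_extractor(sub(-idx))),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(null_values))
  if (n_failed > max_fail_frac * n_perm)
    stop(sprintf("%.1f%% of permutation refits failed (max %.1f%%)",
                 100 * n_failed / n_perm, 100 * max_fail_frac))
  res <- perm_result(observed, null_values[!is.na(null_values)], "upper",
                     n_perm, seed, statistic = "|param A - param B|",
                     extra = list(paramA = pA, paramB = pB,
                                  n_failed = n_failed))
  res
}

#' Parameter extractor: PLE scaling exponent b
#'
#' @param model_type `"I"` or `"III"`.
#' @return function(table) returning the fitted `b`.
#' @export
ple_b_extractor <- function(model_type = "I") {
  force(model_type)
  function(table) {
    pts <- ple_points(table, model_type)
    loglog_fit(pts$m, pts$V)$slope
  }
}

#' Diversity-area relationship curve by sample accumulation
#'
#' "Area" is the number of pooled subjects. For each of `n_orders` random
#' sample orderings the counts are pooled cumulatively and the Hill number
#' of order `q` computed at each accumulation level; the curve is the mean
#' diversity at each area over orderings.
#'
#' @param table an [otu_table()] with `>= 4` samples.
#' @param q diversity order.
#' @param n_orders number of random orderings averaged.
#' @param seed integer seed.
#' @return data.frame with columns `A` (1..n samples) and `D`.
#' @export
dar_curve <- function(table, q, n_orders = 100, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  n <- ncol(m)
  if (n < 4) stop("DAR accumulation needs at least 4 samples")
  acc <- with_seed(seed, {
    vapply(seq_len(n_orders), function(o) {
      ord <- sample.int(n)
      cum <- matrixStats_rowCumsum(m[, ord, drop = FALSE])
      vapply(seq_len(n), function(a) hill_number(cum[, a], q), numeric(1))
    }, numeric(n))
  })
  data.frame(A = seq_len(n), D = rowMeans(acc))
}

# cumulative row-wise sums across columns (taxa x samples -> pooled counts)
matrixStats_rowCumsum <- function(m) {
  t(apply(m, 1, cumsum))
}

#' Fit a diversity-area relationship model
#'
#' Power law (PL): `D = c * A^z`, fitted as OLS of `ln D` on `ln A`.
#' Power law with exponential cutoff (PLEC): `D = c * A^z * exp(d * A)`,
#' fitted as OLS of `ln D` on `(ln A, A)`; `d < 0` produces an eventual
#' decay that caps accruable diversity.
#'
#' @param points data.frame with columns `A >= 1` and `D > 0`, `>= 4` rows.
#' @param model `"PL"` or `"PLEC"`.
#' @param q diversity order label stored on the fit.
#' @return Object of class `dar_fit`: `c`, `z`, `d` (`NA` for PL),
#'   `r_squared`, `model`, `q`, `points`.
#' @export
fit_dar <- function(points, model = c("PL", "PLEC"), q = NA_real_) {
  model <- match.arg(model)
  pts <- points[points$A >= 1 & points$D > 0, , drop = FALSE]
  if (nrow(pts) < 4) stop("need at least 4 points with A >= 1 and D > 0")
  y <- log(pts$D)
  X <- if (model == "PL") cbind(1, log(pts$A)) else cbind(1, log(pts$A), pts$A)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) stop("singular design for DAR fit")
  beta <- qr.coef(qr_, y)
  fitvals <- as.numeric(X %*% beta)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 1 else 1 - sum((y - fitvals)^2) / tss
  structure(list(c = exp(beta[1]), z = beta[2],
                 d = if (model == "PLEC") beta[3] else NA_real_,
                 r_squared = r2, model = model, q = q, points = pts),
            class = "dar_fit")
}

#' @export
print.dar_fit <- function(x, ...) {
  if (x$model == "PL")
    cat(sprintf("DAR PL fit: D = %.4g * A^%.4g  (R^2 = %.4f)\n",
                x$c, x$z, x$r_squared))
  else
    cat(sprintf("DAR PLEC fit: D = %.4g * A^%.4g * exp(%.4g A)  (R^2 = %.4f)\n",
                x$c, x$z, x$d, x$r_squared))
  invisible(x)
}

#' Maximal accrual diversity from a PLEC fit
#'
#' For `D = c * A^z * exp(d A)` with `z > 0` and `d < 0`, diversity peaks
#' at `A_max = -z / d` with `D_max = c * A_max^z * exp(-z)`.
#'
#' @param fit a PLEC [fit_dar()] result with `d < 0` and `z > 0`.
#' @return List of class `mad_estimate`: `A_max` (subjects), `D_max`
#'   (effective species), `q`.
#' @export
dar_mad <- function(fit) {
  stopifnot(inherits(fit, "dar_fit"))
  if (fit$model != "PLEC") stop("MAD is defined for PLEC fits only")
  if (is.na(fit$d) || fit$d >= 0)
    stop("no finite maximum: the exponential term does not decay (d >= 0)")
  if (fit$z <= 0) stop("MAD requires z > 0")
  A_max <- -fit$z / fit$d
  D_max <- fit$c * A_max^fit$z * exp(-fit$z)
  structure(list(A_max = unname(A_max), D_max = unname(D_max), q = fit$q),
            class = "mad_estimate")
}

#' @export
print.mad_estimate <- function(x, ...) {
  cat(sprintf("Maximal accrual diversity: D_max = %.4g effective species at A_max = %.4g subjects\n",
              x$D_max, x$A_max))
  invisible(x)
}

#' Parameter extractor: DAR exponent z
#'
#' @param q diversity order for the accumulation curve.
#' @param model `"PL"` or `"PLEC"`.
#' @param n_orders,seed accumulation settings (the seed is fixed so the
#'   extractor is deterministic given the table).
#' @return function(table) returning the fitted `z`.
#' @export
dar_z_extractor <- function(q = 0, model = "PL", n_orders = 20, seed = 7L) {
  force(q); force(model); force(n_orders); force(seed)
  function(table) {
    fit_dar(dar_curve(table, q, n_orders, seed), model = model, q = q)$z
  }
}
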