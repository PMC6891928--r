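#' Hill number of order q
#'
#' Diversity in units of effective species:
#' `D(q) = (sum_i p_i^q)^(1/(1-q))` over the relative abundances `p_i` of
#' the taxa with positive abundance. `q = 0` is richness, `q = 1` the
#' Shannon limit `exp(-sum p_i log p_i)` (computed analytically), `q = 2`
#' the inverse Simpson concentration.
#'
#' @param abundances non-negative vector (counts or relative abundances;
#'   the result is scale-invariant) with at least one positive entry.
#' @param q non-negative diversity order.
#' @return Hill number, a real `>= 1` for any non-empty community.
#' @export
hill_number <- function(abundances, q) {
  if (anyNA(abundances)) stop("abundances contain NA")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  p <- abundances[abundances > 0]
  if (!length(p)) stop("all abundances are zero")
  p <- p / sum(p)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample Hill diversity profiles
#'
#' @param table an [otu_table()] (counts or relative mode).
#' @param q_values diversity orders (default 0, 1, 2, 3).
#' @return data.frame with columns `sample_id`, `q`, `D`.
#' @export
hill_profile <- function(table, q_values = c(0, 1, 2, 3)) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  out <- expand.grid(sample_id = colnames(m), q = q_values,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$D <- mapply(function(s, q) hill_number(m[, s], q),
                  out$sample_id, out$q)
  out[order(out$sample_id, out$q), c("sample_id", "q", "D")]
}

#' Hill profiles restricted to a stratum of taxa
#'
#' Computes per-sample Hill numbers on the sample renormalised over a
#' taxon subset, e.g. one phylum or the core (or periphery) of a detected
#' core/periphery partition. Samples with zero total abundance in the
#' stratum are skipped and reported in the `skipped` attribute.
#'
#' @param table an [otu_table()].
#' @param taxa character vector of taxon ids defining the stratum, or a
#'   named character vector of per-taxon labels (e.g. from [phylum_of()])
#'   together with `stratum` naming the label to select.
#' @param stratum label to select when `taxa` is a label vector.
#' @param q_values diversity orders.
#' @return data.frame as [hill_profile()], with attribute `skipped`.
#' @export
stratified_profiles <- function(table, taxa, stratum = NULL,
                                q_values = c(0, 1, 2, 3)) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.null(stratum)) taxa <- names(taxa)[taxa == stratum]
  taxa <- intersect(taxa, otu_ids(table))
  if (!length(taxa)) stop("stratum matches no taxa in the table")
  m <- table$counts[taxa, , drop = FALSE]
  tot <- colSums(m)
  skipped <- colnames(m)[tot <= 0]
  keep <- colnames(m)[tot > 0]
  sub <- table
  sub$counts <- m[, keep, drop = FALSE]
  prof <- hill_profile(sub, q_values)
  attr(prof, "skipped") <- skipped
  prof
}

#' Two-group comparison: Wilcoxon rank-sum test plus Cohen's d
#'
#' The two cohorts are unpaired, so the "Wilcoxon" comparison is the
#' two-sample rank-sum (Mann-Whitney) form, two-sided (exact for small
#' tie-free groups, normal approximation with tie correction otherwise).
#' Cohen's d uses the pooled standard deviation. The direction call is by
#' the Wilcoxon p-value at `alpha`, with medians ordering A vs B.
#'
#' @param valuesA,valuesB numeric vectors (each of length `>= 2`).
#' @param alpha significance level for the direction call.
#' @return List of class `group_comparison`: `wilcoxon_p`, `cohens_d`,
#'   `medianA`, `medianB`, `direction` (`"A>B"`, `"A<B"`, `"A~B"`), and
#'   the input values.
#' @export
compare_groups <- function(valuesA, valuesB, alpha = 0.05) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("each group needs at least 2 values")
  if (all(valuesA == valuesA[1]) && all(valuesB == valuesB[1]) &&
      valuesA[1] == valuesB[1]) {
    p <- 1; d <- 0
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(valuesA, valuesB, alternative = "two.sided")$p.value)
    nA <- length(valuesA); nB <- length(valuesB)
    sp <- sqrt(((nA - 1) * stats::var(valuesA) + (nB - 1) * stats::var(valuesB)) /
                 (nA + nB - 2))
    d <- if (sp == 0) 0 else (mean(valuesA) - mean(valuesB)) / sp
  }
  direction <- if (p > alpha) "A~B"
  else if (stats::median(valuesA) > stats::median(valuesB)) "A>B" else "A<B"
  structure(list(wilcoxon_p = p, cohens_d = d,
                 medianA = stats::median(valuesA),
                 medianB = stats::median(valuesB),
                 direction = direction, alpha = alpha,
                 valuesA = valuesA, valuesB = valuesB),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon p = %.4g, Cohen's d = %.3f, medians %.4g vs %.4g -> %s\n",
              x$wilcoxon_p, x$cohens_d, x$medianA, x$medianB, x$direction))
  invisible(x)
}

#' Compare per-sample Hill diversity between two cohorts
#'
#' Convenience wrapper: computes per-sample Hill numbers in each cohort at
#' each order and runs [compare_groups()] per order.
#'
#' @param tableA,tableB cohort [otu_table()]s.
#' @param q_values diversity orders.
#' @param taxa,stratum optional stratum restriction as in
#'   [stratified_profiles()].
#' @param alpha significance level.
#' @return data.frame: `q`, `medianA`, `medianB`, `wilcoxon_p`,
#'   `cohens_d`, `direction`.
#' @export
compare_diversity <- function(tableA, tableB, q_values = c(0, 1, 2, 3),
                              taxa = NULL, stratum = NULL, alpha = 0.05) {
  prof <- function(tab) {
    if (is.null(taxa)) hill_profile(tab, q_values)
    else stratified_profiles(tab, taxa, stratum, q_values)
  }
  pA <- prof(tableA); pB <- prof(tableB)
  do.call(rbind, lapply(q_values, function(q) {
    cmp <- compare_groups(pA$D[pA$q == q], pB$D[pB$q == q], alpha)
    data.frame(q = q, medianA = cmp$medianA, medianB = cmp$medianB,
               wilcoxon_p = cmp$wilcoxon_p, cohens_d = cmp$cohens_d,
               direction = cmp$direction, stringsAsFactors = FALSE)
  }))
}
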