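#' Observed shared and cohort-specific taxa
#'
#' A taxon is "present" in a cohort when its total reads there are
#' positive. Taxa absent from both cohorts are excluded entirely.
#'
#' @param tableA,tableB cohort [otu_table()]s with identical taxon rows.
#' @return List: `shared`, `specificA`, `specificB` (taxon id vectors).
#' @export
observed_shared <- function(tableA, tableB) {
  if (!identical(otu_ids(tableA), otu_ids(tableB)))
    stop("tables must share an identical, aligned taxon list")
  inA <- rowSums(tableA$counts) > 0
  inB <- rowSums(tableB$counts) > 0
  ids <- otu_ids(tableA)
  list(shared = ids[inA & inB],
       specificA = ids[inA & !inB],
       specificB = ids[!inA & inB])
}

#' Shared-species permutation test between two cohorts
#'
#' Tests whether the observed number of taxa shared between two cohorts is
#' smaller than expected by chance, under two null models:
#' * **A1** (read reshuffling): all reads of both cohorts are pooled and
#'   reallocated at random to the two cohorts, preserving each cohort's
#'   total read count. Implemented per taxon as a sequential multivariate
#'   hypergeometric split, exactly the distribution of shuffling
#'   taxon-labelled read tokens.
#' * **A2** (sample reshuffling): whole sample columns are pooled and
#'   re-assigned to two groups of the original sizes. A2 preserves
#'   within-sample structure and is the more conservative of the two.
#'
#' @param tableA,tableB counts-mode cohort tables with aligned taxa.
#' @param algorithm `"A1"` or `"A2"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"lower"` (default; the fewer-shared-than-chance
#'   alternative) or `"two_sided"`.
#' @return A `shared_species_result`: the fields of a `perm_result` plus
#'   `algorithm`, `shared`, `specificA`, `specificB`.
#' @export
shared_species_test <- function(tableA, tableB, algorithm = c("A1", "A2"),
                                n_perm = 1000, seed = 1L,
                                tail = c("lower", "two_sided")) {
  algorithm <- match.arg(algorithm)
  tail <- match.arg(tail)
  stopifnot_counts(tableA, "shared_species_test")
  stopifnot_counts(tableB, "shared_species_test")
  obs <- observed_shared(tableA, tableB)
  observed <- length(obs$shared)
  null_values <- if (algorithm == "A1")
    null_shared_a1(tableA, tableB, n_perm, seed)
  else
    null_shared_a2(tableA, tableB, n_perm, seed)
  res <- perm_result(observed, null_values, tail, n_perm, seed,
                     statistic = "shared species",
                     extra = list(algorithm = algorithm,
                                  observed_shared = observed,
                                  shared = obs$shared,
                                  specificA = obs$specificA,
                                  specificB = obs$specificB))
  class(res) <- c("shared_species_result", class(res))
  res
}

# A1 null: multivariate hypergeometric split of each taxon's pooled reads,
# conditioned on the two cohorts' total read counts.
null_shared_a1 <- function(tableA, tableB, n_perm, seed) {
  rA <- rowSums(tableA$counts)
  rB <- rowSums(tableB$counts)
  if (any(abs(c(rA, rB) - round(c(rA, rB))) > 1e-8))
    stop("A1 requires integer read counts")
  pooled <- round(rA + rB)
  keep <- pooled > 0
  pooled <- pooled[keep]
  totA <- round(sum(rA))
  tot <- sum(pooled)
  nt <- length(pooled)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      remA <- totA
      remT <- tot
      shared <- 0L
      for (i in seq_len(nt)) {
        ni <- pooled[i]
        x <- stats::rhyper(1, ni, remT - ni, remA)
        if (x > 0L && x < ni) shared <- shared + 1L
        remA <- remA - x
        remT <- remT - ni
      }
      shared
    }, numeric(1))
  })
}

# A2 null: re-split pooled sample columns into groups of the original sizes.
null_shared_a2 <- function(tableA, tableB, n_perm, seed) {
  if (ncol(tableA$counts) < 2 || ncol(tableB$counts) < 2)
    stop("A2 requires at least 2 samples per cohort")
  pres <- cbind(tableA$counts, tableB$counts) > 0
  nA <- ncol(tableA$counts)
  n <- ncol(pres)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n, nA)
      sum(rowSums(pres[, idx, drop = FALSE]) > 0 &
            rowSums(pres[, -idx, drop = FALSE]) > 0)
    }, numeric(1))
  })
}
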