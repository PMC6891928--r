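#' Core/periphery pattern-match objective
#'
#' For a binary adjacency matrix `A` and a binary core-membership vector
#' `delta`, the ideal core/periphery pattern `P` has `p_ij = 1` whenever
#' at least one of `i`, `j` is a core node (fully linked core, periphery
#' linked only to the core) and `p_ij = 0` for periphery-periphery pairs
#' and the diagonal. The objective is `rho = sum_ij a_ij p_ij` over
#' ordered pairs (each undirected edge touching the core counts twice);
#' maximising it over `delta` defines the detected core.
#'
#' @param adjacency binary symmetric matrix with zero diagonal, or a
#'   `signed_network` (binarised, unsigned).
#' @param delta binary (or logical) vector, 1 = core; must contain both a
#'   core and a periphery node.
#' @param normalize divide by the ideal pattern's ordered edge count
#'   (`n_core (n_core - 1) + 2 n_core n_periphery`), giving a value in
#'   `[0, 1]` comparable across partition sizes. Default off: the raw
#'   pattern match is what detection optimises.
#' @return The objective value `rho`.
#' @export
cpn_objective <- function(adjacency, delta, normalize = FALSE) {
  A <- as_adjacency(adjacency)
  delta <- as.logical(delta)
  if (length(delta) != nrow(A)) stop("`delta` length must match node count")
  if (all(delta) || !any(delta))
    stop("`delta` must contain at least one core and one periphery node")
  per <- !delta
  m2 <- sum(A)                       # ordered edge count
  e_pp2 <- sum(A[per, per, drop = FALSE])
  rho <- m2 - e_pp2
  if (normalize) {
    nc <- sum(delta); np <- sum(per)
    rho <- rho / (nc * (nc - 1) + 2 * nc * np)
  }
  rho
}

as_adjacency <- function(x) {
  if (inherits(x, "signed_network")) {
    n <- length(x$nodes)
    A <- matrix(0L, n, n, dimnames = list(x$nodes, x$nodes))
    if (nrow(x$edges)) {
      i <- match(x$edges$u, x$nodes); j <- match(x$edges$v, x$nodes)
      A[cbind(i, j)] <- 1L; A[cbind(j, i)] <- 1L
    }
    return(A)
  }
  A <- as.matrix(x)
  if (nrow(A) != ncol(A) || any(A != t(A)) || any(diag(A) != 0) ||
      !all(A %in% c(0, 1)))
    stop("adjacency must be binary, symmetric, with zero diagonal")
  A
}

# Greedy label switching to a local maximum of (rho, -n_core).
# rho = 2m - 2*e_pp, so flips reduce periphery-periphery edges first and
# then shrink the core at constant rho.
greedy_core <- function(A, delta) {
  n <- nrow(A)
  repeat {
    per <- !delta
    pn <- as.vector(A %*% per)       # periphery neighbours per node
    gain <- ifelse(!delta, pn, 0)    # periphery -> core removes pn pp-edges
    cand <- which(gain > 0)
    if (length(cand) && sum(delta) < n - 1) {
      v <- cand[which.max(gain[cand])]
      delta[v] <- TRUE
      next
    }
    drop <- which(delta & pn == 0)
    if (length(drop) && sum(delta) > 1) {
      delta[drop[1]] <- FALSE
      next
    }
    break
  }
  delta
}

#' Detect the core/periphery partition of a network
#'
#' Greedy single-node label switching to a local maximum of
#' [cpn_objective()], run from `n_restarts` random initial partitions
#' plus a degree-ranked initialisation (core = nodes of above-average
#' degree); the best objective wins, with ties broken by the smaller
#' core and then by the lexicographically smallest membership vector.
#'
#' @param net a `signed_network` (or binary adjacency matrix) with at
#'   least 3 nodes and 1 edge.
#' @param n_restarts number of random restarts.
#' @param seed integer seed (restart initialisation).
#' @return Object of class `core_partition`: `delta` (named 0/1 vector),
#'   `rho`, `core`, `periphery`, `n_core`, `n_periphery`.
#' @export
detect_core <- function(net, n_restarts = 50, seed = 1L) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n < 3) stop("core/periphery detection needs at least 3 nodes")
  if (sum(A) == 0) stop("core/periphery detection needs at least 1 edge")
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- rowSums(A)
  clip <- function(delta) {
    if (!any(delta)) delta[which.max(deg)] <- TRUE
    if (all(delta)) delta[which.min(deg)] <- FALSE
    delta
  }
  inits <- with_seed(seed, {
    c(list(clip(deg >= mean(deg))),
      lapply(seq_len(n_restarts), function(k)
        clip(stats::runif(n) < 0.5)))
  })
  best <- NULL
  for (d0 in inits) {
    d <- greedy_core(A, d0)
    sc <- list(rho = cpn_objective(A, d), ncore = sum(d),
               key = paste(as.integer(d), collapse = ""))
    if (is.null(best) ||
        sc$rho > best$rho ||
        (sc$rho == best$rho && sc$ncore < best$ncore) ||
        (sc$rho == best$rho && sc$ncore == best$ncore && sc$key < best$key)) {
      best <- c(sc, list(delta = d))
    }
  }
  delta <- stats::setNames(as.integer(best$delta), nodes)
  structure(list(delta = delta, rho = best$rho,
                 core = nodes[best$delta], periphery = nodes[!best$delta],
                 n_core = sum(best$delta),
                 n_periphery = n - sum(best$delta)),
            class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("Core/periphery partition: %d core, %d periphery nodes (rho = %g)\n",
              x$n_core, x$n_periphery, x$rho))
  invisible(x)
}

#' Shared core (or periphery) test, observed-network strategy
#'
#' Detects the partition on each observed network and tests whether the
#' two cohorts' core (or periphery) node sets overlap less than expected
#' by chance. The null draws random node subsets of the observed sizes
#' from the union of the two networks' node sets and records their
#' overlap.
#'
#' @param netA,netB cohort `signed_network`s.
#' @param what `"core"` or `"periphery"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param n_restarts restarts for [detect_core()].
#' @return A `perm_result` with extra fields `setA`, `setB`, `shared`.
#' @export
shared_core_observed <- function(netA, netB, what = c("core", "periphery"),
                                 n_perm = 1000, seed = 1L, n_restarts = 50) {
  what <- match.arg(what)
  pA <- detect_core(netA, n_restarts, child_seed(seed, 1))
  pB <- detect_core(netB, n_restarts, child_seed(seed, 2))
  setA <- if (what == "core") pA$core else pA$periphery
  setB <- if (what == "core") pB$core else pB$periphery
  if (!length(setA) || !length(setB))
    stop("empty ", what, " set in one of the networks")
  universe <- union(netA$nodes, netB$nodes)
  observed <- length(intersect(setA, setB))
  null_values <- with_seed(child_seed(seed, 3), {
    vapply(seq_len(n_perm), function(k) {
      a <- sample(universe, length(setA))
      b <- sample(universe, length(setB))
      length(intersect(a, b))
    }, numeric(1))
  })
  perm_result(observed, null_values, "lower", n_perm, seed,
              statistic = paste("shared", what, "nodes"),
              extra = list(setA = setA, setB = setB,
                           shared = intersect(setA, setB), what = what))
}

#' Shared core (or periphery) test, permutated-network strategy
#'
#' The observed statistic is the overlap of the core (periphery) sets
#' detected on the two observed cohort networks. The null rebuilds
#' `n_perm` pairs of networks from pooled-and-resplit samples, re-detects
#' the partition on each, and records the pair's overlap.
#'
#' @param tableA,tableB counts-mode cohort tables with aligned taxa.
#' @param what `"core"` or `"periphery"`.
#' @param n_perm number of permutated network pairs.
#' @param seed integer seed.
#' @param fdr_alpha,min_total network construction settings.
#' @param n_restarts restarts for [detect_core()]. Observed and
#'   permutated networks use the same number so the null statistic is
#'   exchangeable with the observed one; lower it (via
#'   `n_restarts_perm`) only as a deliberate speed trade-off.
#' @param n_restarts_perm restarts used on permutated pairs.
#' @param max_fail_frac maximum tolerated fraction of pairs where network
#'   construction or detection fails.
#' @return A `perm_result` with extra fields `setA`, `setB`, `shared`,
#'   `n_failed`.
#' @export
shared_core_permutated <- function(tableA, tableB,
                                   what = c("core", "periphery"),
                                   n_perm = 1000, seed = 1L,
                                   fdr_alpha = 0.001, min_total = 80,
                                   n_restarts = 50,
                                   n_restarts_perm = n_restarts,
                                   max_fail_frac = 0.05) {
  what <- match.arg(what)
  netA <- build_scn(tableA, fdr_alpha, min_total)
  netB <- build_scn(tableB, fdr_alpha, min_total)
  pA <- detect_core(netA, n_restarts, child_seed(seed, 1))
  pB <- detect_core(netB, n_restarts, child_seed(seed, 2))
  setA <- if (what == "core") pA$core else pA$periphery
  setB <- if (what == "core") pB$core else pB$periphery
  observed <- length(intersect(setA, setB))
  r_perm <- n_restarts_perm
  k <- 0L
  null_values <- unlist(permutated_pairs(
    tableA, tableB, n = n_perm, seed = child_seed(seed, 3),
    fdr_alpha = fdr_alpha, min_total = min_total,
    fun = function(a, b) {
      k <<- k + 1L
      tryCatch({
        ca <- detect_core(a, r_perm, child_seed(seed, 10 + 2 * k))
        cb <- detect_core(b, r_perm, child_seed(seed, 11 + 2 * k))
        sa <- if (what == "core") ca$core else ca$periphery
        sb <- if (what == "core") cb$core else cb$periphery
        length(intersect(sa, sb))
      }, error = function(e) NA_real_)
    }))
  n_failed <- sum(is.na(null_values))
  if (n_failed > max_fail_frac * n_perm)
    stop(sprintf("core detection failed in %.1f%% of permutated pairs",
                 100 * n_failed / n_perm))
  perm_result(observed, null_values[!is.na(null_values)], "lower",
              n_perm, seed, statistic = paste("shared", what, "nodes"),
              extra = list(setA = setA, setB = setB,
                           shared = intersect(setA, setB), what = what,
                           n_failed = n_failed))
}

#' Properties of a core/periphery partition
#'
#' @param net a `signed_network`.
#' @param partition a [detect_core()] result on `net`.
#' @return List of class `cpn_properties`: `rho`, `n_core`,
#'   `n_periphery`, `core_density`, `periphery_density`,
#'   `core_periphery_density`, and `core_subgraph` (the
#'   [network_properties()] of the core-induced subgraph).
#' @export
cpn_properties <- function(net, partition) {
  stopifnot(inherits(net, "signed_network"),
            inherits(partition, "core_partition"))
  A <- as_adjacency(net)
  d <- as.logical(partition$delta[net$nodes])
  nc <- sum(d); np <- sum(!d)
  dens <- function(sub2, npairs2) if (npairs2 <= 0) NA_real_ else sub2 / npairs2
  core_e2 <- sum(A[d, d, drop = FALSE])
  per_e2 <- sum(A[!d, !d, drop = FALSE])
  cp_e <- sum(A[d, !d, drop = FALSE])
  core_edges <- net$edges[net$edges$u %in% partition$core &
                            net$edges$v %in% partition$core, , drop = FALSE]
  structure(list(
    rho = partition$rho, n_core = nc, n_periphery = np,
    core_density = dens(core_e2, nc * (nc - 1)),
    periphery_density = dens(per_e2, np * (np - 1)),
    core_periphery_density = dens(cp_e, nc * np),
    core_subgraph = network_properties(
      signed_network(partition$core, core_edges, net$n_samples))),
    class = "cpn_properties")
}
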