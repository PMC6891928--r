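# Edge weights for path length: 1/|rho|, so stronger associations are
# shorter and the shortest path is the strongest chain of associations.
edge_weights <- function(net) {
  if (!nrow(net$edges)) return(numeric(0))
  if (any(net$edges$rho == 0)) stop("edges with rho = 0 have no defined length")
  1 / abs(net$edges$rho)
}

# Dense all-pairs shortest-path distances by vectorised Floyd-Warshall.
# The networks here are small (tens to a few hundred nodes) and the
# permutated-network null rebuilds thousands of them, so the dense form
# beats per-graph construction overhead.
apsp_dist <- function(n, ei, ej, w) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[cbind(ei, ej)] <- pmin(D[cbind(ei, ej)], w)
  D[cbind(ej, ei)] <- D[cbind(ei, ej)]
  for (k in seq_len(n)) {
    dk <- D[, k]
    if (all(!is.finite(dk[-k]))) next
    cand <- outer(dk, D[k, ], "+")
    upd <- cand < D
    if (any(upd)) D[upd] <- cand[upd]
  }
  D
}

#' Shortest-path tree membership for one root
#'
#' Marks the edges that lie on at least one shortest path from `root` to
#' any other node, using `1/|rho|` edge lengths: edge `(i, j)` qualifies
#' when `d(root, i) + w_ij = d(root, j)` (or symmetrically). Unreachable
#' parts of the graph contribute no edges; an isolated root yields an
#' empty tree.
#'
#' @param net a `signed_network`.
#' @param root node id.
#' @return Logical vector over `net$edges` rows (`TRUE` = edge in the
#'   root's shortest-path tree), with attribute `root`.
#' @export
shortest_path_tree <- function(net, root) {
  stopifnot(inherits(net, "signed_network"))
  ri <- match(root, net$nodes)
  if (is.na(ri)) stop("root not in network: ", root)
  n <- length(net$nodes)
  if (!nrow(net$edges))
    return(structure(logical(0), root = root))
  ei <- match(net$edges$u, net$nodes)
  ej <- match(net$edges$v, net$nodes)
  w <- edge_weights(net)
  D <- apsp_dist(n, ei, ej, w)
  d <- D[ri, ]
  tol <- 1e-10 * max(1, max(w))
  on <- (abs(d[ei] + w - d[ej]) < tol | abs(d[ej] + w - d[ei]) < tol) &
    is.finite(d[ei]) & is.finite(d[ej])
  structure(on, root = root)
}

#' Link salience of every edge
#'
#' The salience of edge `(i, j)` is the fraction of shortest-path trees
#' (one per root node, over all `N` nodes of the network, isolated nodes
#' included) that contain the edge. Edges of a tree-shaped component have
#' salience `N_component / N`; in a connected tree every edge has
#' salience 1.
#'
#' @param net a `signed_network`.
#' @return Object of class `salience_map`: `edges` (the network's edge
#'   table plus a `salience` column in `[0, 1]`), `n_roots`, `nodes`.
#' @export
link_salience <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  if (n == 0) stop("empty network")
  edges <- net$edges
  if (!nrow(edges)) {
    edges$salience <- numeric(0)
    return(structure(list(edges = edges, n_roots = n, nodes = net$nodes),
                     class = "salience_map"))
  }
  ei <- match(edges$u, net$nodes)
  ej <- match(edges$v, net$nodes)
  w <- edge_weights(net)
  D <- apsp_dist(n, ei, ej, w)
  tol <- 1e-10 * max(1, max(w))
  # T_ij(x) = 1 iff d(x,i) + w == d(x,j) or d(x,j) + w == d(x,i); average
  # the indicator over all roots x (rows of D) in one vectorised sweep.
  Di <- D[, ei, drop = FALSE]
  Dj <- D[, ej, drop = FALSE]
  won <- sweep(Di, 2, w, "+")
  onT <- (abs(won - Dj) < tol) | (abs(sweep(Dj, 2, w, "+") - Di) < tol)
  onT[!is.finite(Di) | !is.finite(Dj)] <- FALSE
  edges$salience <- colMeans(onT)
  structure(list(edges = edges, n_roots = n, nodes = net$nodes),
            class = "salience_map")
}

#' @export
print.salience_map <- function(x, ...) {
  cat(sprintf("Link salience over %d roots: %d edges, salience range [%.3f, %.3f]\n",
              x$n_roots, nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$salience) else NA,
              if (nrow(x$edges)) max(x$edges$salience) else NA))
  invisible(x)
}

#' Extract the high-salience skeleton
#'
#' Keeps the edges with salience at or above `s_star` while preserving
#' every node of the source network. Skeletons are nested: the edge set
#' at a higher threshold is a subset of the edge set at a lower one.
#'
#' @param sal a [link_salience()] result.
#' @param s_star threshold in `[0, 1]` (conventional values 0.25 and 0.5).
#' @return List of class `skeleton`: `network` (a `signed_network` whose
#'   edge table keeps the `salience` column), `threshold`.
#' @export
extract_skeleton <- function(sal, s_star) {
  stopifnot(inherits(sal, "salience_map"))
  if (s_star < 0 || s_star > 1) stop("`s_star` must lie in [0, 1]")
  keep <- sal$edges$salience >= s_star
  net <- signed_network(sal$nodes, sal$edges[keep, c("u", "v", "rho", "p_adj"),
                                             drop = FALSE])
  net$edges$salience <- sal$edges$salience[keep]
  structure(list(network = net, threshold = s_star), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("High-salience skeleton (s >= %.2f): %d nodes, %d edges\n",
              x$threshold, length(x$network$nodes), nrow(x$network$edges)))
  invisible(x)
}

skeleton_edge_keys <- function(skel) {
  e <- skel$network$edges
  if (!nrow(e)) return(character(0))
  paste(pmin(e$u, e$v), pmax(e$u, e$v), sep = "~")
}

#' Shared-skeleton permutation test (permutated-network strategy)
#'
#' The observed statistic is the number of edges (unordered taxon pairs)
#' shared by the two cohorts' skeletons at threshold `s_star`. The null
#' rebuilds network pairs from pooled-and-resplit samples, recomputes
#' salience and skeletons per pair, and records the shared-edge count.
#' This analysis has no observed-network variant: random skeletons have
#' no meaningful node-set permutation analogue.
#'
#' @param tableA,tableB counts-mode cohort tables with aligned taxa.
#' @param s_star salience threshold.
#' @param n_perm number of permutated network pairs.
#' @param seed integer seed.
#' @param fdr_alpha,min_total network construction settings.
#' @param max_fail_frac maximum tolerated fraction of failed pairs.
#' @return A `perm_result` with extra fields `skeletonA`, `skeletonB`,
#'   `shared_edges`, `n_failed`.
#' @export
shared_skeleton_analysis <- function(tableA, tableB, s_star = 0.25,
                                     n_perm = 1000, seed = 1L,
                                     fdr_alpha = 0.001, min_total = 80,
                                     max_fail_frac = 0.05) {
  skel_of <- function(net) extract_skeleton(link_salience(net), s_star)
  skA <- skel_of(build_scn(tableA, fdr_alpha, min_total))
  skB <- skel_of(build_scn(tableB, fdr_alpha, min_total))
  kA <- skeleton_edge_keys(skA); kB <- skeleton_edge_keys(skB)
  observed <- length(intersect(kA, kB))
  null_values <- unlist(permutated_pairs(
    tableA, tableB, n = n_perm, seed = child_seed(seed, 1),
    fdr_alpha = fdr_alpha, min_total = min_total,
    fun = function(a, b) {
      tryCatch(length(intersect(skeleton_edge_keys(skel_of(a)),
                                skeleton_edge_keys(skel_of(b)))),
               error = function(e) NA_real_)
    }))
  n_failed <- sum(is.na(null_values))
  if (n_failed > max_fail_frac * n_perm)
    stop(sprintf("skeleton extraction failed in %.1f%% of permutated pairs",
                 100 * n_failed / n_perm))
  perm_result(observed, null_values[!is.na(null_values)], "lower",
              n_perm, seed, statistic = "shared skeleton edges",
              extra = list(skeletonA = skA, skeletonB = skB,
                           shared_edges = intersect(kA, kB),
                           s_star = s_star, n_failed = n_failed))
}

#' Properties of a high-salience skeleton
#'
#' @param skeleton an [extract_skeleton()] result.
#' @return The [network_properties()] of the skeleton graph.
#' @export
hsn_properties <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton"))
  network_properties(skeleton$network)
}
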