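#' Construct a signed species co-occurrence network
#'
#' Filters low-abundance taxa (total reads below `min_total`), converts to
#' relative abundance, computes all pairwise Spearman correlations, applies
#' Benjamini-Hochberg FDR adjustment across all tested pairs, and keeps the
#' edges with adjusted p at or below `fdr_alpha` (or raw p when
#' `use_adjusted = FALSE`). Correlation p-values use the t approximation
#' for `n >= 12` samples and the exact null distribution below that.
#'
#' @param table counts-mode [otu_table()] with `>= 10` samples.
#' @param fdr_alpha significance threshold on the (adjusted) p-value.
#' @param min_total read-count prefilter passed to [filter_min_total()]
#'   (0 disables it).
#' @param use_adjusted threshold BH-adjusted p (default) or raw p.
#' @return Object of class `signed_network`: `nodes` (taxon ids), `edges`
#'   (data.frame `u`, `v`, `rho`, `p_adj`), `n_samples`, `fdr_alpha`.
#' @export
build_scn <- function(table, fdr_alpha = 0.001, min_total = 80,
                      use_adjusted = TRUE) {
  stopifnot_counts(table, "build_scn")
  if (ncol(table$counts) < 10)
    stop("co-occurrence networks need at least 10 samples")
  tab <- if (min_total > 0) filter_min_total(table, min_total) else table
  if (nrow(tab$counts) < 2)
    stop("fewer than 2 taxa survive the abundance filter")
  rel <- to_relative(tab)
  net <- scn_from_matrix(rel$counts, fdr_alpha, use_adjusted)
  net
}

empty_edges <- data.frame(u = character(0), v = character(0),
                          rho = numeric(0), p_adj = numeric(0),
                          stringsAsFactors = FALSE)

# Core construction on a relative-abundance matrix (taxa x samples).
# Kept free of otu_table overhead so permutation loops stay fast.
scn_from_matrix <- function(m, fdr_alpha = 0.001, use_adjusted = TRUE) {
  nodes <- rownames(m)
  ns <- ncol(m)
  keep <- rowSums(m != m[, 1L]) > 0    # drop constant rows (no rank signal)
  edges <- empty_edges
  if (sum(keep) >= 2) {
    mv <- m[keep, , drop = FALSE]
    rho <- stats::cor(t(mv), method = "spearman")
    iu <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[iu]
    if (ns >= 12) {
      tstat <- r * sqrt((ns - 2) / pmax(1e-300, 1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = ns - 2)
      p[abs(r) >= 1] <- 0
    } else {
      p <- vapply(seq_len(nrow(iu)), function(k) {
        suppressWarnings(stats::cor.test(mv[iu[k, 1], ], mv[iu[k, 2], ],
                                         method = "spearman")$p.value)
      }, numeric(1))
    }
    padj <- stats::p.adjust(p, method = "BH")
    crit <- if (use_adjusted) padj else p
    sel <- which(crit <= fdr_alpha & r != 0)
    if (length(sel)) {
      rn <- rownames(mv)
      edges <- structure(list(u = rn[iu[sel, 1]], v = rn[iu[sel, 2]],
                              rho = r[sel], p_adj = padj[sel]),
                         class = "data.frame",
                         row.names = seq_along(sel))
    }
  }
  structure(list(nodes = nodes, edges = edges, n_samples = ns,
                 fdr_alpha = fdr_alpha),
            class = "signed_network")
}

#' Assemble a signed network from an edge list
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `u`, `v`, `rho` (and optionally
#'   `p_adj`; filled with `NA` if absent).
#' @param n_samples optional sample count annotation.
#' @return A `signed_network`.
#' @export
signed_network <- function(nodes, edges, n_samples = NA_integer_) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(u = character(0), v = character(0),
                        rho = numeric(0), p_adj = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    if (!all(c("u", "v", "rho") %in% names(edges)))
      stop("edges need columns u, v, rho")
    if (is.null(edges$p_adj)) edges$p_adj <- NA_real_
    edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
    if (!all(c(edges$u, edges$v) %in% nodes))
      stop("edge endpoints must be listed in `nodes`")
    key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  structure(list(nodes = as.character(nodes),
                 edges = edges[, c("u", "v", "rho", "p_adj")],
                 n_samples = n_samples, fdr_alpha = NA_real_),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("Signed co-occurrence network: %d nodes, %d edges (%d +, %d -)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$rho > 0), sum(x$edges$rho < 0)))
  invisible(x)
}

#' Convert a signed network to an igraph object
#'
#' @param net a `signed_network`.
#' @return Undirected [igraph::igraph] graph with `rho`, `p_adj` edge
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Basic properties of a co-occurrence network
#'
#' All fields are computed on the unsigned graph except the
#' positive-to-negative edge ratio. An empty graph yields the zero/NA
#' sentinel record.
#'
#' @param net a `signed_network`.
#' @return List of class `network_properties`: `n_nodes`, `n_edges`,
#'   `density`, `mean_degree`, `clustering_coefficient`, `n_components`
#'   (of non-isolated structure, isolated nodes counted as their own
#'   components), `diameter_largest` (unweighted diameter of the largest
#'   connected component), `degree_skewness`, `pn_ratio` (`Inf` when
#'   there are no negative edges; `NaN` for an edgeless graph).
#' @export
network_properties <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  if (n == 0 || m == 0) {
    return(structure(list(
      n_nodes = n, n_edges = 0L, density = 0, mean_degree = 0,
      clustering_coefficient = 0, n_components = n, diameter_largest = 0,
      degree_skewness = NA_real_, pn_ratio = NaN),
      class = "network_properties"))
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  cc <- igraph::transitivity(g, type = "global")
  pos <- sum(net$edges$rho > 0); neg <- sum(net$edges$rho < 0)
  structure(list(
    n_nodes = n,
    n_edges = m,
    density = if (n < 2) 0 else 2 * m / (n * (n - 1)),
    mean_degree = mean(deg),
    clustering_coefficient = if (is.nan(cc)) 0 else cc,
    n_components = comp$no,
    diameter_largest = igraph::diameter(big, weights = NA),
    degree_skewness = if (stats::sd(deg) == 0) 0 else e1071::skewness(deg),
    pn_ratio = if (neg == 0) Inf else pos / neg),
    class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  cat(sprintf(paste0("Network properties: %d nodes, %d edges, density %.3f, ",
                     "mean degree %.2f, clustering %.3f, %d components, ",
                     "diameter %d, degree skewness %.3f, P/N ratio %s\n"),
              x$n_nodes, x$n_edges, x$density, x$mean_degree,
              x$clustering_coefficient, x$n_components, x$diameter_largest,
              ifelse(is.na(x$degree_skewness), NA, x$degree_skewness),
              format(x$pn_ratio)))
  invisible(x)
}

#' Census of trio motifs anchored on the most abundant OTU
#'
#' The most abundant OTU (MAO) is the network node with the greatest total
#' reads in `table` (ties broken by lexicographic id). Every unordered
#' pair `{u, v}` of the remaining nodes defines a trio `{MAO, u, v}`,
#' classified by which of its three possible edges exist and by the sign
#' pattern of the existing edges. The named DLM class (double-link MAO
#' trio) counts trios with exactly two edges, both incident to the MAO.
#'
#' @param net a `signed_network`.
#' @param table the counts-mode table the network was built from (used
#'   only to rank total reads).
#' @return List of class `trio_census`: `mao`, `counts` (named integer
#'   vector per class; a class label `"a|b|c"` gives the sign of the two
#'   MAO edges (canonical order) and of the `u`-`v` edge, `"0"` marking an
#'   absent edge), `dlm`, `n_trios` (`= choose(n_nodes - 1, 2)`).
#' @export
trio_census <- function(net, table) {
  stopifnot(inherits(net, "signed_network"))
  stopifnot(inherits(table, "otu_table"))
  nodes <- net$nodes
  if (!all(nodes %in% otu_ids(table)))
    stop("network nodes missing from the table")
  tot <- rowSums(table$counts)[nodes]
  mao <- nodes[order(-tot, nodes)][1]
  others <- setdiff(nodes, mao)
  n <- length(others)
  if (n < 2)
    return(structure(list(mao = mao, counts = integer(0), dlm = 0L,
                          n_trios = 0L), class = "trio_census"))
  idx <- stats::setNames(seq_along(nodes), nodes)
  A <- matrix(FALSE, length(nodes), length(nodes))
  Sg <- matrix("", length(nodes), length(nodes))
  if (nrow(net$edges)) {
    ui <- idx[net$edges$u]; vi <- idx[net$edges$v]
    sg <- ifelse(net$edges$rho > 0, "+", "-")
    A[cbind(ui, vi)] <- TRUE; A[cbind(vi, ui)] <- TRUE
    Sg[cbind(ui, vi)] <- sg; Sg[cbind(vi, ui)] <- sg
  }
  oi <- idx[others]
  mi <- idx[mao]
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  u <- oi[pairs[, 1]]; v <- oi[pairs[, 2]]
  e_mu <- A[cbind(rep(mi, length(u)), u)]
  e_mv <- A[cbind(rep(mi, length(v)), v)]
  e_uv <- A[cbind(u, v)]
  s_mu <- Sg[cbind(rep(mi, length(u)), u)]
  s_mv <- Sg[cbind(rep(mi, length(v)), v)]
  s_uv <- Sg[cbind(u, v)]
  # class label "a|b|c": a = sign of MAO-u edge, b = sign of MAO-v edge,
  # c = sign of u-v edge, with "0" for an absent edge; u and v are
  # interchangeable, so the MAO-edge pair is stored in canonical order.
  p1 <- ifelse(e_mu, s_mu, "0")
  p2 <- ifelse(e_mv, s_mv, "0")
  p3 <- ifelse(e_uv, s_uv, "0")
  cls <- paste(pmin(p1, p2), pmax(p1, p2), p3, sep = "|")
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  dlm <- sum(e_mu & e_mv & !e_uv)
  structure(list(mao = mao, counts = counts, dlm = as.integer(dlm),
                 n_trios = length(u)),
            class = "trio_census")
}

#' @export
print.trio_census <- function(x, ...) {
  cat(sprintf("MAO trio census anchored on %s: %d trios, DLM = %d\n",
              x$mao, x$n_trios, x$dlm))
  invisible(x)
}

#' Pairs of permutated networks from pooled samples
#'
#' Pools the samples of both cohorts and, `n` times, re-splits them into
#' groups of the original sizes, building a co-occurrence network from
#' each half. This is the permutated-network null shared by the
#' network-property, core/periphery, and skeleton comparisons.
#'
#' @param tableA,tableB counts-mode cohort tables with aligned taxa.
#' @param n number of pairs.
#' @param seed integer seed.
#' @param fun optional function(netA, netB) applied to each pair; when
#'   supplied only its results are kept (memory-friendly streaming).
#' @param fdr_alpha,min_total,use_adjusted passed to [build_scn()].
#' @return List of `n` elements: `list(A = net, B = net)` pairs, or
#'   `fun`'s results.
#' @export
permutated_pairs <- function(tableA, tableB, n = 1000, seed = 1L,
                             fun = NULL, fdr_alpha = 0.001, min_total = 80,
                             use_adjusted = TRUE) {
  stopifnot_counts(tableA, "permutated_pairs")
  stopifnot_counts(tableB, "permutated_pairs")
  if (!identical(otu_ids(tableA), otu_ids(tableB)))
    stop("cohort tables must be aligned on taxa")
  pooled <- cbind(tableA$counts, tableB$counts)
  nA <- ncol(tableA$counts)
  ntot <- ncol(pooled)
  build_half <- function(cols) {
    m <- pooled[, cols, drop = FALSE]
    if (min_total > 0) m <- m[rowSums(m) >= min_total, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 taxa survive the abundance filter")
    cs <- colSums(m)
    if (any(cs <= 0)) stop("zero-total sample in permutated group")
    scn_from_matrix(sweep(m, 2, cs, "/"), fdr_alpha, use_adjusted)
  }
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      idx <- sample.int(ntot, nA)
      pair <- list(A = build_half(idx), B = build_half(setdiff(seq_len(ntot), idx)))
      if (is.null(fun)) pair else fun(pair$A, pair$B)
    })
  })
}

#' Permutation comparison of a network statistic
#'
#' @param statA,statB the observed statistic in each cohort's network.
#' @param null_pairs_stats 2-column matrix (or list of length-2 vectors)
#'   of the statistic on each permutated network pair; needs `>= 100`
#'   rows.
#' @param max_undefined_frac maximum tolerated fraction of non-finite
#'   null entries.
#' @return A `perm_result` for `|statA - statB|`, upper tail.
#' @export
compare_network_stat <- function(statA, statB, null_pairs_stats,
                                 max_undefined_frac = 0.05) {
  if (is.list(null_pairs_stats))
    null_pairs_stats <- do.call(rbind, null_pairs_stats)
  null_pairs_stats <- as.matrix(null_pairs_stats)
  if (nrow(null_pairs_stats) < 100)
    stop("need at least 100 null pairs")
  diffs <- abs(null_pairs_stats[, 1] - null_pairs_stats[, 2])
  bad <- !is.finite(diffs) | !is.finite(statA) | !is.finite(statB)
  if (!is.finite(statA) || !is.finite(statB) ||
      mean(!is.finite(diffs)) > max_undefined_frac)
    stop("statistic undefined in observed networks or in more than ",
         100 * max_undefined_frac, "% of null pairs")
  perm_result(abs(statA - statB), diffs[is.finite(diffs)], "upper",
              nrow(null_pairs_stats), NA_integer_,
              statistic = "|network stat A - B|",
              extra = list(statA = statA, statB = statB))
}

#' Write a network as an edge-list TSV
#'
#' Columns: `u`, `v`, `rho`, `p_adj`, `sign`.
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  e$sign <- ifelse(e$rho > 0, "+", "-")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
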