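# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with the package:
# exhaustive enumeration and closed forms only.

# --- graphs ---------------------------------------------------------------

# random signed weighted graph as a signed_network
random_net <- function(n, p_edge = 0.5, seed = 1, signed = TRUE) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  nodes <- sprintf("n%02d", seq_len(n))
  rho <- runif(nrow(pairs), 0.1, 1) *
    (if (signed) sample(c(-1, 1), nrow(pairs), TRUE) else 1)
  signed_network(nodes, data.frame(u = nodes[pairs[, 1]],
                                   v = nodes[pairs[, 2]],
                                   rho = rho))
}

adj_to_edges <- function(A, rho = 0.8) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  data.frame(u = rownames(A)[idx[, 1]], v = colnames(A)[idx[, 2]],
             rho = rho, stringsAsFactors = FALSE)
}

net_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$u, net$nodes); j <- match(net$edges$v, net$nodes)
    A[cbind(i, j)] <- 1L; A[cbind(j, i)] <- 1L
  }
  A
}

# --- link salience oracle -------------------------------------------------

# All simple paths between two nodes, as lists of vertex sequences.
all_simple_paths_rec <- function(adj_list, from, to, visited) {
  if (from == to) return(list(to))
  out <- list()
  for (nb in adj_list[[from]]) {
    if (!nb %in% visited) {
      for (tail in all_simple_paths_rec(adj_list, nb, to, c(visited, nb)))
        out[[length(out) + 1]] <- c(from, tail)
    }
  }
  out
}

# Salience by exhaustive enumeration: for every root x and target y find
# ALL shortest paths, mark their edges into T(x), then average T over all
# roots. Tolerant tie handling: any path within 1e-9 of the minimum
# length counts as shortest.
oracle_salience <- function(net) {
  n <- length(net$nodes)
  ne <- nrow(net$edges)
  ei <- match(net$edges$u, net$nodes)
  ej <- match(net$edges$v, net$nodes)
  w <- 1 / abs(net$edges$rho)
  wmat <- matrix(Inf, n, n)
  wmat[cbind(ei, ej)] <- w; wmat[cbind(ej, ei)] <- w
  adj_list <- lapply(seq_len(n), function(i) which(is.finite(wmat[i, ])))
  edge_id <- matrix(0L, n, n)
  edge_id[cbind(ei, ej)] <- seq_len(ne); edge_id[cbind(ej, ei)] <- seq_len(ne)
  s <- numeric(ne)
  for (x in seq_len(n)) {
    Tx <- logical(ne)
    for (y in seq_len(n)) {
      if (y == x) next
      paths <- all_simple_paths_rec(adj_list, x, y, x)
      if (!length(paths)) next
      lens <- vapply(paths, function(p)
        sum(wmat[cbind(p[-length(p)], p[-1])]), numeric(1))
      best <- min(lens)
      for (p in paths[lens <= best + 1e-9]) {
        ids <- edge_id[cbind(p[-length(p)], p[-1])]
        Tx[ids] <- TRUE
      }
    }
    s <- s + Tx
  }
  s / n
}

# --- core/periphery oracle ------------------------------------------------

# Exhaustive maximum of the pattern-match objective over all 2^n - 2
# admissible membership vectors; returns best rho and the smallest best
# core size (the package's tie-break).
oracle_cpn <- function(A) {
  n <- nrow(A)
  m2 <- sum(A)
  best_rho <- -Inf; best_ncore <- Inf; best_delta <- NULL
  for (code in 1:(2^n - 2)) {
    delta <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    per <- !delta
    rho <- m2 - sum(A[per, per, drop = FALSE])
    nc <- sum(delta)
    if (rho > best_rho || (rho == best_rho && nc < best_ncore)) {
      best_rho <- rho; best_ncore <- nc; best_delta <- delta
    }
  }
  list(rho = best_rho, n_core = best_ncore, delta = best_delta)
}

# ideal core/periphery graph: complete core, periphery attached to every
# core node, no periphery-periphery edges
perfect_cpn_graph <- function(k_core, k_periph) {
  n <- k_core + k_periph
  A <- matrix(0L, n, n)
  A[seq_len(k_core), seq_len(k_core)] <- 1L
  A[seq_len(k_core), k_core + seq_len(k_periph)] <- 1L
  A[k_core + seq_len(k_periph), seq_len(k_core)] <- 1L
  diag(A) <- 0L
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

# --- rank-sum oracle ------------------------------------------------------

# Exact two-sided rank-sum p by enumerating all assignments of the pooled
# values to group A (tie-free data only).
oracle_wilcoxon <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); nA <- length(a)
  ranks <- rank(pool)
  w_obs <- sum(ranks[seq_len(nA)])
  combs <- combn(n, nA)
  w_all <- apply(combs, 2, function(idx) sum(ranks[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# --- multiple testing oracle ----------------------------------------------

# Benjamini-Hochberg step-up adjusted p-values, written directly from the
# procedure: sort ascending, p_(i) * m / i, cumulative minimum from the
# largest down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- trio census oracle ---------------------------------------------------

oracle_trio_dlm <- function(net, mao) {
  others <- setdiff(net$nodes, mao)
  A <- net_adjacency(net)
  dlm <- 0L
  total_classes <- character(0)
  if (length(others) >= 2) {
    cmb <- combn(others, 2)
    for (k in seq_len(ncol(cmb))) {
      u <- cmb[1, k]; v <- cmb[2, k]
      e_mu <- A[mao, u] == 1; e_mv <- A[mao, v] == 1; e_uv <- A[u, v] == 1
      if (e_mu && e_mv && !e_uv) dlm <- dlm + 1L
    }
  }
  dlm
}
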