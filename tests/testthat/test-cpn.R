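test_that("the pattern-match objective follows the ideal-pattern definition", {
  A <- perfect_cpn_graph(3, 4)
  delta <- c(rep(1, 3), rep(0, 4))
  # perfect graph with matching delta: every ordered edge matches, the
  # maximum attainable
  expect_equal(cpn_objective(A, delta), sum(A))
  # empty graph: zero for any delta
  expect_equal(cpn_objective(matrix(0, 5, 5), c(1, 1, 0, 0, 0)), 0)
  # an edge between two periphery nodes contributes nothing
  A2 <- matrix(0, 4, 4); A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(cpn_objective(A2, c(1, 1, 0, 0)), 0)
  expect_equal(cpn_objective(A2, c(0, 0, 1, 0)), 2)
  expect_error(cpn_objective(A, rep(1, 7)), "periphery")
  expect_error(cpn_objective(matrix(1, 3, 3), c(1, 0, 0)), "diagonal")
  # normalised form: a perfect graph with the matching delta scores 1
  expect_equal(cpn_objective(A, delta, normalize = TRUE), 1)
  expect_lt(cpn_objective(perfect_cpn_graph(3, 6), c(1, 1, 1, 0, 0, 0,
                                                     0, 0, 1),
                          normalize = TRUE), 1)
})

test_that("greedy detection recovers planted perfect core/periphery graphs exactly", {
  A <- perfect_cpn_graph(4, 8)
  cp <- detect_core(A, n_restarts = 20, seed = 1)
  expect_setequal(cp$core, rownames(A)[1:4])
  expect_equal(cp$rho, sum(A))
  # determinism
  cp2 <- detect_core(A, n_restarts = 20, seed = 1)
  expect_identical(cp$delta, cp2$delta)
})

test_that("greedy detection attains the exhaustive optimum on small graphs", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, runif(1, 0.2, 0.7))
    A <- A + t(A)
    dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
    if (sum(A) == 0) next
    best <- oracle_cpn(A)
    got <- detect_core(A, n_restarts = 30, seed = i)
    expect_equal(got$rho, best$rho, info = sprintf("graph %d", i))
  }
})

test_that("node relabelling permutes the partition without changing rho", {
  net <- random_net(12, p_edge = 0.35, seed = 5)
  cp <- detect_core(net, n_restarts = 40, seed = 2)
  A <- net_adjacency(net)
  set.seed(3)
  perm <- sample(12)
  Ap <- A[perm, perm]
  # objective of the permuted delta on the permuted adjacency is unchanged
  expect_equal(cpn_objective(Ap, cp$delta[perm]), cp$rho)
  # and detection on the permuted graph reaches the same objective
  cpp <- detect_core(Ap, n_restarts = 40, seed = 2)
  expect_equal(cpp$rho, cp$rho)
})

test_that("detection never falls below the degree-ranked initialisation optimum", {
  for (s in 1:5) {
    net <- random_net(15, p_edge = 0.3, seed = 40 + s)
    if (!nrow(net$edges)) next
    A <- net_adjacency(net)
    deg <- rowSums(A)
    d0 <- deg >= mean(deg)
    if (!any(d0)) d0[which.max(deg)] <- TRUE
    if (all(d0)) d0[which.min(deg)] <- FALSE
    local_opt <- cpn_objective(A, mgxdiff:::greedy_core(A, d0))
    expect_gte(detect_core(net, n_restarts = 10, seed = s)$rho, local_opt)
  }
})

test_that("observed-network shared-core test matches the hypergeometric law", {
  # identical cores: overlap is maximal, p ~ 1
  A <- perfect_cpn_graph(4, 8)
  netA <- signed_network(rownames(A), adj_to_edges(A))
  same <- shared_core_observed(netA, netA, "core", n_perm = 300, seed = 1)
  expect_gt(same$p_value, 0.9)
  # disjoint cores within a small shared universe: permutation p matches
  # the hypergeometric tail
  nodesB <- rownames(A)[c(5:12, 1:4)]  # same universe, core on other nodes
  B <- perfect_cpn_graph(4, 8)
  dimnames(B) <- list(nodesB, nodesB)
  netB <- signed_network(rownames(A), adj_to_edges(B))
  r <- shared_core_observed(netA, netB, "core", n_perm = 2000, seed = 2)
  expect_equal(r$observed, 0)
  # P(overlap = 0) drawing two independent 4-subsets of 12 nodes
  p_exact <- sum(dhyper(0, 4, 8, 4))
  expect_lt(abs(r$p_value - p_exact), 0.05)
  expect_gte(r$p_value, 1 / 2001)
})

test_that("core/periphery properties behave on ideal and random graphs", {
  A <- perfect_cpn_graph(4, 8)
  net <- signed_network(rownames(A), adj_to_edges(A))
  cp <- detect_core(net, n_restarts = 10, seed = 1)
  pr <- cpn_properties(net, cp)
  expect_equal(pr$core_density, 1)
  expect_equal(pr$periphery_density, 0)
  expect_equal(pr$core_periphery_density, 1)
  expect_equal(pr$core_subgraph$density, 1)
  rnet <- random_net(14, p_edge = 0.45, seed = 9)
  rcp <- detect_core(rnet, n_restarts = 20, seed = 3)
  rpr <- cpn_properties(rnet, rcp)
  dens <- c(rpr$core_density, rpr$periphery_density,
            rpr$core_periphery_density)
  expect_true(all(dens >= 0 & dens <= 1, na.rm = TRUE))
  expect_equal(rpr$rho, rcp$rho)
})
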