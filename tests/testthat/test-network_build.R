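# counts table whose columns all sum to the same total, so closure to
# relative abundance preserves every taxon's ranks exactly
constant_total_table <- function(parts, total = 10000) {
  filler <- total - colSums(parts)
  stopifnot(all(filler >= 0))
  m <- rbind(parts, filler = filler)
  rownames(m) <- c(rownames(parts), "filler")
  otu_table(m)
}

test_that("a single perfectly rank-correlated pair yields exactly one rho = 1 edge", {
  # background taxa dominate the filler's variance, so neither the pair
  # nor any background taxon correlates detectably with the filler
  set.seed(4)
  n <- 50
  t1 <- sample(1:100, n)
  parts <- rbind(t1 = t1, t2 = 2 * t1,
                 matrix(sample(1:1000, 8 * n, TRUE), 8, n,
                        dimnames = list(paste0("bg", 1:8), NULL)))
  colnames(parts) <- paste0("s", 1:n)
  tab <- constant_total_table(parts, total = 20000)
  net <- build_scn(tab, min_total = 0)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$u, net$edges$v), c("t1", "t2"))
  expect_equal(net$edges$rho, 1, tolerance = 1e-12)
  # anti-correlated pair: single negative edge
  parts2 <- parts
  parts2["t2", ] <- 201 - 2 * t1
  net2 <- build_scn(constant_total_table(parts2), min_total = 0)
  e <- net2$edges[net2$edges$u == "t1" | net2$edges$v == "t1", ]
  expect_equal(nrow(e), 1)
  expect_lt(e$rho, 0)
})

test_that("independent taxa produce FDR-controlled, near-empty networks", {
  total <- 0
  for (s in 1:15) {
    set.seed(1000 + s)
    m <- matrix(rpois(20 * 60, 50), nrow = 20,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:60)))
    total <- total + nrow(build_scn(otu_table(m), min_total = 0)$edges)
  }
  expect_lte(total, 3)
})

test_that("network construction is invariant to sample order and taxon relabelling", {
  spec <- planted_network_spec(n_taxa = 15, core_size = 4, periphery_size = 8,
                               seed = 6)
  tab <- generate_planted_network_cohort(spec, 50)
  net <- build_scn(tab, min_total = 0)
  key <- function(n) sort(paste(pmin(n$edges$u, n$edges$v),
                                pmax(n$edges$u, n$edges$v),
                                round(n$edges$rho, 12)))
  shuf <- tab
  set.seed(2)
  shuf$counts <- shuf$counts[, sample(ncol(shuf$counts))]
  expect_identical(key(build_scn(shuf, min_total = 0)), key(net))
  rel <- tab
  map <- setNames(paste0("X", seq_len(nrow(tab$counts))), rownames(tab$counts))
  rownames(rel$counts) <- unname(map)
  net_rel <- build_scn(rel, min_total = 0)
  back <- net_rel
  back$edges$u <- names(map)[match(net_rel$edges$u, map)]
  back$edges$v <- names(map)[match(net_rel$edges$v, map)]
  expect_identical(key(back), key(net))
  expect_error(build_scn(otu_table(tab$counts[, 1:5]), min_total = 0),
               "10 samples")
})

test_that("network properties match closed forms on canonical graphs", {
  nodes5 <- paste0("n", 1:5)
  k5 <- signed_network(nodes5,
                       data.frame(u = t(combn(nodes5, 2))[, 1],
                                  v = t(combn(nodes5, 2))[, 2], rho = 0.9))
  p <- network_properties(k5)
  expect_equal(p$density, 1)
  expect_equal(p$clustering_coefficient, 1)
  expect_equal(p$mean_degree, 4)
  expect_identical(p$pn_ratio, Inf)
  cyc <- signed_network(nodes5,
                        data.frame(u = nodes5, v = nodes5[c(2:5, 1)],
                                   rho = c(0.5, 0.5, 0.6, -0.7, -0.7)))
  pc <- network_properties(cyc)
  expect_equal(pc$density, 0.5)
  expect_equal(pc$clustering_coefficient, 0)
  expect_equal(pc$diameter_largest, 2)
  expect_equal(pc$n_components, 1)
  # equal positive and negative edges (pentagon has 3+/2-; make it 2/2)
  sq <- signed_network(paste0("m", 1:4),
                       data.frame(u = c("m1", "m2", "m3", "m4"),
                                  v = c("m2", "m3", "m4", "m1"),
                                  rho = c(0.5, -0.5, 0.5, -0.5)))
  expect_equal(network_properties(sq)$pn_ratio, 1)
  empty <- signed_network(nodes5, data.frame())
  pe <- network_properties(empty)
  expect_equal(pe$n_edges, 0L)
  expect_equal(pe$density, 0)
  expect_true(is.nan(pe$pn_ratio))
})

test_that("MAO trio census matches combinatorics and brute-force enumeration", {
  # star centred on the MAO: every pair of leaves is a DLM
  nodes <- paste0("n", 1:5)
  m <- matrix(1, 5, 10, dimnames = list(nodes, paste0("s", 1:10)))
  m[1, ] <- 100  # n1 is the most abundant taxon
  tab <- otu_table(m)
  star <- signed_network(nodes, data.frame(u = "n1", v = nodes[-1], rho = 0.8))
  cen <- trio_census(star, tab)
  expect_identical(cen$mao, "n1")
  expect_equal(cen$dlm, choose(4, 2))
  expect_equal(cen$n_trios, choose(4, 2))
  # closed triangle containing the MAO is not a DLM
  tri <- signed_network(nodes, data.frame(u = c("n1", "n1", "n2"),
                                          v = c("n2", "n3", "n3"),
                                          rho = c(0.8, 0.8, -0.5)))
  cen2 <- trio_census(tri, tab)
  expect_equal(cen2$dlm, 0)
  expect_true(any(grepl("\\+\\|\\+\\|-", names(cen2$counts))))
  # random graphs: DLM equals direct enumeration, class counts cover all trios
  for (s in 1:10) {
    net <- random_net(sample(8:30, 1), p_edge = 0.3, seed = 700 + s)
    mm <- matrix(seq_along(net$nodes), length(net$nodes), 5,
                 dimnames = list(net$nodes, paste0("s", 1:5)))
    tt <- otu_table(mm)
    cen3 <- trio_census(net, tt)
    mao <- net$nodes[which.max(rowSums(mm))]
    expect_identical(cen3$mao, mao)
    expect_equal(cen3$dlm, oracle_trio_dlm(net, mao))
    expect_equal(sum(cen3$counts), choose(length(net$nodes) - 1, 2))
  }
})

test_that("the BH adjustment used for edge screening matches a direct step-up oracle", {
  set.seed(9)
  for (i in 1:5) {
    p <- runif(sample(10:1000, 1))^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("permutated pairs preserve group sizes and are seed-deterministic", {
  spec <- planted_network_spec(n_taxa = 12, core_size = 3, periphery_size = 6,
                               seed = 3)
  A <- suppressWarnings(generate_planted_network_cohort(spec, 20, "a"))
  B <- suppressWarnings(generate_planted_network_cohort(planted_network_spec(
    n_taxa = 12, core_size = 3, periphery_size = 6, seed = 4), 25, "b"))
  pp <- permutated_pairs(A, B, n = 5, seed = 8, min_total = 0)
  for (pr in pp) {
    expect_equal(pr$A$n_samples, 20)
    expect_equal(pr$B$n_samples, 25)
  }
  pp2 <- permutated_pairs(A, B, n = 5, seed = 8, min_total = 0)
  expect_identical(lapply(pp, function(x) x$A$edges),
                   lapply(pp2, function(x) x$A$edges))
})

test_that("network statistic comparison handles ties, floors and bad stats", {
  null_stats <- cbind(rnorm(200), rnorm(200))
  same <- compare_network_stat(1.5, 1.5, null_stats)
  expect_gte(same$p_value, 1 / 201)
  big <- compare_network_stat(100, -100, null_stats)
  expect_equal(big$p_value, 1 / 201)
  expect_error(compare_network_stat(1, 2, null_stats[1:50, ]), "100")
  bad <- null_stats; bad[1:50, 1] <- Inf
  expect_error(compare_network_stat(1, 2, bad), "undefined")
})

test_that("networks survive an edge-list export/import round trip", {
  net <- random_net(10, p_edge = 0.4, seed = 42)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  e <- utils::read.delim(f, stringsAsFactors = FALSE)
  back <- signed_network(net$nodes, e[, c("u", "v", "rho", "p_adj")])
  expect_equal(network_properties(back)[1:8], network_properties(net)[1:8])
})
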