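tabm <- function(m) {
  dimnames(m) <- list(paste0("t", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  otu_table(m)
}

test_that("variance-mean points match hand arithmetic", {
  # Type I: one point per sample (mean/variance across taxa)
  t1 <- tabm(cbind(c(2, 4, 6), c(1, 1, 1), c(10, 0, 2), c(3, 6, 9)))
  p1 <- ple_points(t1, "I")
  expect_equal(p1$m[1], 4)
  expect_equal(p1$V[1], 4)        # unbiased variance of (2,4,6)
  # constant sample (V = 0) excluded and counted
  expect_equal(attr(p1, "n_excluded"), 1)
  # Type III: one point per taxon (across samples)
  t3 <- tabm(rbind(c(1, 3), c(2, 6), c(5, 1), c(4, 4)))
  p3 <- ple_points(t3, "III")
  expect_equal(p3$m[1], 2)
  expect_equal(p3$V[1], 2)
  # identical columns: all Type-III variances zero -> error
  t0 <- tabm(matrix(rep(c(1, 2, 3, 4), 3), ncol = 3))
  expect_error(ple_points(t0, "III"), "usable")
  expect_error(ple_points(tabm(matrix(1, 5, 2)), "I"), "3 samples")
})

test_that("power-law fitting is exact on noiseless data and validates input", {
  m <- c(0.5, 1, 2, 5, 10, 40)
  f <- fit_power_law(data.frame(m = m, V = 2 * m^1.8))
  expect_equal(f$b, 1.8, tolerance = 1e-12)
  expect_equal(f$a, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(m = c(1, 2), V = c(1, 2))), "3 points")
  expect_error(fit_power_law(data.frame(m = c(2, 2, 2), V = c(1, 2, 3))),
               "singular")
})

test_that("rescaling m transforms the fitted intercept exactly as algebra demands", {
  # V = a m^b; under m -> k m the slope is unchanged and a' = a k^-b
  pts <- generate_power_law_points(3, 1.5, 40, noise_sd = 0.2, seed = 8)
  f0 <- fit_power_law(pts)
  for (k in c(0.1, 2, 117)) {
    fk <- fit_power_law(data.frame(m = k * pts$m, V = pts$V))
    expect_equal(fk$b, f0$b, tolerance = 1e-9)
    expect_equal(fk$a, f0$a * k^(-f0$b), tolerance = 1e-6)
  }
})

test_that("scaling-parameter permutation test is exact-null on identical cohorts", {
  g <- generate_cohorts(cohort_spec(n_samples_a = 12, n_samples_b = 12,
                                    n_shared_taxa = 60, seed = 31))
  halves <- split_by_group(g$table, g$metadata)
  r <- compare_scaling_param(halves[[1]], halves[[1]],
                             ple_b_extractor("I"), n_perm = 100, seed = 4)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
  r2 <- compare_scaling_param(halves[[1]], halves[[2]],
                              ple_b_extractor("I"), n_perm = 100, seed = 4)
  expect_gte(r2$p_value, 1 / 101)
})

test_that("the accumulation curve is monotone at q = 0 and flat for replicated samples", {
  g <- generate_cohorts(cohort_spec(n_samples_a = 10, n_samples_b = 10,
                                    n_shared_taxa = 100, abund_sdlog = 2.5,
                                    depth_mean = 300, seed = 17))
  crv <- dar_curve(g$table, q = 0, n_orders = 15, seed = 5)
  expect_true(all(diff(crv$D) >= -1e-9))
  expect_identical(crv$A, 1:20)
  # identical samples: D(A) constant
  one <- matrix(rep(c(5, 3, 0, 2), 6), ncol = 6,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:6)))
  flat <- dar_curve(otu_table(one), q = 1, n_orders = 3, seed = 1)
  expect_true(all(abs(flat$D - flat$D[1]) < 1e-12))
  # determinism
  expect_identical(dar_curve(g$table, 0, 5, seed = 9),
                   dar_curve(g$table, 0, 5, seed = 9))
  expect_error(dar_curve(otu_table(one[, 1:3,
    drop = FALSE]), 0), "4 samples")
})

test_that("DAR fits recover exact PL and PLEC parameters", {
  A <- 1:40
  plec <- data.frame(A = A, D = 10 * A^0.4 * exp(-0.01 * A))
  f <- fit_dar(plec, "PLEC")
  expect_equal(unname(f$c), 10, tolerance = 1e-9)
  expect_equal(unname(f$z), 0.4, tolerance = 1e-11)
  expect_equal(unname(f$d), -0.01, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # PLEC on exact PL data: d ~ 0
  pl <- data.frame(A = A, D = 3 * A^0.7)
  expect_lt(abs(fit_dar(pl, "PLEC")$d), 1e-9)
  expect_equal(unname(fit_dar(pl, "PL")$z), 0.7, tolerance = 1e-12)
  expect_error(fit_dar(plec[1:3, ], "PL"), "4 points")
  expect_error(fit_dar(data.frame(A = c(2, 2, 2, 2), D = 1:4), "PL"),
               "singular")
})

test_that("maximal accrual diversity matches its closed form and an optimiser", {
  f <- fit_dar(data.frame(A = 1:40, D = 10 * (1:40)^0.4 * exp(-0.01 * 1:40)),
               "PLEC")
  md <- dar_mad(f)
  expect_equal(md$A_max, 40, tolerance = 1e-6)
  expect_equal(md$D_max, 10 * 40^0.4 * exp(-0.4), tolerance = 1e-6)
  # closed form vs numerical maximisation for random admissible triples
  set.seed(12)
  for (i in 1:20) {
    cc <- runif(1, 1, 50); z <- runif(1, 0.05, 1.5); d <- -runif(1, 0.001, 0.2)
    fobj <- function(A) cc * A^z * exp(d * A)
    opt <- optimize(fobj, c(1e-6, 10 * (-z / d)), maximum = TRUE, tol = 1e-10)
    fit <- structure(list(c = cc, z = z, d = d, model = "PLEC", q = 0),
                     class = "dar_fit")
    est <- dar_mad(fit)
    expect_equal(est$A_max, opt$maximum, tolerance = 1e-5)
    expect_equal(est$D_max, opt$objective, tolerance = 1e-9)
  }
  bad <- structure(list(c = 2, z = 0.5, d = 0.01, model = "PLEC", q = 0),
                   class = "dar_fit")
  expect_error(dar_mad(bad), "no finite maximum")
  pl <- structure(list(c = 2, z = 0.5, d = NA_real_, model = "PL", q = 0),
                  class = "dar_fit")
  expect_error(dar_mad(pl), "PLEC")
})
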