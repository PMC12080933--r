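test_that("the double-pass variance partition is exact arithmetic", {
  expect_equal(partition_double(4, 0.5),
               c(sigma_e2 = 2, sigma_i2 = 2))
  expect_equal(partition_double(3, 0), c(sigma_e2 = 0, sigma_i2 = 3))
  expect_equal(partition_double(3, 1), c(sigma_e2 = 3, sigma_i2 = 0))
  expect_error(partition_double(-1, 0.5))
})

test_that("equal variance components imply a correlation of one half", {
  expect_identical(dvc_from_variances(2.7, 2.7), 0.5)
  expect_equal(dvc_from_variances(3, 1), 0.75)
  expect_equal(dvc_from_variances(0, 2), 0)
})

test_that("solve_components reproduces hand-computed values", {
  comp <- solve_components(0.4, 0.5, 0.3, 1, sqrt(2))
  expect_equal(comp$sigmaL2, 0.4, tolerance = 1e-12)
  expect_equal(comp$covLB, 0.3 * sqrt(2) - 0.4, tolerance = 1e-12)  # 0.02426
  expect_equal(round(comp$covLB, 5), 0.02426)
  expect_equal(round(comp$sigmaB2, 5), 0.55147)
  expect_equal(comp$sigmaI2_flat, 0.6, tolerance = 1e-12)
  expect_equal(comp$sigmaI2_nat, 1.0, tolerance = 1e-12)
  expect_length(comp$negative_flags, 0)
})

test_that("the zero-covariance case and the identical-experiments case degenerate correctly", {
  # rho_cross = rho_flat * s1/s2 makes cov exactly zero
  s1 <- 1.1; s2 <- 1.7; rf <- 0.45
  comp <- solve_components(rf, 0.6, rf * s1 / s2, s1, s2)
  expect_equal(comp$covLB, 0, tolerance = 1e-12)
  # equal SDs and equal correlations: no depth-driven component
  comp2 <- solve_components(0.5, 0.5, 0.5, 1.3, 1.3)
  expect_equal(comp2$sigmaB2, 0, tolerance = 1e-12)
  expect_equal(comp2$covLB, 0, tolerance = 1e-12)
})

test_that("components and correlations are exact inverses and conserve total variance", {
  set.seed(7)
  for (i in 1:25) {
    sL2 <- runif(1, 0.1, 2)
    sB2 <- runif(1, 0, 2)
    cov <- runif(1, -1, 1) * sqrt(sL2 * sB2) * 0.9
    sIf2 <- runif(1, 0.1, 2)
    sIn2 <- runif(1, 0.1, 2)
    if (sL2 + sB2 + 2 * cov <= 0) next
    rho <- correlations_from_components(sL2, sB2, cov, sIf2, sIn2)
    comp <- solve_components(rho$rho_flat, rho$rho_nat, rho$rho_cross,
                             rho$sigma_flat, rho$sigma_nat)
    expect_equal(comp$sigmaL2, sL2, tolerance = 1e-12)
    expect_equal(comp$sigmaB2, sB2, tolerance = 1e-12)
    expect_equal(comp$covLB, cov, tolerance = 1e-12)
    expect_equal(comp$sigmaI2_flat, sIf2, tolerance = 1e-12)
    expect_equal(comp$sigmaI2_nat, sIn2, tolerance = 1e-12)
    # conservation per experiment
    expect_equal(comp$sigmaE2_flat + comp$sigmaI2_flat, comp$sigmaT2_flat,
                 tolerance = 1e-12)
    expect_equal(comp$sigmaE2_nat + comp$sigmaI2_nat, comp$sigmaT2_nat,
                 tolerance = 1e-12)
    # and back again
    rho2 <- correlations_from_components(comp$sigmaL2, comp$sigmaB2,
                                         comp$covLB, comp$sigmaI2_flat,
                                         comp$sigmaI2_nat)
    expect_equal(rho2$rho_cross, rho$rho_cross, tolerance = 1e-12)
  }
})

test_that("negative algebraic components are flagged, not clipped", {
  comp <- solve_components(0.9, 0.05, 0.9, 1, 1)
  expect_true("sigmaB2" %in% comp$negative_flags)
  expect_lt(comp$sigmaB2, 0)
})

test_that("partial correlation arithmetic and bounds", {
  expect_equal(partial_correlation(0.4, 0.5, 0.8), 0.4 / sqrt(0.4))
  expect_equal(round(partial_correlation(0.4, 0.5, 0.8), 5), 0.63246)
  expect_equal(partial_correlation(0.5, 0.5, 0.5), 1)
  expect_equal(partial_correlation(0, 0.4, 0.9), 0)
  p <- partial_correlation(0.9, 0.5, 0.5)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "clamped"))
  expect_error(partial_correlation(0.3, -0.1, 0.5), "positive")
})

test_that("a constant estimator has a zero-width bootstrap interval", {
  tr <- sim_one_condition(repeats = 20L, seed = 19L)
  ci <- suppressWarnings(bootstrap_ci(tr, function(r) c(k = 42), n_boot = 50L))
  expect_equal(unname(ci$lower), 42)
  expect_equal(unname(ci$upper), 42)
})

test_that("bootstrap resampling is reproducible and respects trial pairing", {
  tr <- sim_one_condition(repeats = 30L, seed = 20L)
  est <- function(r) {
    # any resample must keep all four passes of a unique trial together
    tab <- table(table(r$trial_id))
    stopifnot(identical(names(tab), "4"))
    c(pc = mean(r$chose_comparison))
  }
  c1 <- bootstrap_ci(tr, est, n_boot = 120L, seed = 5L)
  c2 <- bootstrap_ci(tr, est, n_boot = 120L, seed = 5L)
  expect_identical(c1$replicates, c2$replicates)
  c3 <- bootstrap_ci(tr, est, n_boot = 120L, seed = 6L)
  expect_false(identical(c1$replicates, c3$replicates))
  expect_lt(c1$lower, c1$upper)
  expect_warning(bootstrap_ci(tr, est, n_boot = 50L), "unstable")
})

test_that("doubling the resample count leaves percentile endpoints stable", {
  tr <- sim_one_condition(repeats = 50L, seed = 24L)
  est <- function(r) c(pc = mean(r$chose_comparison))
  a <- bootstrap_ci(tr, est, n_boot = 300L, seed = 1L)
  b <- bootstrap_ci(tr, est, n_boot = 600L, seed = 2L)
  w <- a$upper - a$lower
  expect_lt(abs(a$lower - b$lower), 0.5 * w)
  expect_lt(abs(a$upper - b$upper), 0.5 * w)
})

test_that("68% bootstrap intervals for rho have near-nominal coverage", {
  # 200 replicate datasets at 500 trials/condition; rho_true = 0.5
  sigma_tot <- sqrt(2 * 1.28)
  n_rep <- 200L
  hits <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- sim_one_condition(repeats = 100L, sigmaL = 0.8, sigmaB = 0.8,
                            sigmaI = sqrt(1.28), seed = 3000L + i)
    nat <- tr[tr$experiment == "natural", ]
    est <- function(r) c(rho = fit_dvc(tabulate_agreement(r), sigma_tot)$rho)
    ci <- bootstrap_ci(nat, est, n_boot = 120L, level = 0.68,
                       seed = 100L + i)
    hits[i] <- ci$lower <= 0.5 && 0.5 <= ci$upper
  }
  expect_gte(mean(hits), 0.60)
  expect_lte(mean(hits), 0.76)
})
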