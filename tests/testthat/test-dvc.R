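test_that("agreement tabulation uses the canonical pattern order", {
  # hand-built: pass1 = (1,0,1,0), pass2 = (1,0,0,1)
  rec <- make_records(list(c(1L, 0L, 1L, 0L), c(1L, 0L, 0L, 1L)))
  cnt <- tabulate_agreement(rec)
  expect_equal(length(cnt), 1L)
  m <- cnt[[1]]$counts
  expect_equal(rownames(m), c("--", "-+", "+-", "++"))
  expect_equal(as.numeric(m), c(1, 1, 1, 1))
  # identical response vectors put all mass on the agreement patterns
  rec2 <- make_records(list(c(1L, 1L, 0L), c(1L, 1L, 0L)))
  m2 <- tabulate_agreement(rec2)[[1]]$counts
  expect_equal(as.numeric(m2), c(1, 0, 0, 2))
})

test_that("four-pass tabulation of the full design yields 16-pattern tables with complete rows", {
  tr <- sim_recovery_study(seed = 12L, repeats = 20L)
  cnt <- tabulate_agreement(tr)
  expect_equal(attr(cnt, "n_pass"), 4L)
  expect_equal(length(cnt), 5L)  # 5 pedestals x 1 bin
  for (cond in cnt) {
    expect_equal(nrow(cond$counts), 16L)
    expect_true(all(colSums(cond$counts) == 20L))  # repeats per level
  }
})

test_that("misaligned pass groups raise an informative error", {
  rec <- make_records(list(c(1L, 0L), c(0L, 1L)))
  rec$trial_id[rec$pass_idx == 2] <- c(2L, 3L)
  expect_error(tabulate_agreement(rec), "trial_id")
  rec2 <- make_records(list(c(1L, 0L), c(0L, 1L)))
  expect_error(tabulate_agreement(rbind(rec2, rec2)), "more than once")
})

test_that("independent random responses spread over the four patterns evenly", {
  set.seed(5)
  n <- 1e5
  rec <- make_records(list(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5)),
                      comparison = -7.5)  # at the standard: d-prime 0
  cnt <- tabulate_agreement(rec)
  expect_equal(as.numeric(cnt[[1]]$counts) / n, rep(0.25, 4),
               tolerance = 0.03)
  fit <- fit_dvc(cnt, 1.0)
  expect_lt(abs(fit$rho), 0.02)
})

test_that("double-pass correlation recovers the generative value", {
  # equal stimulus and noise variance => rho_true = 0.5
  tr <- sim_one_condition(repeats = 100L, sigmaL = 0.8, sigmaB = 0.8,
                          sigmaI = sqrt(0.8^2 + 0.8^2), seed = 14L)
  nat <- tr[tr$experiment == "natural", ]
  sig_tot <- sqrt(2 * (0.8^2 + 0.8^2))
  fit <- fit_dvc(tabulate_agreement(nat), sig_tot)
  # 500 trials/condition: frozen seed, ~2.5 SE tolerance
  expect_lt(abs(fit$rho - 0.5), 0.12)
  expect_false(fit$boundary)
  expect_equal(fit$sigma_e2 + fit$sigma_i2, sig_tot^2, tolerance = 1e-9)
})

test_that("agreement exactly at the chance curve gives rho of zero", {
  # analytic counts: N * {(1-PC)^2, PC(1-PC), PC(1-PC), PC^2}
  delta <- c(-1, -0.5, 0, 0.5, 1)
  pc <- pnorm(delta / 1.3)
  counts <- rbind((1 - pc)^2, pc * (1 - pc), pc * (1 - pc), pc^2) * 1000
  o <- optimize(function(r)
    doublepass:::cpp_nll_double(counts, delta / 1.3, r, c(0, 0)),
    c(-0.999, 0.999), tol = 1e-9)
  expect_lt(abs(o$minimum), 1e-3)
})

test_that("perfect agreement drives rho to the boundary with a flag", {
  rec <- make_records(list(rep(c(0L, 1L), 25), rep(c(0L, 1L), 25)),
                      comparison = -7.5)
  fit <- fit_dvc(tabulate_agreement(rec), 1.0)
  expect_gt(fit$rho, 0.999)
  expect_true(fit$boundary)
})

test_that("the expected-agreement curve has the right limits and chance form", {
  expect_equal(agreement_curve(0, 0), 0.5, tolerance = 1e-10)
  expect_equal(agreement_curve(1.3, 1), 1, tolerance = 1e-9)
  d76 <- qnorm(0.76)
  expect_equal(agreement_curve(d76, 0), 0.76^2 + 0.24^2, tolerance = 1e-6)
  # increasing in rho at fixed d-prime
  expect_true(all(diff(sapply(c(0, 0.3, 0.6, 0.9), function(r)
    agreement_curve(0.5, r))) > 0))
})

test_that("the fitted correlation maximises the likelihood over a grid", {
  tr <- sim_one_condition(repeats = 60L, seed = 15L)
  cnt <- tabulate_agreement(tr[tr$experiment == "natural", ])
  st <- sqrt(3)
  fit <- fit_dvc(cnt, st)
  dz <- cnt[[1]]$delta / st
  nll_hat <- doublepass:::cpp_nll_double(cnt[[1]]$counts, dz, fit$rho, c(0, 0))
  for (r in seq(-0.95, 0.95, length.out = 21)) {
    expect_gte(doublepass:::cpp_nll_double(cnt[[1]]$counts, dz, r, c(0, 0)),
               nll_hat - 1e-7)
  }
})

test_that("quasi-quadruple-pass estimation recovers known generative correlations", {
  # (sigmaL, sigmaB, sigmaI_flat, sigmaI_nat) = (1, 1, 1, 1), cov = 0:
  # rho_flat = 1/2, rho_nat = 2/3, rho_cross = 1/sqrt(6)
  tr <- sim_one_condition(repeats = 2000L, seed = 5L)
  cnt <- tabulate_agreement(tr)
  fit <- fit_quadpass(cnt, sqrt(2), sqrt(3))
  expect_lt(abs(fit$rho_flat - 0.5), 0.04)
  expect_lt(abs(fit$rho_nat - 2 / 3), 0.04)
  expect_lt(abs(fit$rho_cross - 1 / sqrt(6)), 0.04)
  # the fitted triple beats a coarse grid
  nll <- function(r) doublepass:::cpp_nll_quad(cnt[[1]]$counts,
                                               cnt[[1]]$delta / sqrt(2),
                                               cnt[[1]]$delta / sqrt(3),
                                               r[1], r[2], r[3], 256L)
  nll_hat <- nll(c(fit$rho_flat, fit$rho_nat, fit$rho_cross))
  for (g in list(c(0.4, 0.6, 0.3), c(0.5, 0.7, 0.4), c(0.6, 0.6, 0.45))) {
    expect_gte(nll(g), nll_hat - 1e-6)
  }
})

test_that("statistically identical experiments give matching correlations", {
  # sigmaB = 0 and equal noise: the two experiments are exchangeable, so
  # rho_flat ~ rho_nat ~ rho_cross
  tr <- sim_one_condition(repeats = 1000L, sigmaL = 1, sigmaB = 0,
                          sigmaI = 1, seed = 16L)
  fit <- fit_quadpass(tabulate_agreement(tr), sqrt(2), sqrt(2))
  expect_lt(max(abs(c(fit$rho_flat, fit$rho_nat, fit$rho_cross) - 0.5)), 0.06)
})

test_that("fully independent responses yield near-zero correlations", {
  tr <- sim_one_condition(repeats = 1000L, sigmaL = 0, sigmaB = 0,
                          sigmaI = 1.2, seed = 17L)
  fit <- fit_quadpass(tabulate_agreement(tr), 1.2, 1.2)
  expect_lt(max(abs(c(fit$rho_flat, fit$rho_nat, fit$rho_cross))), 0.05)
})

test_that("the cov-zero constraint ties the cross correlation and matches when cov is truly zero", {
  tr <- sim_one_condition(repeats = 2000L, seed = 5L)
  cnt <- tabulate_agreement(tr)
  free <- fit_quadpass(cnt, sqrt(2), sqrt(3))
  tied <- fit_quadpass(cnt, sqrt(2), sqrt(3), cov_zero = TRUE)
  expect_equal(tied$rho_cross, tied$rho_flat * sqrt(2) / sqrt(3),
               tolerance = 1e-9)
  # constrained fit cannot beat the free fit, and loses little when cov = 0
  expect_lte(tied$loglik, free$loglik + 1e-6)
  expect_lt(free$loglik - tied$loglik, 3)
  expect_lt(abs(tied$rho_flat - free$rho_flat), 0.05)
  # the implied components agree across the two fitting modes
  cf <- solve_components(free$rho_flat, free$rho_nat, free$rho_cross,
                         sqrt(2), sqrt(3))
  ct <- solve_components(tied$rho_flat, tied$rho_nat, tied$rho_cross,
                         sqrt(2), sqrt(3))
  expect_lt(abs(cf$sigmaB2 - ct$sigmaB2), 0.15)
  expect_lt(abs(ct$covLB), 1e-9)
})

test_that("between-observer estimation reduces to within-observer for duplicated data", {
  tr <- sim_one_condition(repeats = 500L, seed = 18L)
  nat <- tr[tr$experiment == "natural", ]
  # observer 2 is a relabelled copy of observer 1
  groups <- list(list(experiment = "natural", pass_idx = 1L),
                 list(experiment = "natural", pass_idx = 2L),
                 list(experiment = "natural", pass_idx = 1L),
                 list(experiment = "natural", pass_idx = 2L))
  cnt <- tabulate_agreement(nat, pass_groups = groups)
  st <- sqrt(3)
  bet <- fit_between(cnt, st, st)
  within <- fit_dvc(tabulate_agreement(nat), st)
  # duplicated passes are degenerate: the cross correlation is pushed to its
  # positive-semidefinite bound, which couples the within-observer estimates;
  # they still track the within-observer fit closely
  expect_lt(abs(bet$rho_11 - within$rho), 0.12)
  expect_lt(abs(bet$rho_22 - within$rho), 0.2)
  expect_gt(bet$rho_12, 0.85)
})

test_that("fully shared stimulus drive gives a partial correlation near one", {
  a <- sim_one_condition(repeats = 500L, sigmaL = 1, sigmaB = 0.6,
                         sigmaI = 1, seed = 21L, stimulus_seed = 7L)
  b <- sim_one_condition(repeats = 500L, sigmaL = 1, sigmaB = 0.6,
                         sigmaI = 1, seed = 22L, stimulus_seed = 7L)
  b$observer_id <- "obs2"
  nat <- rbind(a[a$experiment == "natural", ], b[b$experiment == "natural", ])
  groups <- list(list(experiment = "natural", pass_idx = 1L, observer_id = "obs1"),
                 list(experiment = "natural", pass_idx = 2L, observer_id = "obs1"),
                 list(experiment = "natural", pass_idx = 1L, observer_id = "obs2"),
                 list(experiment = "natural", pass_idx = 2L, observer_id = "obs2"))
  cnt <- tabulate_agreement(nat, pass_groups = groups)
  st <- sqrt(1 + 0.6^2 + 1)
  bet <- fit_between(cnt, st, st)
  expect_gt(bet$partial, 0.85)
  # independent stimulus draws instead: between-observer correlation ~ 0
  c2 <- sim_one_condition(repeats = 500L, sigmaL = 1, sigmaB = 0.6,
                          sigmaI = 1, seed = 23L, stimulus_seed = 8L)
  c2$observer_id <- "obs2"
  nat2 <- rbind(a[a$experiment == "natural", ],
                c2[c2$experiment == "natural", ])
  bet2 <- fit_between(tabulate_agreement(nat2, pass_groups = groups), st, st)
  expect_lt(abs(bet2$rho_12), 0.08)
})
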