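# Parameter-recovery machinery shared by the acceptance checks: simulate
# observers at the study scale from known generative components, estimate
# correlations and components, and bootstrap their confidence intervals.

RECOVERY_TRUTH <- list(rho_flat = 0.5, rho_nat = 2 / 3,
                       rho_cross = 1 / sqrt(6),
                       sigmaL2 = 1, sigmaB2 = 1, covLB = 0,
                       sigmaI2_flat = 1, sigmaI2_nat = 1)

# full analysis of one observer's single-bin records at one pedestal:
# constrained threshold fits for both experiments, quasi-quadruple-pass fit
# at the analysed pedestal, components via the closed-form solution.
# `warm` supplies starting values and cheap settings for bootstrap refits.
quad_analysis <- function(records, pedestal, warm = NULL) {
  thr <- list(
    flat = fit_thresholds(records[records$experiment == "flattened", ],
                          start = warm$thr_flat,
                          reltol = if (is.null(warm)) 1e-8 else 1e-7),
    nat = fit_thresholds(records[records$experiment == "natural", ],
                         start = warm$thr_nat,
                         reltol = if (is.null(warm)) 1e-8 else 1e-7))
  sub <- records[records$pedestal_arcmin == pedestal, ]
  cnt <- tabulate_agreement(sub)
  s1 <- as.numeric(predict(thr$flat, pedestal))
  s2 <- as.numeric(predict(thr$nat, pedestal))
  fit <- fit_quadpass(cnt, s1, s2,
                      npts = if (is.null(warm)) 256L else 32L,
                      start = warm$rho,
                      reltol = if (is.null(warm)) 1e-8 else 1e-6)
  comp <- solve_components(fit$rho_flat, fit$rho_nat, fit$rho_cross, s1, s2)
  list(thr = thr, fit = fit, comp = comp,
       values = c(rho_flat = fit$rho_flat, rho_nat = fit$rho_nat,
                  rho_cross = fit$rho_cross,
                  sigmaL2 = comp$sigmaL2, sigmaB2 = comp$sigmaB2,
                  covLB = comp$covLB, sigmaI2_flat = comp$sigmaI2_flat,
                  sigmaI2_nat = comp$sigmaI2_nat))
}

# one recovery replicate: `n_obs` observers sharing the stimulus stream
# (as in the real study design), each analysed at `pedestal`, with a
# trial-level bootstrap CI around every estimate.  Returns a matrix of
# logicals: does the CI cover the generative value?
recovery_replicate <- function(rep_seed, pedestal, n_obs = 3L,
                               n_boot = 200L, level = 0.95) {
  stim_seed <- doublepass:::derive_seed(rep_seed, 1L)
  covered <- NULL
  for (obs in seq_len(n_obs)) {
    cfg <- design_config(contrast_bins = "high",
                         repeats_per_comparison = 100L,
                         comparison_step = 1.2, seed = rep_seed)
    gp <- generative_params(contrast_bins = "high", sigmaL = 1, sigmaB = 1,
                            covLB = 0, sigmaI_flat = 1, sigmaI_nat = 1)
    rec <- simulate_observer(build_design(cfg, paste0("obs", obs)), gp,
                             seed = doublepass:::derive_seed(rep_seed, 100L + obs),
                             stimulus_seed = stim_seed)
    point <- quad_analysis(rec, pedestal)
    warm <- list(thr_flat = unname(coef(point$thr$flat)),
                 thr_nat = unname(coef(point$thr$nat)),
                 rho = as.numeric(point$values[1:3]))
    est <- function(r) quad_analysis(r, pedestal, warm = warm)$values
    ci <- bootstrap_ci(rec, est, n_boot = n_boot, level = level,
                       seed = doublepass:::derive_seed(rep_seed, 200L + obs))
    truth <- unlist(RECOVERY_TRUTH)[names(point$values)]
    covered <- rbind(covered, ci$lower <= truth & truth <= ci$upper)
  }
  covered
}
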