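# Shared fixture builders.  Everything is generated in code at test time;
# seeds are fixed so every run sees identical data.

# one-condition double-pass (two experiments) dataset with constant
# generative SDs; "paper scale" is repeats = 100 (500 trials per condition
# over 5 comparison levels)
sim_one_condition <- function(repeats = 100L, sigmaL = 1, sigmaB = 1,
                              covLB = 0, sigmaI = 1, seed = 1L,
                              pedestal = -7.5, bin = "high", step = 1.2,
                              stimulus_seed = NULL) {
  cfg <- design_config(pedestals = pedestal, contrast_bins = bin,
                       repeats_per_comparison = as.integer(repeats),
                       comparison_step = step, seed = seed)
  gp <- generative_params(pedestals = pedestal, contrast_bins = bin,
                          sigmaL = sigmaL, sigmaB = sigmaB, covLB = covLB,
                          sigmaI_flat = sigmaI, sigmaI_nat = sigmaI)
  simulate_observer(build_design(cfg), gp, seed = seed,
                    stimulus_seed = stimulus_seed)
}

# five-pedestal single-bin study with constant component SDs (the
# parameter-recovery configuration: 500 trials per condition)
sim_recovery_study <- function(seed, repeats = 100L, sigmaL = 1, sigmaB = 1,
                               sigmaI = 1, observer_id = "obs1") {
  cfg <- design_config(contrast_bins = "high",
                       repeats_per_comparison = as.integer(repeats),
                       comparison_step = 1.2, seed = seed)
  gp <- generative_params(contrast_bins = "high", sigmaL = sigmaL,
                          sigmaB = sigmaB, covLB = 0,
                          sigmaI_flat = sigmaI, sigmaI_nat = sigmaI)
  simulate_observer(build_design(cfg, observer_id = observer_id), gp,
                    seed = seed)
}

# constrained threshold fits for both experiments of a single-bin dataset
fit_both_thresholds <- function(records) {
  list(flat = fit_thresholds(records[records$experiment == "flattened", ]),
       nat = fit_thresholds(records[records$experiment == "natural", ]))
}

# tiny hand-rolled records data.frame for tabulation tests
make_records <- function(resp_by_pass, pedestal = -7.5, bin = "low",
                         comparison = -6.5, experiment = "natural") {
  n <- length(resp_by_pass[[1]])
  do.call(rbind, lapply(seq_along(resp_by_pass), function(p) {
    data.frame(observer_id = "obs1", experiment = experiment,
               pass_idx = p, trial_id = seq_len(n),
               pedestal_arcmin = pedestal, contrast_bin = bin,
               comparison_arcmin = comparison,
               interval_of_comparison = 1L,
               chose_comparison = resp_by_pass[[p]],
               stringsAsFactors = FALSE)
  }))
}
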