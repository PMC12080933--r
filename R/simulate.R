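#' Generative decision-variable parameters
#'
#' Per-condition standard deviations of the components of the decision
#' variable under the generative model
#' `D = (delta_cmp - delta_std) + L + B + W`: a luminance-driven component
#' `L` shared by all four passes of both experiments, a depth-driven
#' component `B` present only in the natural experiment and shared by its two
#' passes, and internal noise `W` drawn fresh on every pass.  All SDs are in
#' arcmin of disparity at the level of the trial's decision variable.
#'
#' Each of `sigmaL`, `sigmaB`, `covLB`, `sigmaI_flat`, `sigmaI_nat` may be a
#' single number, a vector named by contrast bin (recycled over pedestals),
#' or a function of `(pedestal, bin)` returning a number.  The defaults
#' emulate the headline empirical pattern of natural-stimulus disparity
#' discrimination: total SD follows a log-linear law in the pedestal,
#' luminance-driven variance is independent of the disparity-contrast bin,
#' depth-driven variance grows with it, and the interaction covariance is
#' zero.
#'
#' @param pedestals,contrast_bins condition grid (defaults match
#'   [design_config()]).
#' @param sigmaL SD of the luminance-driven component, arcmin.
#' @param sigmaB SD of the depth-driven component, arcmin (applies to the
#'   natural experiment only).
#' @param covLB covariance between L and B, arcmin^2.
#' @param sigmaI_flat,sigmaI_nat internal-noise SDs in the flattened and
#'   natural experiments, arcmin.
#' @param criterion decision criterion (default 0).
#' @param step_m,step_b log-linear law used by the defaults, matching
#'   [design_config()].
#' @return an object of class `generative_params`: a `data.frame` with one
#'   row per (pedestal, bin).
#' @export
generative_params <- function(pedestals = c(-11.25, -9.38, -7.5, -5.63, -3.75),
                              contrast_bins = c("low", "high"),
                              sigmaL = NULL, sigmaB = NULL, covLB = 0,
                              sigmaI_flat = NULL, sigmaI_nat = NULL,
                              criterion = 0,
                              step_m = -0.15, step_b = -1.05) {
  grid <- expand.grid(pedestal_arcmin = pedestals,
                      contrast_bin = as.character(contrast_bins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_sd <- exp(step_m * grid$pedestal_arcmin + step_b)
  # default partition: ~45% of flattened-experiment variance is
  # luminance-driven; the depth-driven SD scales with the bin
  dflt <- list(
    sigmaL = sqrt(0.45) * base_sd,
    sigmaB = ifelse(grid$contrast_bin == "high", 0.9, 0.35) * base_sd,
    sigmaI_flat = sqrt(0.55) * base_sd,
    sigmaI_nat = sqrt(0.55) * base_sd)
  resolve <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.function(x))
      return(mapply(x, grid$pedestal_arcmin, grid$contrast_bin))
    if (!is.null(names(x)) && all(names(x) %in% grid$contrast_bin))
      return(unname(x[grid$contrast_bin]))
    rep_len(x, nrow(grid))
  }
  out <- data.frame(grid,
                    sigmaL = resolve(sigmaL, dflt$sigmaL),
                    sigmaB = resolve(sigmaB, dflt$sigmaB),
                    covLB = resolve(covLB, rep(0, nrow(grid))),
                    sigmaI_flat = resolve(sigmaI_flat, dflt$sigmaI_flat),
                    sigmaI_nat = resolve(sigmaI_nat, dflt$sigmaI_nat),
                    criterion = rep_len(criterion, nrow(grid)),
                    stringsAsFactors = FALSE)
  if (any(out$sigmaL < 0 | out$sigmaB < 0 | out$sigmaI_flat < 0 |
          out$sigmaI_nat < 0))
    stop("all component SDs must be non-negative")
  bad <- abs(out$covLB) > out$sigmaL * out$sigmaB &
    abs(out$covLB) > 0
  if (any(bad))
    stop("covLB must satisfy |covLB| <= sigmaL * sigmaB")
  class(out) <- c("generative_params", "data.frame")
  out
}

#' Simulate observer responses for a double-pass schedule
#'
#' Completes the `chose_comparison` column of a schedule from
#' [build_design()] under the generative decision-variable model.  For each
#' unique trial the stimulus-driven draws are made once -- `L` (jointly with
#' `B` when `covLB != 0`) is shared by all passes of both experiments, `B`
#' enters the natural experiment only -- and internal noise `W` is drawn
#' independently per experiment and pass.  The response on a pass is
#' `chose_comparison = 1` iff `D > criterion`.
#'
#' Stimulus draws and noise draws come from separate seeded streams so that
#' two observers simulated with the same `stimulus_seed` but different
#' `seed`s see identical stimulus perturbations with independent noise (the
#' shared-stimulus configuration of between-observer analyses).
#'
#' @param schedule a schedule from [build_design()].
#' @param params a [generative_params()] covering every (pedestal, bin) in
#'   the schedule.
#' @param seed integer seed for the internal-noise stream.
#' @param stimulus_seed integer seed for the stimulus-perturbation stream;
#'   defaults to a stream derived from `seed`.
#' @return the schedule with `chose_comparison` filled in (0/1).
#' @export
#' @examples
#' cfg <- design_config(pedestals = -7.5, contrast_bins = "low",
#'                      repeats_per_comparison = 10L)
#' trials <- simulate_observer(build_design(cfg), generative_params(
#'   pedestals = -7.5, contrast_bins = "low"), seed = 7)
#' table(trials$chose_comparison)
simulate_observer <- function(schedule, params, seed = 1L,
                              stimulus_seed = NULL) {
  stopifnot(is.data.frame(schedule), inherits(params, "generative_params"))
  if (is.null(stimulus_seed)) stimulus_seed <- derive_seed(seed, 9001L)
  key_s <- paste(schedule$pedestal_arcmin, schedule$contrast_bin)
  key_p <- paste(params$pedestal_arcmin, params$contrast_bin)
  miss <- setdiff(unique(key_s), key_p)
  if (length(miss) > 0)
    stop("no generative parameters for condition(s): ",
         paste(miss, collapse = "; "))
  idx <- match(key_s, key_p)

  # one row per unique trial, in trial_id order
  uniq <- !duplicated(schedule$trial_id)
  ord <- order(schedule$trial_id[uniq])
  u_rows <- which(uniq)[ord]
  n_u <- length(u_rows)
  pidx_u <- idx[u_rows]

  sL <- params$sigmaL[pidx_u]
  sB <- params$sigmaB[pidx_u]
  cLB <- params$covLB[pidx_u]

  set.seed(derive_seed(stimulus_seed, 11L))
  zL <- rnorm(n_u)
  zB <- rnorm(n_u)
  L <- sL * zL
  # conditional construction gives the requested covariance exactly in
  # distribution: B = (cov/sigmaL^2) L + sqrt(sigmaB^2 - cov^2/sigmaL^2) zB
  B <- ifelse(sL > 0 & sB > 0,
              (cLB / pmax(sL^2, 1e-300)) * L +
                sqrt(pmax(sB^2 - cLB^2 / pmax(sL^2, 1e-300), 0)) * zB,
              sB * zB)

  trial_of_row <- match(schedule$trial_id, schedule$trial_id[u_rows])
  delta <- schedule$comparison_arcmin - schedule$pedestal_arcmin
  is_nat <- schedule$experiment == first_experiment(schedule)
  V <- L[trial_of_row] + ifelse(is_nat, B[trial_of_row], 0)

  sigI <- ifelse(is_nat, params$sigmaI_nat[idx], params$sigmaI_flat[idx])
  set.seed(derive_seed(seed, 13L))
  W <- rnorm(nrow(schedule)) * sigI

  D <- delta + V + W
  schedule$chose_comparison <- as.integer(D > params$criterion[idx])
  schedule
}

# the experiment treated as carrying the depth-driven component: "natural"
# when present, otherwise the first experiment label in the data
first_experiment <- function(records) {
  ex <- unique(records$experiment)
  if ("natural" %in% ex) "natural" else ex[[1]]
}
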