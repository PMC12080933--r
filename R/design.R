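#' Configuration of the double-pass study design
#'
#' Describes a fully crossed two-experiment double-pass design: disparity
#' pedestals crossed with disparity-contrast bins, a fixed set of comparison
#' levels per pedestal (method of constant stimuli), a number of repeats per
#' comparison, and two passes per experiment.  The defaults reproduce the
#' reference design: 5 pedestals ([-11.25, -9.38, -7.5, -5.63, -3.75] arcmin,
#' negative = uncrossed) x 2 disparity-contrast bins x 5 comparison levels x
#' 100 repeats, giving 5000 unique trials per experiment and 20,000
#' presentations per observer over both passes of both experiments.
#'
#' Comparison levels are symmetric around each standard and include it
#' (offsets `comparison_offsets * step`), so the middle level sits at the
#' standard itself, where percent-comparison-chosen is 50% -- the least
#' informative point for thresholds but the most informative for
#' decision-variable correlation.  The default step scales with the expected
#' log-linear threshold law so that noiseless percent-comparison-chosen spans
#' roughly 10-90%.
#'
#' @param pedestals standard disparities, arcmin (signed, negative =
#'   uncrossed).
#' @param contrast_bins labels of the two disparity-contrast bins.
#' @param comparisons_per_pedestal number of comparison levels (odd).
#' @param repeats_per_comparison repeats of each comparison level.
#' @param n_passes passes per experiment.
#' @param experiments experiment labels; the first is treated as having
#'   depth-driven stimulus variance, the second as flattened.
#' @param comparison_step step between adjacent comparison levels, arcmin;
#'   either a single value or one per pedestal.  The default is
#'   `0.7 * exp(step_m * pedestal + step_b)`, tracking the threshold law.
#' @param step_m,step_b slope and intercept of the log-linear threshold law
#'   used to set the default comparison step (per arcmin; log arcmin).
#' @param seed integer seed used for interval-order randomisation.
#' @return an object of class `design_config`.
#' @export
design_config <- function(pedestals = c(-11.25, -9.38, -7.5, -5.63, -3.75),
                          contrast_bins = c("low", "high"),
                          comparisons_per_pedestal = 5L,
                          repeats_per_comparison = 100L,
                          n_passes = 2L,
                          experiments = c("natural", "flattened"),
                          comparison_step = NULL,
                          step_m = -0.15, step_b = -1.05,
                          seed = 1L) {
  if (comparisons_per_pedestal < 1 || repeats_per_comparison < 1 ||
      n_passes < 1 || length(pedestals) < 1 || length(contrast_bins) < 1)
    stop("design counts must be positive")
  if (comparisons_per_pedestal %% 2 == 0)
    stop("comparisons_per_pedestal must be odd (levels straddle the standard)")
  if (is.null(comparison_step))
    comparison_step <- 0.7 * exp(step_m * pedestals + step_b)
  comparison_step <- rep_len(comparison_step, length(pedestals))
  structure(list(pedestals = pedestals,
                 contrast_bins = as.character(contrast_bins),
                 comparisons_per_pedestal = as.integer(comparisons_per_pedestal),
                 repeats_per_comparison = as.integer(repeats_per_comparison),
                 n_passes = as.integer(n_passes),
                 experiments = as.character(experiments),
                 comparison_step = comparison_step,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  n_unique <- length(x$pedestals) * length(x$contrast_bins) *
    x$comparisons_per_pedestal * x$repeats_per_comparison
  cat("Double-pass design configuration\n")
  cat("  pedestals (arcmin):", paste(x$pedestals, collapse = ", "), "\n")
  cat("  contrast bins:     ", paste(x$contrast_bins, collapse = ", "), "\n")
  cat("  comparisons x repeats:", x$comparisons_per_pedestal, "x",
      x$repeats_per_comparison, "\n")
  cat("  experiments:", paste(x$experiments, collapse = ", "),
      " passes:", x$n_passes, "\n")
  cat("  unique trials per experiment:", n_unique, "\n")
  invisible(x)
}

#' Comparison levels for one pedestal
#'
#' @param config a [design_config()].
#' @param pedestal one of `config$pedestals`.
#' @return numeric vector of comparison disparities, arcmin.
#' @export
comparison_levels <- function(config, pedestal) {
  i <- match(pedestal, config$pedestals)
  if (is.na(i)) stop("pedestal not in design")
  k <- (config$comparisons_per_pedestal - 1L) / 2L
  pedestal + (-k:k) * config$comparison_step[i]
}

#' Build the trial schedule for a double-pass study
#'
#' Expands a [design_config()] into one stub row per (experiment, unique
#' trial, pass) with empty responses.  Trial ids are shared one-to-one across
#' the two experiments (paired scene locations), so the same `trial_id`
#' denotes the natural and flattened version of the same stimulus pair.  The
#' interval containing the comparison is randomised per unique trial from the
#' design seed and is identical across passes (and across the paired
#' experiments) of that trial.
#'
#' @param config a [design_config()].
#' @param observer_id observer label attached to every row.
#' @return a `data.frame` with columns `observer_id`, `experiment`,
#'   `pass_idx`, `trial_id`, `pedestal_arcmin`, `contrast_bin`,
#'   `comparison_arcmin`, `interval_of_comparison`, `chose_comparison`
#'   (`NA` until simulated or loaded).
#' @export
#' @examples
#' sched <- build_design(design_config(repeats_per_comparison = 2L))
#' nrow(sched)  # 2 experiments x 2 passes x 100 unique trials
build_design <- function(config, observer_id = "obs1") {
  stopifnot(inherits(config, "design_config"))
  cells <- expand.grid(pedestal_arcmin = config$pedestals,
                       contrast_bin = config$contrast_bins,
                       comparison_idx = seq_len(config$comparisons_per_pedestal),
                       repeat_idx = seq_len(config$repeats_per_comparison),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- (config$comparisons_per_pedestal - 1L) / 2L
  step <- config$comparison_step[match(cells$pedestal_arcmin, config$pedestals)]
  cells$comparison_arcmin <- cells$pedestal_arcmin +
    (cells$comparison_idx - 1L - k) * step
  n_unique <- nrow(cells)
  cells$trial_id <- seq_len(n_unique)
  set.seed(derive_seed(config$seed, 101L))
  interval <- sample(c(1L, 2L), n_unique, replace = TRUE)
  out <- do.call(rbind, lapply(config$experiments, function(ex) {
    do.call(rbind, lapply(seq_len(config$n_passes), function(p) {
      data.frame(observer_id = observer_id, experiment = ex, pass_idx = p,
                 trial_id = cells$trial_id,
                 pedestal_arcmin = cells$pedestal_arcmin,
                 contrast_bin = cells$contrast_bin,
                 comparison_arcmin = cells$comparison_arcmin,
                 interval_of_comparison = interval,
                 chose_comparison = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# derive a reproducible sub-seed (< 2^31) from a base seed and a stream tag
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}
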