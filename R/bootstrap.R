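#' Trial-level bootstrap confidence intervals
#'
#' Percentile bootstrap for any estimator operating on trial records.  The
#' resampling unit is the unique trial: within every (pedestal, bin,
#' comparison-level) cell, unique trial ids are resampled with replacement,
#' and every pass of a resampled trial -- in both experiments and, when
#' present, both observers -- travels with it.  This preserves the
#' between-pass and between-experiment pairing that all the correlation
#' estimators condition on.
#'
#' @param records completed trial records.
#' @param estimator function taking a records data.frame and returning a
#'   numeric vector (named, ideally) of per-condition scalars.
#' @param n_boot number of bootstrap resamples (values below 100 trigger a
#'   warning).
#' @param level confidence level (default 0.68, the conventional
#'   one-standard-error band of double-pass studies; 0.95 for the
#'   between-observer analyses).
#' @param seed integer seed; resampling is reproducible given it.
#' @return list with `estimate` (estimator on the original records), `lower`
#'   and `upper` (percentile bounds), `level`, `n_boot`, and `replicates`
#'   (the `n_boot` x k matrix of bootstrap estimates).
#' @export
bootstrap_ci <- function(records, estimator, n_boot = 200L, level = 0.68,
                         seed = 1L) {
  stopifnot(is.data.frame(records), is.function(estimator))
  if (n_boot < 100L)
    warning("n_boot < 100 gives unstable percentile intervals")
  est <- estimator(records)
  cell <- paste(records$pedestal_arcmin, records$contrast_bin,
                records$comparison_arcmin, sep = "\r")
  # unique trials and the cell each belongs to (cells are constant within a
  # trial across passes/experiments by design)
  first <- !duplicated(records$trial_id)
  u_ids <- records$trial_id[first]
  u_cell <- cell[first]
  rows_of_trial <- split(seq_len(nrow(records)),
                         match(records$trial_id, u_ids))
  trials_of_cell <- split(seq_along(u_ids), u_cell)
  set.seed(derive_seed(seed, 4242L))
  reps <- matrix(NA_real_, n_boot, length(est))
  colnames(reps) <- names(est)
  for (b in seq_len(n_boot)) {
    pick <- unlist(lapply(trials_of_cell, function(tr)
      tr[sample.int(length(tr), length(tr), replace = TRUE)]),
      use.names = FALSE)
    rows <- unlist(rows_of_trial[pick], use.names = FALSE)
    res <- records[rows, , drop = FALSE]
    # relabel so duplicated trials stay aligned across their passes but are
    # distinct resampling units
    res$trial_id <- rep(seq_along(pick),
                        lengths(rows_of_trial[pick]))
    reps[b, ] <- estimator(res)
  }
  alpha <- (1 - level) / 2
  list(estimate = est,
       lower = apply(reps, 2, quantile, probs = alpha, na.rm = TRUE,
                     names = FALSE),
       upper = apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
                     names = FALSE),
       level = level, n_boot = n_boot, replicates = reps)
}
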