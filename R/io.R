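TRIAL_COLUMNS <- c("observer_id", "experiment", "pass_idx", "trial_id",
                   "pedestal_arcmin", "contrast_bin", "comparison_arcmin",
                   "interval_of_comparison", "chose_comparison")

#' Write / read trial records as CSV
#'
#' The on-disk schema is fixed: a header line
#' `observer_id,experiment,pass_idx,trial_id,pedestal_arcmin,contrast_bin,comparison_arcmin,interval_of_comparison,chose_comparison`
#' followed by one row per presentation, full double precision for the
#' disparity columns.
#'
#' @param records trial records `data.frame`.
#' @param path CSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   records `data.frame`.
#' @export
write_trials <- function(records, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(records[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(rec))
  if (length(miss)) stop("trial CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  rec
}
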