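#' Window-averaged disparity decision variable
#'
#' For a trial described by per-pixel disparity maps of its comparison and
#' standard stimuli, computes the decision variable of a spatial-integration
#' observer: the mean of `delta_cmp(x) - delta_std(x)` over a pillbox window
#' of the given diameter centred on the patch centre.  A pixel belongs to
#' the pillbox when its centre lies within `diameter/2` of the patch centre
#' (boundary ties included); diameter 1 reduces to the central-pixel
#' difference and the full patch width to the unweighted patch mean.
#'
#' @param cmp_map,std_map disparity maps (arcmin per pixel), same shape.
#' @param diameter_px pillbox diameter in pixels, in `[1, patch width]`.
#' @return decision variable, arcmin.
#' @export
windowed_dv <- function(cmp_map, std_map, diameter_px) {
  stopifnot(identical(dim(cmp_map), dim(std_map)))
  dm <- dim(cmp_map)
  # the patch diagonal is the largest useful pillbox: it covers every pixel
  if (diameter_px < 1 || diameter_px > sqrt(sum(dm^2)) + 1e-9)
    stop("diameter must lie in [1, patch diagonal]")
  ctr <- centre_px(dm)
  r2 <- outer((seq_len(dm[1]) - ctr[1])^2, (seq_len(dm[2]) - ctr[2])^2, `+`)
  inside <- r2 <= (diameter_px / 2)^2 + 1e-9
  if (!any(inside)) stop("empty integration window")
  mean((cmp_map - std_map)[inside])
}

#' Heuristic disparity decision variables
#'
#' Decision variables for three single-statistic observers: the largest
#' near disparity (`"nearest"`: maximum signed disparity, more positive =
#' nearer under the uncrossed-negative convention), the largest far
#' disparity (`"farthest"`: minimum signed disparity), and the maximally
#' deviant disparity (`"max_deviant"`: the pixel value farthest from the
#' map's central value, signed value returned).  The decision variable is
#' the heuristic of the comparison map minus that of the standard map.
#'
#' @param cmp_map,std_map disparity maps (arcmin per pixel).
#' @param heuristic one of `"nearest"`, `"farthest"`, `"max_deviant"`.
#' @return decision variable, arcmin.
#' @export
heuristic_dv <- function(cmp_map, std_map,
                         heuristic = c("nearest", "farthest", "max_deviant")) {
  heuristic <- match.arg(heuristic)
  stopifnot(identical(dim(cmp_map), dim(std_map)))
  stat <- function(m) {
    switch(heuristic,
           nearest = max(m),
           farthest = min(m),
           max_deviant = {
             ctr <- centre_px(dim(m))
             m[which.max(abs(m - m[ctr[1], ctr[2]]))]
           })
  }
  stat(cmp_map) - stat(std_map)
}

#' Compare spatial-integration models of trial-by-trial responses
#'
#' For each candidate decision-variable model (pillbox windows of several
#' diameters and/or disparity heuristics), regresses the binary responses on
#' the model's per-trial decision variable by logistic regression with
#' group-specific terms (one intercept and one slope per grouping cell,
#' emulating a random-effects structure conditioned on pedestal,
#' disparity-contrast bin and observer), and reports McFadden's pseudo-R^2
#' (absolute, against the group-intercept null) and AIC.  `delta_aic` is
#' relative to the first model in the list, conventionally the 1-px
#' central-pixel model, so positive values mean a worse fit than the
#' central-pixel account.
#'
#' @param trials list of trials, each a list with `cmp_map`, `std_map`, and
#'   optional grouping fields.
#' @param responses 0/1 vector, one per trial.
#' @param diameters pillbox diameters to test (px).
#' @param heuristics heuristic names to test (see [heuristic_dv()]).
#' @param grouping optional factor (or data.frame of factors) with one row
#'   per trial; `NULL` fits a single group.
#' @param slope_by_group if `FALSE`, only intercepts vary by group.
#' @return `data.frame` with one row per model: `model`, `pseudo_r2`,
#'   `aic`, `delta_aic`, `n`, `separation`.
#' @export
compare_models <- function(trials, responses, diameters = c(1, 4, 8, 16, 32),
                           heuristics = character(0), grouping = NULL,
                           slope_by_group = TRUE) {
  stopifnot(length(trials) == length(responses), length(trials) > 0)
  n <- length(trials)
  grp <- if (is.null(grouping)) factor(rep("all", n))
  else if (is.data.frame(grouping)) interaction(grouping, drop = TRUE)
  else factor(grouping)
  dm <- dim(trials[[1]]$cmp_map)
  models <- c(lapply(diameters, function(d) list(label = sprintf("window_%dpx", d),
                                                 fun = function(tr) windowed_dv(tr$cmp_map, tr$std_map, d))),
              lapply(heuristics, function(h) list(label = h,
                                                  fun = function(tr) heuristic_dv(tr$cmp_map, tr$std_map, h))))
  rows <- lapply(models, function(m) {
    da <- vapply(trials, m$fun, numeric(1))
    sep <- FALSE
    fml <- if (nlevels(grp) > 1) {
      if (slope_by_group) responses ~ 0 + grp + grp:da else responses ~ 0 + grp + da
    } else responses ~ da
    fit <- withCallingHandlers(
      glm(fml, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    null_fml <- if (nlevels(grp) > 1) responses ~ 0 + grp else responses ~ 1
    nul <- suppressWarnings(glm(null_fml, family = binomial()))
    r2 <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(nul))
    data.frame(model = m$label, pseudo_r2 = r2, aic = AIC(fit),
               n = n, separation = sep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out[, c("model", "pseudo_r2", "aic", "delta_aic", "n", "separation")]
}

#' Simulate disparity-map trials for spatial-integration analyses
#'
#' Generates trials whose standard and comparison stimuli carry smooth
#' disparity maps (central value equal to the nominal disparity, surround
#' varying with the requested disparity-contrast), plus responses from a
#' model observer that integrates over a pillbox of diameter
#' `observer_diameter_px` (1 = central pixel) and adds internal noise.
#'
#' @param n_trials number of trials.
#' @param pedestal standard disparity, arcmin.
#' @param delta comparison-minus-standard difference(s), arcmin (recycled).
#' @param dc_arcmin disparity-contrast of the surround.
#' @param observer_diameter_px integration diameter of the generative
#'   observer.
#' @param sigma_noise internal-noise SD, arcmin.
#' @param size_px map size.
#' @param seed integer seed.
#' @return list with `trials` (list of `cmp_map`/`std_map`) and `responses`.
#' @export
simulate_map_trials <- function(n_trials, pedestal = -7.5, delta = 0.75,
                                dc_arcmin = 0.75, observer_diameter_px = 1,
                                sigma_noise = 0.3, size_px = 16L, seed = 1L) {
  set.seed(derive_seed(seed, 555L))
  delta <- rep_len(delta, n_trials)
  mk_map <- function(centre_val) {
    pert <- smooth_noise(size_px, passes = 1)
    ctr <- centre_px(c(size_px, size_px))
    pert <- pert - pert[ctr[1], ctr[2]]  # centre pixel exactly nominal
    sc <- sqrt(mean(pert^2))
    centre_val + pert * (dc_arcmin / max(sc, 1e-12))
  }
  trials <- lapply(seq_len(n_trials), function(i)
    list(cmp_map = mk_map(pedestal + delta[i]), std_map = mk_map(pedestal)))
  dv <- vapply(trials, function(tr)
    windowed_dv(tr$cmp_map, tr$std_map, observer_diameter_px), numeric(1))
  responses <- as.integer(dv + rnorm(n_trials, sd = sigma_noise) > 0)
  list(trials = trials, responses = responses)
}
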