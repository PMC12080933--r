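#' Percent comparison chosen from d-prime (2IFC)
#'
#' Classical two-interval forced-choice conversion `PC = Phi(d'/sqrt(2))`,
#' where `d'` is the per-interval sensitivity index.  With the criterion
#' d-prime of 1 used to define threshold, performance sits at the 76% point
#' of the psychometric function.
#'
#' @param dprime sensitivity index (per-interval convention).
#' @return proportion comparison chosen, in (0, 1).
#' @export
#' @examples
#' pc_from_dprime(1)  # ~0.7602
pc_from_dprime <- function(dprime) {
  pnorm(dprime / sqrt(2))
}

#' Sensitivity from a disparity difference and decision-variable SD
#'
#' `d' = (delta_cmp - delta_std) / sigma_t`, sign-preserving.  `sigma_t` is
#' the total SD of the decision variable for the condition; this is the
#' normalised mean used throughout the orthant likelihoods.
#'
#' @param delta_cmp comparison disparity, arcmin.
#' @param delta_std standard (pedestal) disparity, arcmin.
#' @param sigma_t total decision-variable SD, arcmin (> 0).
#' @return d-prime (unitless).
#' @export
dprime <- function(delta_cmp, delta_std, sigma_t) {
  if (any(sigma_t <= 0)) stop("sigma_t must be positive")
  (delta_cmp - delta_std) / sigma_t
}

#' Discrimination threshold from decision-variable SD
#'
#' `T = sigma_t * dprime_crit`.  With the default criterion d-prime of 1,
#' the threshold equals the decision-variable SD and the total variance of
#' the decision variable equals the squared threshold.
#'
#' @param sigma_t total decision-variable SD, arcmin.
#' @param dprime_crit criterion d-prime defining the just-noticeable
#'   difference (default 1).
#' @return threshold, arcmin.
#' @export
threshold <- function(sigma_t, dprime_crit = 1.0) {
  if (any(sigma_t <= 0)) stop("sigma_t must be positive")
  sigma_t * dprime_crit
}

# aggregate trial records of one condition into per-level counts
level_counts <- function(records) {
  u <- sort(unique(records$comparison_arcmin))
  idx <- match(records$comparison_arcmin, u)
  data.frame(comparison_arcmin = u,
             k = as.numeric(rowsum(records$chose_comparison, idx)),
             n = tabulate(idx, nbins = length(u)))
}

bernoulli_ll <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(k * log(p) + (n - k) * log1p(-p))
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit (one condition)
#'
#' Fits `P(chose comparison) = Phi((comparison - mean) / sigma)` to the
#' binary responses of a single (pedestal, bin) condition by maximising the
#' Bernoulli likelihood.  The mean may be estimated or fixed at the standard
#' disparity (`fix_mean`), matching the constraint used in the pooled
#' threshold fits.
#'
#' @param records trial records of one condition (any number of passes).
#' @param fix_mean if non-`NULL`, the psychometric mean is fixed at this
#'   value (typically the pedestal) and only `sigma` is estimated.
#' @return list with `mean`, `sigma`, `loglik`, `n`, and `flag`
#'   (`"ok"`, `"sigma_lower_bound"` or `"sigma_upper_bound"` for degenerate
#'   step-function or flat data).
#' @export
fit_psychometric <- function(records, fix_mean = NULL) {
  lev <- level_counts(records)
  if (nrow(lev) < 2) stop("need responses at >= 2 comparison levels")
  rng <- diff(range(lev$comparison_arcmin))
  lo_sig <- rng * 1e-4
  hi_sig <- rng * 1e3
  nll <- function(par) {
    mu <- if (is.null(fix_mean)) par[1] else fix_mean
    sig <- exp(par[length(par)])
    -bernoulli_ll(lev$k, lev$n, pnorm((lev$comparison_arcmin - mu) / sig))
  }
  mu0 <- if (is.null(fix_mean)) stats::weighted.mean(lev$comparison_arcmin,
                                                     lev$n) else fix_mean
  # coarse grid on log-sigma, then refine
  gs <- log(rng * c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6))
  g0 <- gs[which.min(vapply(gs, function(s)
    nll(if (is.null(fix_mean)) c(mu0, s) else s), numeric(1)))]
  par0 <- if (is.null(fix_mean)) c(mu0, g0) else g0
  fit <- if (is.null(fix_mean)) {
    optim(par0, nll, method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 500))
  } else {
    o <- optimize(function(s) nll(s), interval = log(c(lo_sig, hi_sig)),
                  tol = 1e-10)
    list(par = o$minimum, value = o$objective)
  }
  sig <- exp(fit$par[length(fit$par)])
  flag <- "ok"
  # a perfect Bernoulli fit means step-function data: sigma is driven to 0
  # and is not identified beyond "smaller than the level spacing"
  if (sig <= lo_sig * 1.01 || -fit$value > -1e-6) flag <- "sigma_lower_bound"
  if (sig >= hi_sig * 0.99) flag <- "sigma_upper_bound"
  list(mean = if (is.null(fix_mean)) fit$par[1] else fix_mean,
       sigma = sig, loglik = -fit$value, n = sum(lev$n), flag = flag)
}

#' Constrained log-linear threshold fit across pedestals
#'
#' Jointly fits all pedestals of one (experiment, contrast-bin) data set
#' under the constraint that the decision-variable SD changes log-linearly
#' with the pedestal, `sigma_t = exp(m * pedestal + b)`.  Each condition's
#' psychometric function is a cumulative Gaussian with mean fixed at its
#' pedestal and SD `exp(m * pedestal + b)`; `(m, b)` maximise the summed
#' Bernoulli log-likelihood.  Optimisation runs on unconstrained `(m, b)`
#' from a coarse multi-start grid with convergence tolerance 1e-8 on the
#' log-likelihood.
#'
#' @param records trial records of one experiment and one contrast bin, at
#'   two or more pedestals.
#' @param dprime_crit criterion d-prime defining threshold (default 1).
#' @param start optional `c(m, b)` starting point; suppresses the multi-start
#'   grid (used by bootstrap refits).
#' @param reltol optimiser convergence tolerance.
#' @return an object of class `threshold_fit` with elements `m`, `b`,
#'   `sigma_t` (named by pedestal), `thresholds`, `loglik`, `bin`,
#'   `experiment`, `dprime_crit`, `convergence`.
#' @export
fit_thresholds <- function(records, dprime_crit = 1.0, start = NULL,
                           reltol = 1e-8) {
  peds <- sort(unique(records$pedestal_arcmin))
  if (length(peds) < 2)
    stop("constrained threshold fit needs >= 2 pedestals")
  bins <- unique(records$contrast_bin)
  exps <- unique(records$experiment)
  if (length(bins) > 1 || length(exps) > 1)
    stop("fit_thresholds expects one experiment and one contrast bin; got ",
         paste(exps, collapse = "/"), " x ", paste(bins, collapse = "/"))
  levs <- lapply(peds, function(p)
    level_counts(records[records$pedestal_arcmin == p, , drop = FALSE]))
  nll <- function(par) {
    m <- par[1]; b <- par[2]
    tot <- 0
    for (i in seq_along(peds)) {
      sig <- exp(m * peds[i] + b)
      lv <- levs[[i]]
      tot <- tot - bernoulli_ll(lv$k, lv$n,
                                pnorm((lv$comparison_arcmin - peds[i]) / sig))
    }
    tot
  }
  if (is.null(start)) {
    # multi-start: slopes and intercepts bracketing plausible threshold laws
    starts <- expand.grid(m = c(-0.3, -0.15, 0, 0.15),
                          b = c(-2, -1, 0, 1))
    vals <- apply(starts, 1, nll)
    best <- NULL
    for (i in order(vals)[1:3]) {
      f <- optim(as.numeric(starts[i, ]), nll, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 1000))
      if (is.null(best) || f$value < best$value) best <- f
    }
  } else {
    best <- optim(start, nll, method = "Nelder-Mead",
                  control = list(reltol = reltol, maxit = 600))
  }
  if (best$convergence != 0)
    stop("constrained threshold fit did not converge (code ",
         best$convergence, ")")
  sig <- exp(best$par[1] * peds + best$par[2])
  structure(list(m = best$par[1], b = best$par[2],
                 sigma_t = setNames(sig, peds),
                 thresholds = setNames(sig * dprime_crit, peds),
                 loglik = -best$value,
                 bin = bins, experiment = exps,
                 dprime_crit = dprime_crit,
                 convergence = best$convergence),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Constrained log-linear threshold fit (", x$experiment, ", ",
      x$bin, " bin)\n", sep = "")
  cat(sprintf("  sigma_t = exp(%.4f * pedestal + %.4f)\n", x$m, x$b))
  cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  print(round(data.frame(pedestal = as.numeric(names(x$sigma_t)),
                         sigma_t = as.numeric(x$sigma_t),
                         threshold = as.numeric(x$thresholds)), 4),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(m = object$m, b = object$b)
}

#' @export
logLik.threshold_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' Predict decision-variable SD (or threshold) at new pedestals
#'
#' @param object a [fit_thresholds()] object.
#' @param newdata pedestals (arcmin); defaults to the fitted ones.
#' @param what `"sigma_t"` or `"threshold"`.
#' @param ... unused.
#' @export
predict.threshold_fit <- function(object, newdata = NULL,
                                  what = c("sigma_t", "threshold"), ...) {
  what <- match.arg(what)
  p <- if (is.null(newdata)) as.numeric(names(object$sigma_t)) else newdata
  s <- exp(object$m * p + object$b)
  if (what == "threshold") s <- s * object$dprime_crit
  setNames(s, p)
}
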