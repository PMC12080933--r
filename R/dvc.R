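#' Tabulate joint response patterns across passes
#'
#' Counts, per condition (pedestal x contrast bin) and comparison level, how
#' often each joint response pattern occurred across the requested passes.
#' A pass group is one (observer, experiment, pass) slice of the records;
#' groups are aligned by `trial_id` (unique trials are shared across passes
#' and, for paired designs, across experiments and observers).  Patterns are
#' indexed in the canonical order of [pattern_labels()] (binary counting,
#' `-` = 0, `+` = 1, first group most significant).
#'
#' With `pass_groups = NULL` the groups are inferred: the two passes of a
#' single experiment, or -- when both experiments are present -- the four
#' passes ordered (flattened pass 1, flattened pass 2, natural pass 1,
#' natural pass 2), the ordering assumed by [fit_quadpass()].
#'
#' @param records completed trial records (see [simulate_observer()] or
#'   [read_trials()]).
#' @param pass_groups list of group selectors, each a list with elements
#'   `experiment`, `pass_idx` and optionally `observer_id`.
#' @return an object of class `agreement_counts`: a list of conditions, each
#'   with `pedestal`, `bin`, `comparison` (levels), `delta`, and a
#'   `counts` matrix (`2^k` patterns x levels).
#' @export
tabulate_agreement <- function(records, pass_groups = NULL) {
  stopifnot(is.data.frame(records))
  if (any(is.na(records$chose_comparison)))
    stop("records contain empty responses")
  if (is.null(pass_groups)) {
    exps <- unique(records$experiment)
    if (length(exps) == 1L) {
      passes <- sort(unique(records$pass_idx))
      pass_groups <- lapply(passes, function(p)
        list(experiment = exps, pass_idx = p))
    } else if (setequal(exps, c("natural", "flattened"))) {
      pass_groups <- list(list(experiment = "flattened", pass_idx = 1L),
                          list(experiment = "flattened", pass_idx = 2L),
                          list(experiment = "natural", pass_idx = 1L),
                          list(experiment = "natural", pass_idx = 2L))
    } else stop("cannot infer pass groups; supply pass_groups")
  }
  k <- length(pass_groups)
  stopifnot(k %in% c(2L, 4L))
  sel <- lapply(pass_groups, function(g) {
    keep <- records$experiment == g$experiment & records$pass_idx == g$pass_idx
    if (!is.null(g$observer_id)) keep <- keep & records$observer_id == g$observer_id
    rows <- records[keep, , drop = FALSE]
    rows[order(rows$trial_id), , drop = FALSE]
  })
  ids <- lapply(sel, `[[`, "trial_id")
  for (i in seq_len(k)) {
    if (length(ids[[i]]) != length(ids[[1]]) || any(ids[[i]] != ids[[1]])) {
      bad <- union(setdiff(ids[[i]], ids[[1]]), setdiff(ids[[1]], ids[[i]]))
      stop("pass groups are not aligned by trial_id; mismatched ids: ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    }
    if (anyDuplicated(ids[[i]]))
      stop("a trial_id appears more than once within a pass group")
  }
  base <- sel[[1]]
  resp <- vapply(sel, `[[`, integer(nrow(base)), "chose_comparison")
  pat <- as.integer(resp %*% 2L^((k - 1L):0L))  # canonical pattern index

  conds <- unique(base[, c("pedestal_arcmin", "contrast_bin")])
  labs <- pattern_labels(k)
  out <- lapply(seq_len(nrow(conds)), function(i) {
    keep <- base$pedestal_arcmin == conds$pedestal_arcmin[i] &
      base$contrast_bin == conds$contrast_bin[i]
    cmp <- sort(unique(base$comparison_arcmin[keep]))
    counts <- vapply(cmp, function(cc) {
      tabulate(pat[keep & base$comparison_arcmin == cc] + 1L,
               nbins = 2L^k)
    }, integer(2L^k))
    dimnames(counts) <- list(labs, cmp)
    list(pedestal = conds$pedestal_arcmin[i], bin = conds$contrast_bin[i],
         comparison = cmp, delta = cmp - conds$pedestal_arcmin[i],
         counts = counts)
  })
  structure(out, n_pass = k, class = "agreement_counts")
}

#' @export
print.agreement_counts <- function(x, ...) {
  cat("Agreement counts:", length(x), "conditions,",
      attr(x, "n_pass"), "passes\n")
  for (cond in x)
    cat(sprintf("  pedestal %7.2f arcmin, %4s bin: %d levels, %d trials\n",
                cond$pedestal, cond$bin, length(cond$comparison),
                sum(cond$counts)))
  invisible(x)
}

# resolve per-condition sigma_t from a threshold_fit, a named vector keyed by
# pedestal, or a scalar
resolve_sigma <- function(sigma_t, pedestal) {
  if (inherits(sigma_t, "threshold_fit"))
    return(as.numeric(predict(sigma_t, newdata = pedestal)))
  if (length(sigma_t) == 1L && is.null(names(sigma_t)))
    return(as.numeric(sigma_t))
  i <- match(as.character(pedestal), names(sigma_t))
  if (is.na(i)) stop("no sigma_t supplied for pedestal ", pedestal)
  as.numeric(sigma_t[i])
}

RHO_EPS <- 1e-6

#' Maximum-likelihood decision-variable correlation (double pass)
#'
#' Estimates, per condition, the correlation `rho` of the decision variable
#' across the two passes from the 4-pattern agreement counts.  The
#' log-likelihood sums `N_j log L_j(rho)` over comparison levels and
#' patterns, where pattern probabilities are bivariate-normal orthants with
#' normalised means `d' = delta / sigma_t` (the level's disparity difference
#' over the condition's decision-variable SD) and zero criteria.  `rho` is
#' profiled on (-1, 1) with boundary flagging; the decision-variable SDs are
#' frozen at the values from the constrained threshold fits.
#'
#' @param counts an [tabulate_agreement()] object with 2 passes.
#' @param sigma_t a [fit_thresholds()] object, or a vector of
#'   decision-variable SDs named by pedestal, or a scalar.
#' @return an object of class `dvc_fit`: a `data.frame` with one row per
#'   condition (`pedestal`, `bin`, `rho`, `sigma_t`, `sigma_e2`, `sigma_i2`,
#'   `loglik`, `boundary`).
#' @export
fit_dvc <- function(counts, sigma_t) {
  stopifnot(inherits(counts, "agreement_counts"), attr(counts, "n_pass") == 2L)
  rows <- lapply(counts, function(cond) {
    if (sum(cond$counts) == 0) stop("empty counts for pedestal ",
                                    cond$pedestal, ", bin ", cond$bin)
    st <- resolve_sigma(sigma_t, cond$pedestal)
    dz <- cond$delta / st
    cz <- c(0, 0)
    o <- optimize(function(r) cpp_nll_double(cond$counts, dz, r, cz),
                  interval = c(-1 + RHO_EPS, 1 - RHO_EPS), tol = 1e-9)
    rho <- o$minimum
    part <- partition_double(st^2, rho)
    data.frame(pedestal = cond$pedestal, bin = cond$bin, rho = rho,
               sigma_t = st, sigma_e2 = part[["sigma_e2"]],
               sigma_i2 = part[["sigma_i2"]],
               loglik = -o$objective,
               boundary = abs(rho) > 1 - 1e-4,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dvc_fit", "data.frame")
  out
}

#' @export
print.dvc_fit <- function(x, ...) {
  cat("Decision-variable correlation (double pass)\n")
  df <- as.data.frame(x)
  df$rho <- round(df$rho, 4)
  df$sigma_t <- round(df$sigma_t, 4)
  df$sigma_e2 <- round(df$sigma_e2, 4)
  df$sigma_i2 <- round(df$sigma_i2, 4)
  df$loglik <- round(df$loglik, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dvc_fit <- function(object, ...) {
  setNames(object$rho, paste(object$pedestal, object$bin, sep = "/"))
}

#' Expected between-pass agreement
#'
#' Expected proportion of trials on which the two passes give the same
#' response, `P(++) + P(--)`, under the bivariate decision-variable model
#' with normalised mean `dprime` and correlation `rho`.  At `rho = 0` this
#' reduces to the chance curve `PC^2 + (1 - PC)^2` with `PC = Phi(dprime)`.
#'
#' @param dprime normalised mean (vectorised).
#' @param rho decision-variable correlation.
#' @return expected agreement proportion(s).
#' @export
agreement_curve <- function(dprime, rho) {
  stopifnot(abs(rho) <= 1)
  n <- length(dprime)
  rr <- rep(rho, n)
  as.numeric(cpp_bvn_cdf(dprime, dprime, rr) +
               cpp_bvn_cdf(-dprime, -dprime, rr))
}

# shared machinery: ML fit of the structured 4x4 correlation model
# (a = within-pair-1, b = within-pair-2, c = cross) for one condition
fit_quad_condition <- function(counts, delta, s1, s2, cov_zero = FALSE,
                               tie = NULL, npts = 256L, start = NULL,
                               reltol = 1e-8) {
  d1 <- delta / s1
  d2 <- delta / s2
  obj_free <- function(u) {
    r <- tanh(u)
    cpp_nll_quad(counts, d1, d2, r[1], r[2], r[3], npts)
  }
  # cov[L,B] = 0 ties the cross correlation to rho_flat * s1 / s2
  obj_tied <- function(u) {
    r <- tanh(u)
    rc <- r[1] * s1 / s2
    if (abs(rc) >= 1) return(1e8 * (1 + abs(rc)))
    cpp_nll_quad(counts, d1, d2, r[1], r[2], rc, npts)
  }
  if (cov_zero) {
    starts <- if (is.null(start)) list(c(0.3, 0.3), c(0, 0), c(0.6, 0.6))
    else list(atanh(pmin(pmax(start[1:2], -0.999), 0.999)))
    best <- NULL
    for (s0 in starts) {
      f <- optim(s0, obj_tied, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 600))
      if (is.null(best) || f$value < best$value) best <- f
    }
    r <- tanh(best$par)
    rho <- c(r[1], r[2], r[1] * s1 / s2)
  } else {
    starts <- if (is.null(start))
      list(c(0.31, 0.31, 0.2), c(0.02, 0.02, 0.01), c(0.69, 0.69, 0.45))
    else list(atanh(pmin(pmax(start, -0.999), 0.999)))
    best <- NULL
    for (s0 in starts) {
      f <- optim(s0, obj_free, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 800))
      if (is.null(best) || f$value < best$value) best <- f
    }
    rho <- tanh(best$par)
  }
  if (best$convergence != 0)
    stop("quadruple-pass fit did not converge (code ", best$convergence, ")")
  list(rho = rho, loglik = -best$value, convergence = best$convergence)
}

#' Quasi-quadruple-pass estimation of three decision-variable correlations
#'
#' Joint maximum-likelihood estimation, per condition, of the within-pair
#' correlations of the flattened and natural experiments (`rho_flat`,
#' `rho_nat`) and the cross-experiment correlation (`rho_cross`) from
#' 16-pattern agreement counts over the four passes.  The normalised mean
#' per comparison level is `(d_flat, d_flat, d_nat, d_nat)` with
#' `d = delta / sigma_t` using each experiment's constrained-threshold SD,
#' the correlation matrix is [build_quad_corr()], and criteria are zero.
#' Correlations are searched through an inverse-hyperbolic-tangent
#' reparameterisation with multi-start; parameter triples outside the
#' positive-semidefinite cone are smoothly penalised.
#'
#' With `cov_zero = TRUE` the interaction covariance between the
#' luminance-driven and depth-driven components is constrained to zero,
#' which ties `rho_cross = rho_flat * sigma_flat / sigma_nat` and leaves two
#' free parameters.
#'
#' @param counts an [tabulate_agreement()] object with 4 passes ordered
#'   (flattened 1, flattened 2, natural 1, natural 2).
#' @param sigma_flat,sigma_nat decision-variable SDs for the flattened and
#'   natural experiments ([fit_thresholds()] objects, named vectors, or
#'   scalars).
#' @param cov_zero constrain `cov[L,B] = 0`?
#' @param npts QMC points per orthant in the likelihood (default 256; the
#'   bootstrap machinery uses fewer).
#' @param start optional starting correlations (length 3).
#' @param reltol optimiser convergence tolerance.
#' @return an object of class `quadpass_fit`: a `data.frame` with one row
#'   per condition (`pedestal`, `bin`, `rho_flat`, `rho_nat`, `rho_cross`,
#'   `sigma_t_flat`, `sigma_t_nat`, `loglik`, `convergence`, `cov_zero`).
#' @export
fit_quadpass <- function(counts, sigma_flat, sigma_nat, cov_zero = FALSE,
                         npts = 256L, start = NULL, reltol = 1e-8) {
  stopifnot(inherits(counts, "agreement_counts"), attr(counts, "n_pass") == 4L)
  rows <- lapply(counts, function(cond) {
    s1 <- resolve_sigma(sigma_flat, cond$pedestal)
    s2 <- resolve_sigma(sigma_nat, cond$pedestal)
    f <- fit_quad_condition(cond$counts, cond$delta, s1, s2,
                            cov_zero = cov_zero, npts = npts, start = start,
                            reltol = reltol)
    data.frame(pedestal = cond$pedestal, bin = cond$bin,
               rho_flat = f$rho[1], rho_nat = f$rho[2], rho_cross = f$rho[3],
               sigma_t_flat = s1, sigma_t_nat = s2,
               loglik = f$loglik, convergence = f$convergence,
               cov_zero = cov_zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quadpass_fit", "data.frame")
  out
}

#' @export
print.quadpass_fit <- function(x, ...) {
  cat("Quasi-quadruple-pass decision-variable correlations",
      if (any(x$cov_zero)) "(cov[L,B] = 0 constraint)" else "", "\n")
  df <- as.data.frame(x)
  for (cl in c("rho_flat", "rho_nat", "rho_cross", "sigma_t_flat",
               "sigma_t_nat")) df[[cl]] <- round(df[[cl]], 4)
  df$loglik <- round(df$loglik, 2)
  print(df[, setdiff(names(df), c("convergence", "cov_zero"))],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.quadpass_fit <- function(object, ...) {
  as.matrix(object[, c("rho_flat", "rho_nat", "rho_cross")])
}

#' Summarise a quasi-quadruple-pass fit as variance components
#'
#' Applies [solve_components()] to every condition of a [fit_quadpass()]
#' result.
#'
#' @param object a `quadpass_fit`.
#' @param ... unused.
#' @return `data.frame` of variance components per condition.
#' @export
summary.quadpass_fit <- function(object, ...) {
  comps <- lapply(seq_len(nrow(object)), function(i)
    as.data.frame(solve_components(object$rho_flat[i], object$rho_nat[i],
                                   object$rho_cross[i],
                                   object$sigma_t_flat[i],
                                   object$sigma_t_nat[i])))
  out <- cbind(object[, c("pedestal", "bin")], do.call(rbind, comps))
  rownames(out) <- NULL
  out
}

#' Between-observer decision-variable correlations
#'
#' Maximum-likelihood estimation of within-observer correlations `rho_11`,
#' `rho_22` and the between-observer correlation `rho_12` from 16-pattern
#' counts over the four passes (observer 1 pass 1, observer 1 pass 2,
#' observer 2 pass 1, observer 2 pass 2) of one experiment, aligned by
#' trial.  The correlation matrix has the same structure as
#' [build_quad_corr()] with `(rho_11, rho_22, rho_12)`.  Also reports the
#' partial correlation `rho_12 / sqrt(rho_11 * rho_22)` -- the
#' between-observer correlation of the stimulus-driven components with
#' internal noise factored out -- clamped to [-1, 1] with a flag.
#'
#' @param counts an [tabulate_agreement()] object with 4 passes ordered as
#'   above (build with explicit `pass_groups` selecting the two observers).
#' @param sigma_1,sigma_2 decision-variable SDs for the two observers.
#' @param npts,start,reltol see [fit_quadpass()].
#' @return an object of class `between_fit`: `data.frame` with `rho_11`,
#'   `rho_22`, `rho_12`, `partial`, `partial_clamped` per condition.
#' @export
fit_between <- function(counts, sigma_1, sigma_2, npts = 256L, start = NULL,
                        reltol = 1e-8) {
  stopifnot(inherits(counts, "agreement_counts"), attr(counts, "n_pass") == 4L)
  rows <- lapply(counts, function(cond) {
    s1 <- resolve_sigma(sigma_1, cond$pedestal)
    s2 <- resolve_sigma(sigma_2, cond$pedestal)
    f <- fit_quad_condition(cond$counts, cond$delta, s1, s2, npts = npts,
                            start = start, reltol = reltol)
    r11 <- f$rho[1]; r22 <- f$rho[2]; r12 <- f$rho[3]
    part <- if (r11 > 0 && r22 > 0) r12 / sqrt(r11 * r22) else NA_real_
    clamped <- isTRUE(abs(part) > 1)
    data.frame(pedestal = cond$pedestal, bin = cond$bin,
               rho_11 = r11, rho_22 = r22, rho_12 = r12,
               partial = if (clamped) sign(part) else part,
               partial_clamped = clamped,
               sigma_t_1 = s1, sigma_t_2 = s2,
               loglik = f$loglik, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("between_fit", "data.frame")
  out
}

#' @export
print.between_fit <- function(x, ...) {
  cat("Between-observer decision-variable correlations\n")
  df <- as.data.frame(x)
  for (cl in c("rho_11", "rho_22", "rho_12", "partial"))
    df[[cl]] <- round(df[[cl]], 4)
  df$loglik <- round(df$loglik, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
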