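#' Partition decision-variable variance (double pass)
#'
#' Splits the total variance of the decision variable into its
#' externally-driven (stimulus) and internally-driven (noise) components:
#' `sigma_e2 = rho * sigma_t2`, `sigma_i2 = sigma_t2 - sigma_e2`.
#'
#' @param sigma_t2 total decision-variable variance, arcmin^2 (> 0).
#' @param rho decision-variable correlation in [-1, 1].
#' @return named vector `c(sigma_e2, sigma_i2)`.
#' @export
#' @examples
#' partition_double(4, 0.5)  # 2 and 2
partition_double <- function(sigma_t2, rho) {
  stopifnot(sigma_t2 > 0, abs(rho) <= 1)
  e <- rho * sigma_t2
  c(sigma_e2 = e, sigma_i2 = sigma_t2 - e)
}

#' Decision-variable correlation from variance components
#'
#' `rho = sigma_e2 / (sigma_e2 + sigma_i2)`: the fraction of decision
#' variance that is repeatable across passes.  Equal stimulus-driven and
#' noise-driven variances give `rho = 0.5`.
#'
#' @param sigma_e2 externally-driven variance (>= 0).
#' @param sigma_i2 internally-driven variance (>= 0, not both zero).
#' @return correlation in [0, 1].
#' @export
dvc_from_variances <- function(sigma_e2, sigma_i2) {
  stopifnot(all(sigma_e2 >= 0), all(sigma_i2 >= 0),
            all(sigma_e2 + sigma_i2 > 0))
  sigma_e2 / (sigma_e2 + sigma_i2)
}

#' Solve the quasi-quadruple-pass variance components
#'
#' Closed-form conversion of the three fitted correlations and the two
#' decision-variable SDs into the five generative components:
#' \describe{
#'   \item{luminance-driven}{`sigmaL2 = rho_flat * sigma_flat^2`}
#'   \item{interaction}{`covLB = rho_cross * sigma_flat * sigma_nat - sigmaL2`}
#'   \item{depth-driven}{`sigmaB2 = rho_nat * sigma_nat^2 - sigmaL2 - 2 covLB`}
#'   \item{internal noise}{`sigmaI2_flat = sigma_flat^2 - sigmaL2`;
#'     `sigmaI2_nat = sigma_nat^2 - sigmaE2_nat`}
#' }
#' with `sigmaE2_nat = sigmaL2 + sigmaB2 + 2 covLB`.  Components that come
#' out (slightly) negative from sampling error are reported raw and flagged,
#' never clipped; the sanctioned remedy is the `cov_zero` refit of
#' [fit_quadpass()].
#'
#' @param rho_flat,rho_nat,rho_cross fitted correlations.
#' @param sigma_flat,sigma_nat decision-variable SDs (arcmin, > 0).
#' @return named list of class `variance_components`: `sigmaL2`, `sigmaB2`,
#'   `covLB`, `sigmaI2_flat`, `sigmaI2_nat`, `sigmaE2_flat`, `sigmaE2_nat`,
#'   `sigmaT2_flat`, `sigmaT2_nat`, `negative_flags`.
#' @export
#' @examples
#' solve_components(0.4, 0.5, 0.3, 1, sqrt(2))
solve_components <- function(rho_flat, rho_nat, rho_cross, sigma_flat,
                             sigma_nat) {
  stopifnot(sigma_flat > 0, sigma_nat > 0)
  sT2f <- sigma_flat^2
  sT2n <- sigma_nat^2
  sL2 <- rho_flat * sT2f
  covLB <- rho_cross * sigma_flat * sigma_nat - sL2
  sB2 <- rho_nat * sT2n - sL2 - 2 * covLB
  sE2n <- sL2 + sB2 + 2 * covLB
  out <- list(sigmaL2 = sL2, sigmaB2 = sB2, covLB = covLB,
              sigmaI2_flat = sT2f - sL2, sigmaI2_nat = sT2n - sE2n,
              sigmaE2_flat = sL2, sigmaE2_nat = sE2n,
              sigmaT2_flat = sT2f, sigmaT2_nat = sT2n)
  neg <- c(sigmaL2 = sL2 < 0, sigmaB2 = sB2 < 0,
           sigmaI2_flat = out$sigmaI2_flat < 0,
           sigmaI2_nat = out$sigmaI2_nat < 0)
  out$negative_flags <- names(neg)[neg]
  class(out) <- c("variance_components", "list")
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (arcmin^2)\n")
  v <- unlist(x[c("sigmaL2", "sigmaB2", "covLB", "sigmaI2_flat",
                  "sigmaI2_nat", "sigmaE2_nat", "sigmaT2_flat",
                  "sigmaT2_nat")])
  print(round(v, 5))
  if (length(x$negative_flags))
    cat("  note: negative component(s):",
        paste(x$negative_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.variance_components <- function(x, ...) {
  data.frame(sigmaL2 = x$sigmaL2, sigmaB2 = x$sigmaB2, covLB = x$covLB,
             sigmaI2_flat = x$sigmaI2_flat, sigmaI2_nat = x$sigmaI2_nat,
             sigmaE2_flat = x$sigmaE2_flat, sigmaE2_nat = x$sigmaE2_nat,
             sigmaT2_flat = x$sigmaT2_flat, sigmaT2_nat = x$sigmaT2_nat,
             negative = length(x$negative_flags) > 0)
}

#' Correlations implied by variance components (inverse map)
#'
#' Forward map from the five generative components to the three
#' correlations and two total SDs; the exact inverse of
#' [solve_components()].
#'
#' @param sigmaL2,sigmaB2,covLB,sigmaI2_flat,sigmaI2_nat components
#'   (arcmin^2).
#' @return named list `rho_flat`, `rho_nat`, `rho_cross`, `sigma_flat`,
#'   `sigma_nat`.
#' @export
correlations_from_components <- function(sigmaL2, sigmaB2, covLB,
                                         sigmaI2_flat, sigmaI2_nat) {
  sT2f <- sigmaL2 + sigmaI2_flat
  sE2n <- sigmaL2 + sigmaB2 + 2 * covLB
  sT2n <- sE2n + sigmaI2_nat
  stopifnot(sT2f > 0, sT2n > 0)
  list(rho_flat = sigmaL2 / sT2f,
       rho_nat = sE2n / sT2n,
       rho_cross = (sigmaL2 + covLB) / sqrt(sT2f * sT2n),
       sigma_flat = sqrt(sT2f), sigma_nat = sqrt(sT2n))
}

#' Between-observer partial correlation
#'
#' `rho_12 / sqrt(rho_11 * rho_22)`: the between-observer correlation of the
#' stimulus-driven components after factoring out each observer's internal
#' noise.  Values outside [-1, 1] (possible from sampling error) are
#' reported with a `clamped` attribute when `clamp = TRUE`.
#'
#' @param rho12 between-observer decision-variable correlation.
#' @param rho11,rho22 within-observer decision-variable correlations (> 0).
#' @param clamp clamp the result to [-1, 1]?
#' @return partial correlation.
#' @export
#' @examples
#' partial_correlation(0.4, 0.5, 0.8)  # 0.63246
partial_correlation <- function(rho12, rho11, rho22, clamp = TRUE) {
  if (any(rho11 <= 0) || any(rho22 <= 0))
    stop("within-observer correlations must be positive")
  p <- rho12 / sqrt(rho11 * rho22)
  if (clamp && any(abs(p) > 1)) {
    out <- pmin(pmax(p, -1), 1)
    attr(out, "clamped") <- abs(p) > 1
    return(out)
  }
  p
}
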