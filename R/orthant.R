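#' Canonical response-pattern labels
#'
#' Response patterns over `n_pass` passes are ordered by binary counting with
#' `-` (comparison not chosen) as 0 and `+` (comparison chosen) as 1, pass 1
#' most significant.  For two passes the order is `--`, `-+`, `+-`, `++`.
#' This order is frozen: every counts matrix and probability vector in the
#' package uses it.
#'
#' @param n_pass number of passes (2 or 4).
#' @return character vector of length `2^n_pass`.
#' @export
#' @examples
#' pattern_labels(2)
pattern_labels <- function(n_pass) {
  stopifnot(n_pass >= 1, n_pass <= 4)
  n <- 2L^n_pass
  vapply(seq_len(n) - 1L, function(i) {
    bits <- as.integer(intToBits(i))[n_pass:1]
    paste(ifelse(bits == 1L, "+", "-"), collapse = "")
  }, character(1))
}

#' Orthant probability of a 2-D or 4-D normal distribution
#'
#' Probability that each coordinate of a multivariate normal falls above
#' (`+`) or below (`-`) its criterion.  Dimension 2 uses a deterministic
#' Gauss-Legendre evaluation of the bivariate normal CDF (absolute accuracy
#' better than 1e-10).  Dimensions 3 and 4 use sequential quasi-Monte-Carlo
#' integration on a fixed Kronecker point set, with randomised shifts and
#' sample-size doubling until the estimated error is below `tol`.
#'
#' @param mean numeric mean vector (normalised units, i.e. d-prime scale).
#' @param corr correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite).
#' @param pattern sign pattern: a string such as `"++"` or `"+-+-"`, or a
#'   numeric vector of +1/-1.
#' @param criteria per-coordinate criteria (normalised); default all zero.
#' @param tol requested absolute accuracy for dimensions 3-4 (default 1e-5;
#'   dimension 2 is accurate to ~1e-10 regardless).
#' @param seed integer seed controlling the randomised shifts of the QMC rule
#'   (results are deterministic given `seed`).
#' @return probability, with attribute `"se"` (error estimate, `NA` in 2-D).
#' @export
#' @examples
#' orthant_prob(c(0, 0), diag(2), "++")                      # 0.25
#' orthant_prob(c(0, 0), matrix(c(1, .5, .5, 1), 2), "++")   # 1/4 + asin(.5)/(2*pi)
orthant_prob <- function(mean, corr, pattern, criteria = NULL, tol = 1e-5,
                         seed = 1L) {
  signs <- parse_pattern(pattern, length(mean))
  dim <- length(mean)
  stopifnot(dim %in% 2:4, nrow(corr) == dim, ncol(corr) == dim)
  check_corr(corr)
  if (is.null(criteria)) criteria <- rep(0, dim)
  stopifnot(length(criteria) == dim)
  if (dim == 2L) {
    out <- cpp_orthant(as.numeric(mean), corr, as.integer(signs),
                       as.numeric(criteria), 0L, 1L, 0.5)
    p <- out$value
    attr(p, "se") <- NA_real_
    return(p)
  }
  npts <- 512L
  nshift <- 10L
  repeat {
    shifts <- make_shifts(seed, nshift * (dim - 1L))
    out <- cpp_orthant(as.numeric(mean), corr, as.integer(signs),
                       as.numeric(criteria), npts, nshift, shifts)
    if (3.5 * out$se < tol || npts >= 65536L) break
    npts <- npts * 2L
  }
  p <- out$value
  attr(p, "se") <- out$se
  p
}

#' Probabilities of all response patterns
#'
#' Probability of every sign pattern (4 in 2-D, 16 in 4-D) in the canonical
#' order of [pattern_labels()].  Probabilities sum to 1 within the quadrature
#' tolerance.
#'
#' @inheritParams orthant_prob
#' @return named numeric vector over all `2^dim` patterns.
#' @export
pattern_probs <- function(mean, corr, criteria = NULL, tol = 1e-5, seed = 1L) {
  dim <- length(mean)
  labs <- pattern_labels(dim)
  p <- vapply(labs, function(l) {
    as.numeric(orthant_prob(mean, corr, l, criteria = criteria, tol = tol,
                            seed = seed))
  }, numeric(1))
  names(p) <- labs
  p
}

#' Structured 4x4 correlation matrix for quadruple-pass analyses
#'
#' Builds the correlation matrix of the normalised decision variable over the
#' four passes (pair 1: passes 1-2; pair 2: passes 3-4): within-pair
#' correlations `rho_flat` and `rho_nat` on the two diagonal blocks and the
#' cross-pair correlation `rho_cross` everywhere else.  For the
#' between-observer variant the same structure applies with
#' (rho_11, rho_22, rho_12).
#'
#' @param rho_flat within-pair correlation for the first pass-pair.
#' @param rho_nat within-pair correlation for the second pass-pair.
#' @param rho_cross cross-pair correlation.
#' @return 4x4 correlation matrix, verified positive semidefinite.
#' @export
#' @examples
#' build_quad_corr(0.5, 2/3, 1/sqrt(6))
build_quad_corr <- function(rho_flat, rho_nat, rho_cross) {
  for (r in c(rho_flat, rho_nat, rho_cross)) {
    if (!is.finite(r) || abs(r) > 1)
      stop("correlations must lie in [-1, 1]")
  }
  if (4 * rho_cross^2 > (1 + rho_flat) * (1 + rho_nat) + 1e-12) {
    stop(sprintf(paste0("correlation triple is not positive semidefinite: ",
                        "requires 4*rho_cross^2 <= (1+rho_flat)*(1+rho_nat) ",
                        "but %.4f > %.4f"),
                 4 * rho_cross^2, (1 + rho_flat) * (1 + rho_nat)))
  }
  m <- matrix(rho_cross, 4, 4)
  m[1, 2] <- m[2, 1] <- rho_flat
  m[3, 4] <- m[4, 3] <- rho_nat
  diag(m) <- 1
  m
}

# --- internal helpers -------------------------------------------------------

parse_pattern <- function(pattern, dim) {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1L, nchar(pattern) == dim)
    ch <- strsplit(pattern, "")[[1]]
    if (!all(ch %in% c("+", "-"))) stop("pattern must contain only + and -")
    return(ifelse(ch == "+", 1L, -1L))
  }
  stopifnot(length(pattern) == dim, all(pattern %in% c(-1, 1)))
  as.integer(pattern)
}

check_corr <- function(corr) {
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation matrix diagonal != 1")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semidefinite")
  if (min(ev) < 1e-10)
    warning("correlation matrix is near-singular; results may be inaccurate")
  invisible(TRUE)
}

make_shifts <- function(seed, n) {
  # deterministic low-discrepancy-ish shifts from a small LCG, independent of
  # R's global RNG state
  s <- as.double((as.integer(seed) %% 2147483647L))
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- s / 2147483647
  }
  out
}
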