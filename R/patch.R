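#' Stereo image patch
#'
#' Container for a range-registered stereo patch: left/right luminance
#' half-images (arbitrary units), a per-pixel vergence-demand map (arcmin),
#' the vergence demand of the central corresponding point `v0`, a
#' raised-cosine (Hann) window, and a half-occlusion validity mask.  The
#' patch convention is 32 px per degree of visual angle.
#'
#' @param left_img,right_img luminance matrices (same shape).
#' @param vergence_map per-pixel vergence demand, arcmin.
#' @param v0 vergence demand of the central corresponding point, arcmin;
#'   defaults to the map value at the centre pixel.
#' @param window weight matrix (>= 0); defaults to a separable Hann window
#'   ([hann_window()]).
#' @param halfocc_mask logical matrix, `TRUE` where the pixel is
#'   half-occluded (excluded from disparity statistics); default none.
#' @param px_per_deg pixels per degree (default 32).
#' @return object of class `stereo_patch`.
#' @export
stereo_patch <- function(left_img, right_img, vergence_map, v0 = NULL,
                         window = NULL, halfocc_mask = NULL,
                         px_per_deg = 32) {
  dm <- dim(left_img)
  if (!identical(dim(right_img), dm) || !identical(dim(vergence_map), dm))
    stop("all patch matrices must have the same shape")
  if (is.null(window)) window <- hann_window(dm[1], dm[2])
  if (!identical(dim(window), dm)) stop("window shape mismatch")
  if (any(window < 0)) stop("window weights must be non-negative")
  if (is.null(halfocc_mask)) halfocc_mask <- matrix(FALSE, dm[1], dm[2])
  if (!identical(dim(halfocc_mask), dm)) stop("mask shape mismatch")
  ctr <- centre_px(dm)
  if (is.null(v0)) v0 <- vergence_map[ctr[1], ctr[2]]
  structure(list(left_img = left_img, right_img = right_img,
                 vergence_map = vergence_map, v0 = v0, window = window,
                 halfocc_mask = halfocc_mask, px_per_deg = px_per_deg),
            class = "stereo_patch")
}

#' @export
print.stereo_patch <- function(x, ...) {
  dm <- dim(x$left_img)
  cat(sprintf("stereo_patch %dx%d px (%.2f deg), v0 = %.3f arcmin\n",
              dm[1], dm[2], dm[1] / x$px_per_deg, x$v0))
  cat(sprintf("  disparity-contrast %.4f arcmin, RMS contrast %.4f, %d half-occluded px\n",
              disparity_contrast(x), tryCatch(rms_contrast(x),
                                              error = function(e) NA),
              sum(x$halfocc_mask)))
  invisible(x)
}

centre_px <- function(dm) c(floor(dm[1] / 2) + 1L, floor(dm[2] / 2) + 1L)

#' Separable 2-D Hann (raised-cosine) window
#'
#' `w(i, j) = hann(i) * hann(j)` with the 1-D profile
#' `0.5 * (1 - cos(2 pi (k - 1) / (n - 1)))`, peaking at the patch centre.
#'
#' @param nr,nc window size in pixels.
#' @return `nr` x `nc` weight matrix in [0, 1].
#' @export
hann_window <- function(nr, nc = nr) {
  h <- function(n) if (n == 1) 1 else 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  outer(h(nr), h(nc))
}

#' Radial 2-D Hann window
#'
#' Alternative raised-cosine convention: `0.5 (1 + cos(pi r / R))` of the
#' radial distance from the centre pixel, zero outside radius `R`.
#'
#' @param nr,nc window size in pixels.
#' @return weight matrix.
#' @export
hann_window_radial <- function(nr, nc = nr) {
  ctr <- centre_px(c(nr, nc))
  r <- sqrt(outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, `+`))
  R <- min(nr, nc) / 2
  w <- 0.5 * (1 + cos(pi * pmin(r / R, 1)))
  w
}

#' Disparity-contrast of a stereo patch
#'
#' Windowed root-mean-square deviation of the vergence-demand map from the
#' central corresponding point's demand:
#' `sqrt( sum w (v - v0)^2 / sum w )`, in arcmin.  Half-occluded pixels are
#' excluded and the window renormalised over the remaining pixels.  The
#' difference `v - v0` is the relative disparity between the centre pixel
#' and the rest of the patch.
#'
#' @param patch a [stereo_patch()].
#' @param region `"whole"` or `"central"`; the latter restricts to a central
#'   disc of diameter `central_diam_px`.
#' @param central_diam_px diameter of the central region, px.
#' @return disparity-contrast, arcmin.
#' @export
disparity_contrast <- function(patch, region = c("whole", "central"),
                               central_diam_px = 4) {
  region <- match.arg(region)
  stopifnot(inherits(patch, "stereo_patch"))
  keep <- !patch$halfocc_mask
  if (region == "central") keep <- keep & central_disc(patch, central_diam_px)
  w <- patch$window * keep
  sw <- sum(w)
  if (sw <= 0)
    stop("disparity-contrast undefined: no unmasked pixels with positive weight")
  sqrt(sum(w * (patch$vergence_map - patch$v0)^2) / sw)
}

central_disc <- function(patch, diam_px) {
  dm <- dim(patch$vergence_map)
  ctr <- centre_px(dm)
  r2 <- outer((seq_len(dm[1]) - ctr[1])^2, (seq_len(dm[2]) - ctr[2])^2, `+`)
  r2 <= (diam_px / 2)^2
}

# per-eye Weber-contrast images, normalised by the windowed mean luminance
weber_contrast <- function(img, window) {
  mu <- sum(img * window) / sum(window)
  if (mu <= 0) stop("mean luminance must be positive")
  list(c = (img - mu) / mu, mean = mu)
}

#' Binocular RMS contrast of a stereo patch
#'
#' `sqrt( sum w (cL^2 + cR^2) / sum w )` where `cL`, `cR` are the per-eye
#' Weber-contrast images `(I - mean) / mean` (windowed means).
#'
#' @param patch a [stereo_patch()].
#' @return RMS contrast (unitless).
#' @export
rms_contrast <- function(patch) {
  stopifnot(inherits(patch, "stereo_patch"))
  w <- patch$window
  cl <- weber_contrast(patch$left_img, w)$c
  cr <- weber_contrast(patch$right_img, w)$c
  sqrt(sum((cl^2 + cr^2) * w) / sum(w))
}

#' Fix the RMS contrast of a patch
#'
#' Scales both eyes' Weber-contrast images by one common factor so that
#' [rms_contrast()] equals `target` exactly (the statistic is linear in a
#' common contrast scale), then reconstructs luminance about the same means.
#'
#' @param patch a [stereo_patch()].
#' @param target desired RMS contrast (> 0); the conventional value for
#'   natural-stimulus work is 0.3, the median of natural patches.
#' @return a new `stereo_patch`.
#' @export
fix_contrast <- function(patch, target = 0.3) {
  cur <- rms_contrast(patch)
  if (cur <= 0) stop("cannot fix the contrast of a zero-contrast patch")
  s <- target / cur
  w <- patch$window
  l <- weber_contrast(patch$left_img, w)
  r <- weber_contrast(patch$right_img, w)
  out <- patch
  out$left_img <- l$mean * (1 + s * l$c)
  out$right_img <- r$mean * (1 + s * r$c)
  out
}

#' Flatten a stereo patch
#'
#' Replaces one half-image by a duplicate of the other, so the stimulus
#' specifies a fronto-parallel plane: the vergence-demand map becomes
#' constant at `v0` and the disparity-contrast is exactly zero.  Luminance
#' structure is preserved (up to the choice of eye).
#'
#' @param patch a [stereo_patch()].
#' @param keep_eye which half-image to duplicate: `"left"`, `"right"`, or
#'   `"random"` (seeded).
#' @param seed seed for `keep_eye = "random"`.
#' @return flattened `stereo_patch`.
#' @export
flatten <- function(patch, keep_eye = c("random", "left", "right"),
                    seed = 1L) {
  keep_eye <- match.arg(keep_eye)
  stopifnot(inherits(patch, "stereo_patch"))
  if (keep_eye == "random") {
    set.seed(derive_seed(seed, 77L))
    keep_eye <- sample(c("left", "right"), 1L)
  }
  out <- patch
  img <- if (keep_eye == "left") patch$left_img else patch$right_img
  out$left_img <- img
  out$right_img <- img
  out$vergence_map <- matrix(patch$v0, nrow(img), ncol(img))
  out$halfocc_mask <- matrix(FALSE, nrow(img), ncol(img))
  out
}

#' Vet a stereo patch for inclusion in a stimulus set
#'
#' A patch is accepted when its central region (default 4 px diameter,
#' 1/8 deg) is a coherent depth target: central disparity-contrast at most
#' `central_tol_arcsec` (default 20 arcsec) and no half-occluded pixels in
#' the central region.  Half-occlusions outside the centre are allowed (and
#' excluded from the disparity statistics).  The whole-patch
#' disparity-contrast assigns the patch to a named bin, or `"none"` when it
#' falls outside every bin.
#'
#' @param patch a [stereo_patch()].
#' @param central_diam_px diameter of the central region, px.
#' @param central_tol_arcsec maximum central disparity-contrast, arcsec.
#' @param bins named list of `c(lo, hi)` disparity-contrast ranges in
#'   arcmin; defaults to the study's low (0.025-0.117) and high
#'   (0.393-1.375) ranges.
#' @return object of class `vetting_report`: list with `accepted`,
#'   `reasons`, `central_dc_arcsec`, `whole_dc_arcmin`, `bin`.
#' @export
vet_patch <- function(patch, central_diam_px = 4, central_tol_arcsec = 20,
                      bins = list(low = c(0.025, 0.117),
                                  high = c(0.393, 1.375))) {
  stopifnot(inherits(patch, "stereo_patch"))
  dm <- dim(patch$vergence_map)
  if (central_diam_px > min(dm))
    stop("central region larger than the patch")
  reasons <- character(0)
  central <- central_disc(patch, central_diam_px)
  if (any(patch$halfocc_mask & central))
    reasons <- c(reasons, "half-occluded pixels in the central region")
  cdc_arcsec <- tryCatch(
    60 * disparity_contrast(patch, region = "central",
                            central_diam_px = central_diam_px),
    error = function(e) NA_real_)
  if (is.na(cdc_arcsec)) {
    # centre fully masked: already rejected above; treat as unmeasurable
    cdc_arcsec <- Inf
  } else if (cdc_arcsec > central_tol_arcsec) {
    reasons <- c(reasons,
                 sprintf("central disparity-contrast %.1f arcsec > %.1f",
                         cdc_arcsec, central_tol_arcsec))
  }
  wdc <- disparity_contrast(patch)
  bin <- "none"
  for (nm in names(bins))
    if (wdc >= bins[[nm]][1] && wdc <= bins[[nm]][2]) bin <- nm
  structure(list(accepted = length(reasons) == 0, reasons = reasons,
                 central_dc_arcsec = cdc_arcsec, whole_dc_arcmin = wdc,
                 bin = bin),
            class = "vetting_report")
}

#' @export
print.vetting_report <- function(x, ...) {
  cat("Patch vetting:", if (x$accepted) "ACCEPTED" else "REJECTED", "\n")
  cat(sprintf("  central disparity-contrast: %.2f arcsec\n",
              x$central_dc_arcsec))
  cat(sprintf("  whole-patch disparity-contrast: %.4f arcmin (bin: %s)\n",
              x$whole_dc_arcmin, x$bin))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

# smooth pseudo-random field: white noise blurred by a separable box filter
smooth_noise <- function(n, passes = 3) {
  z <- matrix(rnorm(n * n), n, n)
  for (i in seq_len(passes)) {
    z <- (z + cbind(z[, -1], z[, 1]) + cbind(z[, n], z[, -n]) +
            rbind(z[-1, ], z[1, ]) + rbind(z[n, ], z[-n, ])) / 5
  }
  z
}

#' Generate a synthetic range-registered stereo patch
#'
#' Builds a stereo patch whose luminance half-images are smoothed noise with
#' non-zero contrast and whose vergence-demand map is constant at the
#' pedestal demand over the central region and perturbed in the surround so
#' that the whole-patch disparity-contrast hits `disparity_contrast_target`
#' to within 1e-6 arcmin (the statistic is linear in the perturbation scale,
#' so the scale is solved analytically).  Optionally marks a fraction of the
#' pixels outside the central region as half-occluded.
#'
#' This generator is a synthetic stand-in for sampling patches from a
#' natural stereo-image database; it emulates the geometry the stimulus
#' statistics operate on, not natural image content.
#'
#' @param seed integer seed.
#' @param size_px patch size in pixels (>= 8).
#' @param disparity_contrast_target whole-patch disparity-contrast, arcmin
#'   (>= 0).
#' @param pedestal central vergence demand (pedestal disparity), arcmin.
#' @param halfocc_fraction fraction of surround pixels marked half-occluded.
#' @param central_diam_px diameter of the flat central region, px.
#' @param rms_target if non-`NULL`, luminance contrast is fixed to this RMS
#'   contrast.
#' @return a [stereo_patch()].
#' @export
#' @examples
#' p <- synth_patch(1, disparity_contrast_target = 0.75, pedestal = -7.5)
#' disparity_contrast(p)  # 0.75
synth_patch <- function(seed = 1L, size_px = 32L,
                        disparity_contrast_target = 0.5, pedestal = -7.5,
                        halfocc_fraction = 0, central_diam_px = 4,
                        rms_target = 0.3) {
  stopifnot(size_px >= 8, disparity_contrast_target >= 0,
            halfocc_fraction >= 0, halfocc_fraction < 1)
  set.seed(derive_seed(seed, 303L))
  n <- as.integer(size_px)
  lum_l <- 100 + 25 * smooth_noise(n, passes = 2)
  lum_r <- lum_l + 2 * smooth_noise(n, passes = 2)  # small uncorrelated part
  lum_l <- pmax(lum_l, 1)
  lum_r <- pmax(lum_r, 1)

  vmap <- matrix(pedestal, n, n)
  window <- hann_window(n)
  p0 <- stereo_patch(lum_l, lum_r, vmap, window = window)
  central <- central_disc(p0, central_diam_px)
  mask <- matrix(FALSE, n, n)
  if (halfocc_fraction > 0) {
    surround <- which(!central)
    k <- round(halfocc_fraction * length(surround))
    if (k > 0) mask[surround[sample.int(length(surround), k)]] <- TRUE
  }
  if (disparity_contrast_target > 0) {
    pert <- smooth_noise(n, passes = 2)
    pert[central] <- 0
    w <- window * (!mask)
    base <- sqrt(sum(w * pert^2) / sum(w))
    if (base <= 0)
      stop("cannot reach the requested disparity-contrast with this smoothness")
    vmap <- pedestal + pert * (disparity_contrast_target / base)
  }
  p <- stereo_patch(lum_l, lum_r, vmap, v0 = pedestal, window = window,
                    halfocc_mask = mask)
  if (!is.null(rms_target)) p <- fix_contrast(p, rms_target)
  p
}

#' Write / read a stereo patch on disk
#'
#' A patch is stored as two TIFF half-images (`<base>_L.tif`,
#' `<base>_R.tif`, 32-bit float, luminance scaled to [0,1] by a factor
#' recorded in the metadata) plus a CSV vergence-demand matrix
#' (`<base>_vergence.csv`) and a small JSON metadata file (`<base>.json`:
#' `v0`, `px_per_deg`, luminance scale, mask indices).
#'
#' @param patch a [stereo_patch()].
#' @param base path prefix (no extension).
#' @return `write_patch` returns `base` invisibly; `read_patch` returns the
#'   reconstructed `stereo_patch`.
#' @export
write_patch <- function(patch, base) {
  stopifnot(inherits(patch, "stereo_patch"))
  sc <- max(patch$left_img, patch$right_img, 1e-12)
  tiff::writeTIFF(patch$left_img / sc, paste0(base, "_L.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(patch$right_img / sc, paste0(base, "_R.tif"),
                  bits.per.sample = 32L)
  write.table(patch$vergence_map, paste0(base, "_vergence.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(v0 = patch$v0, px_per_deg = patch$px_per_deg,
               lum_scale = sc, mask_idx = which(patch$halfocc_mask))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_patch
#' @export
read_patch <- function(base) {
  l <- tiff::readTIFF(paste0(base, "_L.tif"))
  r <- tiff::readTIFF(paste0(base, "_R.tif"))
  v <- as.matrix(read.csv(paste0(base, "_vergence.csv"), header = FALSE))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  mask <- matrix(FALSE, nrow(v), ncol(v))
  if (length(meta$mask_idx)) mask[meta$mask_idx] <- TRUE
  stereo_patch(l * meta$lum_scale, r * meta$lum_scale, v, v0 = meta$v0,
               halfocc_mask = mask, px_per_deg = meta$px_per_deg)
}
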