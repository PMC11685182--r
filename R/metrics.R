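# Reference-based evaluation metrics: segmentation overlap, region
# volumes and agreement, grey/white intensity differentiation, and
# image-quality indices.

#' Dice overlap of one region between two label maps
#'
#' `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty and 0
#' when exactly one is.
#'
#' @param a,b `mosr_label_map`s (or logical arrays) on the same grid.
#' @param region region id, name, or one of the global tissue classes
#'   `"CSF"`, `"GMC"`, `"WM"`, `"GMS"`. Ignored when `a` and `b` are
#'   already binary masks.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, region = NULL) {
  ma <- if (inherits(a, "mosr_label_map")) region_mask(a, region) else as.array(a) > 0
  mb <- if (inherits(b, "mosr_label_map")) region_mask(b, region) else as.array(b) > 0
  if (!all(dim(ma) == dim(mb))) stop_mosr("grid mismatch between label maps")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' Region volumes in cubic centimetres
#'
#' Voxel count times voxel volume for every region in the label map's
#' region table, plus the four global tissue classes.
#'
#' @param lm an `mosr_label_map`.
#' @return data.frame with columns `region` and `volume_cm3`.
#' @export
region_volumes <- function(lm) {
  vox_cm3 <- prod(lm$spacing) / 1000
  rt <- lm$region_table
  counts <- tabulate(lm$labels + 1L, nbins = max(rt$id) + 1L)
  per_region <- counts[rt$id + 1L] * vox_cm3
  globals <- setdiff(GLOBAL_TISSUES, rt$name)   # aggregate classes only
  global <- vapply(globals, function(g) sum(region_mask(lm, g)) * vox_cm3,
                   numeric(1))
  rbind(data.frame(region = rt$name, volume_cm3 = per_region,
                   stringsAsFactors = FALSE),
        data.frame(region = globals, volume_cm3 = unname(global),
                   stringsAsFactors = FALSE))
}

#' Agreement between two volume series
#'
#' Pearson's r, Lin's concordance correlation coefficient (population
#' moments: `CCC = 2 cov / (var_x + var_y + (mean_x - mean_y)^2)`), the
#' mean difference `mean(x - y)`, and Bland-Altman limits of agreement.
#'
#' @param x,y numeric vectors of equal length >= 3 (e.g. predicted and
#'   reference volumes across subjects).
#' @param moments `"population"` (1/n, the original estimator) or
#'   `"sample"` (1/(n-1)).
#' @return list `(r, ccc, mean_diff, ba_lower, ba_upper, n)`; `r` and
#'   `ccc` are NA (with a warning) when either series is constant.
#' @export
concordance <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop_mosr("need at least 3 paired values")
  mx <- mean(x); my <- mean(y)
  denom_n <- if (moments == "population") n else n - 1L
  vx <- sum((x - mx)^2) / denom_n
  vy <- sum((y - my)^2) / denom_n
  sxy <- sum((x - mx) * (y - my)) / denom_n
  d <- x - y
  if (vx < .Machine$double.eps || vy < .Machine$double.eps) {
    warning("zero variance: correlation undefined")
    r <- ccc <- NA_real_
  } else {
    r <- sxy / sqrt(vx * vy)
    ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  }
  list(r = r, ccc = ccc, mean_diff = mean(d),
       ba_lower = mean(d) - 1.96 * sd(d), ba_upper = mean(d) + 1.96 * sd(d),
       n = n)
}

#' Grey/white-matter intensity differentiation
#'
#' Absolute difference in median voxel intensity between the grey- and
#' white-matter masks (masks taken from the reference segmentation and
#' applied to any image), optionally expressed as a percentage change
#' against a reference image's differentiation: `(X - ref)/ref * 100`.
#'
#' @param img `mosr_volume` or 3D array.
#' @param gm_mask,wm_mask logical arrays on `img`'s grid (nonempty).
#' @param reference_diff optional reference `abs_diff` for the percentage.
#' @return list `(abs_diff, pct_vs_reference)`.
#' @export
gm_wm_differentiation <- function(img, gm_mask, wm_mask, reference_diff = NULL) {
  dat <- vol_data(img)
  if (!any(gm_mask) || !any(wm_mask)) stop_mosr("empty tissue mask")
  ad <- abs(median(dat[gm_mask]) - median(dat[wm_mask]))
  pct <- if (!is.null(reference_diff)) (ad - reference_diff) / reference_diff * 100
  list(abs_diff = ad, pct_vs_reference = pct)
}

#' Reference image-quality metrics
#'
#' NMSE (normalized by reference energy `sum(ref^2)`), PSNR
#' (`10 log10(range(ref)^2 / MSE)`, `Inf` for identical images) and a
#' volumetric SSIM (Gaussian window, standard constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L = range(ref)`).
#'
#' @param pred,ref volumes or 3D arrays on the same grid; `ref` must not
#'   be all zero.
#' @param ssim_sigma Gaussian window sigma in voxels.
#' @return list `(nmse, psnr, ssim)`.
#' @export
image_quality <- function(pred, ref, ssim_sigma = 1.5) {
  p <- vol_data(pred); r <- vol_data(ref)
  if (!all(dim(p) == dim(r))) stop_mosr("grid mismatch between pred and ref")
  energy <- sum(r^2)
  if (energy == 0) stop_mosr("reference volume is identically zero")
  mse <- mean((r - p)^2)
  nmse <- sum((r - p)^2) / energy
  L <- diff(range(r))
  psnr <- if (mse == 0) Inf else 10 * log10(L^2 / mse)
  ssim <- ssim3d(p, r, L = L, sigma = ssim_sigma)
  list(nmse = nmse, psnr = psnr, ssim = ssim)
}

# Volumetric SSIM with a Gaussian weighting window (one scalar per pair).
ssim3d <- function(p, r, L, sigma = 1.5) {
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  d <- dim(p); sg <- rep(sigma, 3L)
  blur <- function(v) cpp_gauss_blur3d(v, d, sg)
  mu_p <- blur(p); mu_r <- blur(r)
  var_p <- pmax(blur(p * p) - mu_p^2, 0)
  var_r <- pmax(blur(r * r) - mu_r^2, 0)
  cov_pr <- blur(p * r) - mu_p * mu_r
  num <- (2 * mu_p * mu_r + C1) * (2 * cov_pr + C2)
  den <- (mu_p^2 + mu_r^2 + C1) * (var_p + var_r + C2)
  mean(num / den)
}
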