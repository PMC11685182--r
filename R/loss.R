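# Composite training objective: mean voxel-wise squared error weighted by
# lambda, plus the slice-sampled perceptual term. The L2 term is a *mean*
# (not a sum) over voxels so that the lambda = 100 weighting transfers
# across cube sizes.

#' Voxel-wise L2 loss
#'
#' Mean of squared voxel-wise differences between prediction and target.
#'
#' @param pred,target volumes or 3D arrays on the same grid.
#' @return scalar `>= 0`.
#' @export
l2_loss <- function(pred, target) {
  p <- vol_data(pred); t <- vol_data(target)
  if (!all(dim(p) == dim(t))) stop_mosr("grid mismatch between pred and target")
  mean((p - t)^2)
}

#' Composite training loss
#'
#' `total = lpips_volume(pred, target) + lambda_l2 * l2_loss(pred, target)`.
#'
#' @param pred,target volumes or 3D arrays on the same grid.
#' @param cfg a [loss_config()].
#' @param fx a [feature_extractor()].
#' @param seed slice-sampling seed.
#' @return list with `total` and its two addends `lpips` and `l2`
#'   (the raw unweighted mean squared error).
#' @export
total_loss <- function(pred, target, cfg, fx, seed = cfg$seed) {
  lp <- lpips_volume(pred, target, cfg, fx, seed = seed)
  l2 <- l2_loss(pred, target)
  list(total = lp + cfg$lambda_l2 * l2, lpips = lp, l2 = l2)
}

#' Composite loss with gradient
#'
#' Same value as [total_loss()] plus the analytic gradient with respect
#' to the prediction, used by the training loop.
#'
#' @inheritParams total_loss
#' @return list `(total, lpips, l2, dx)`; `dx` matches the prediction
#'   array.
#' @export
total_loss_grad <- function(pred, target, cfg, fx, seed = cfg$seed) {
  p <- vol_data(pred); t <- vol_data(target)
  lp <- lpips_volume(p, t, cfg, fx, seed = seed, grad = TRUE)
  l2 <- mean((p - t)^2)
  dx <- lp$dx + cfg$lambda_l2 * 2 * (p - t) / length(p)
  list(total = lp$value + cfg$lambda_l2 * l2, lpips = lp$value, l2 = l2,
       dx = dx)
}
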