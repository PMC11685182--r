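# Learned-perceptual-similarity machinery. The distance between two 2D
# slices is computed from the activations of the first `feature_layers`
# stages of a frozen 2D convolutional backbone: at each stage the feature
# maps are unit-normalized across channels at every spatial position,
# scaled by per-channel weights, differenced, squared-summed over
# channels, averaged spatially, and summed over stages.
#
# The published pretrained backbone (an AlexNet classifier with fitted
# channel weights) cannot be bundled; the package ships a seeded
# random-weight extractor with uniform channel weights, which preserves
# every structural property of the distance (zero at identity, symmetry,
# positivity, sensitivity to perturbations) and is what all tests use.

#' Loss configuration
#'
#' @param lambda_l2 weight of the voxel-wise L2 term (default 100).
#' @param n_slices number of paired slices sampled per loss evaluation
#'   (default 6).
#' @param feature_layers number of backbone stages used (default 5).
#' @param slice_axes_policy `"balanced"` (slices split evenly over the
#'   three anatomical axes; 2 per axis at the default 6) or `"uniform"`
#'   (axis drawn uniformly per slice).
#' @param axes axes eligible for slice sampling (subset of 1:3).
#' @param central_frac slices are drawn from this central fraction of
#'   each axis, avoiding empty background slices.
#' @param seed default seed for slice sampling.
#' @return list of class `mosr_loss_config`.
#' @export
loss_config <- function(lambda_l2 = 100, n_slices = 6L, feature_layers = 5L,
                        slice_axes_policy = c("balanced", "uniform"),
                        axes = 1:3, central_frac = 0.8, seed = 1L) {
  if (lambda_l2 <= 0 || n_slices < 1L || feature_layers < 1L)
    stop_mosr("invalid loss configuration")
  structure(list(lambda_l2 = lambda_l2, n_slices = as.integer(n_slices),
                 feature_layers = as.integer(feature_layers),
                 slice_axes_policy = match.arg(slice_axes_policy),
                 axes = as.integer(axes), central_frac = central_frac,
                 seed = seed),
            class = "mosr_loss_config")
}

#' Build a frozen 2D feature extractor
#'
#' A stack of strided 3x3 convolution + ReLU stages whose (post-ReLU)
#' activations are the perceptual features. Grayscale slices are
#' replicated to the 3 input channels and mapped to `[-1, 1]`. Weights
#' are drawn once under `seed` and never updated ("frozen" contract);
#' channel weights `w_l` are uniform 1.
#'
#' @param n_layers number of stages (default 5).
#' @param widths channel widths per stage.
#' @param strides stride per stage (early stages stride 2, shrinking the
#'   spatial grid the way a classification backbone does).
#' @param seed weight seed.
#' @return object of class `mosr_feature_extractor`.
#' @export
feature_extractor <- function(n_layers = 5L,
                              widths = c(8L, 16L, 24L, 24L, 24L)[seq_len(n_layers)],
                              strides = c(2L, 2L, 1L, 1L, 1L)[seq_len(n_layers)],
                              seed = 1L) {
  stopifnot(n_layers >= 1L, length(widths) == n_layers,
            length(strides) == n_layers)
  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      cin <- if (l == 1L) 3L else widths[l - 1L]
      c(init_conv(c(1L, 3L, 3L), cin, widths[l]),
        list(stride = c(1L, strides[l], strides[l]),
             w_chan = rep(1, widths[l])))
    })
  })
  structure(list(layers = layers, n_layers = as.integer(n_layers)),
            class = "mosr_feature_extractor")
}

# A 2D slice (H x W matrix, values ~[0,1]) as a (1,H,W,3) map in [-1,1].
slice_to_input <- function(s) {
  s <- as.matrix(s)
  x <- array(rep(2 * s - 1, 3L), c(1L, dim(s), 3L))
  x
}

# Forward through the extractor; returns per-stage post-ReLU activations
# (and pre-activations when cache=TRUE, for the backward pass).
fx_forward <- function(fx, x, cache = FALSE) {
  acts <- pre <- ins <- vector("list", fx$n_layers)
  h <- x
  for (l in seq_len(fx$n_layers)) {
    ly <- fx$layers[[l]]
    ins[[l]] <- h
    z <- conv_fwd(h, ly$w, ly$b, stride = ly$stride, pad = c(0L, 1L, 1L))
    pre[[l]] <- z
    h <- relu_fwd(z)
    acts[[l]] <- h
  }
  if (cache) list(acts = acts, pre = pre, ins = ins) else list(acts = acts)
}

# Backward: gradient w.r.t. the extractor *input* given per-stage
# gradients on the activations (weights are frozen).
fx_backward <- function(fx, cache, dacts) {
  dh <- NULL
  for (l in rev(seq_len(fx$n_layers))) {
    ly <- fx$layers[[l]]
    dout <- dacts[[l]]
    if (!is.null(dh)) dout <- dout + dh
    dz <- relu_bwd(cache$pre[[l]], dout)
    dh <- conv_bwd(cache$ins[[l]], ly$w, dz,
                   stride = ly$stride, pad = c(0L, 1L, 1L))$dx
  }
  dh
}

# Channel-normalize activations at each spatial position:
# zhat_c = z_c / sqrt(sum_c z_c^2 + eps).
chan_normalize <- function(z, eps = 1e-10) {
  d <- dim(z)
  m <- matrix(z, prod(d[1:3]), d[4])
  nrm <- sqrt(rowSums(m^2) + eps)
  list(zhat = m / nrm, nrm = nrm, dims = d)
}

#' Perceptual distance between two 2D slices
#'
#' @param x,y 2D matrices of the same shape (intensities nominally in
#'   `[0, 1]`).
#' @param fx a [feature_extractor()].
#' @param grad also return the gradient w.r.t. `x`.
#' @return scalar distance `>= 0`; with `grad = TRUE`, a list
#'   `(value, dx)` where `dx` matches `dim(x)`.
#' @export
lpips_2d <- function(x, y, fx, grad = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop_mosr("slices must have identical shape")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_mosr("non-finite slice values")
  fxv <- fx_forward(fx, slice_to_input(x), cache = grad)
  fyv <- fx_forward(fx, slice_to_input(y))
  total <- 0
  dacts <- if (grad) vector("list", fx$n_layers)
  for (l in seq_len(fx$n_layers)) {
    w <- fx$layers[[l]]$w_chan
    nx <- chan_normalize(fxv$acts[[l]])
    ny <- chan_normalize(fyv$acts[[l]])
    diff <- sweep(nx$zhat - ny$zhat, 2, w, `*`)
    hw <- nrow(diff)                       # H_l * W_l spatial positions
    total <- total + sum(diff^2) / hw
    if (grad) {
      # d/d zhat_x of (1/hw) sum (w (zx - zy))^2
      dzhat <- sweep(diff, 2, w, `*`) * (2 / hw)
      # back through the per-position unit normalization
      dz <- (dzhat - nx$zhat * rowSums(dzhat * nx$zhat)) / nx$nrm
      dacts[[l]] <- array(dz, nx$dims)
    }
  }
  if (!grad) return(total)
  dxin <- fx_backward(fx, fxv, dacts)
  # undo channel replication and the [0,1] -> [-1,1] mapping
  d <- dim(dxin)
  dxm <- matrix(dxin, prod(d[1:3]), d[4])
  dx <- matrix(rowSums(dxm) * 2, d[2], d[3])
  list(value = total, dx = dx)
}

# Draw slice (axis, index) pairs. Balanced policy: n_slices distributed
# round-robin over the eligible axes; uniform: axis drawn per slice.
# Within an axis, indices are sampled without replacement from the
# central `central_frac` band.
sample_slices <- function(dims, cfg, seed = cfg$seed) {
  with_seed(seed, {
    axes <- cfg$axes
    S <- cfg$n_slices
    ax_of <- if (cfg$slice_axes_policy == "balanced") {
      rep(axes, length.out = S)
    } else {
      axes[sample.int(length(axes), S, replace = TRUE)]
    }
    out <- vector("list", S)
    for (a in unique(ax_of)) {
      n <- dims[a]
      margin <- floor(n * (1 - cfg$central_frac) / 2 + 1e-9)
      band <- seq.int(margin + 1L, n - margin)
      k <- sum(ax_of == a)
      if (k > length(band))
        stop_mosr("requested %d slices along axis %d but only %d available",
                  k, a, length(band))
      idx <- band[sample.int(length(band), k)]
      out[ax_of == a] <- lapply(idx, function(i) c(axis = a, index = i))
    }
    out
  })
}

extract_slice <- function(arr, axis, index) {
  switch(axis,
         arr[index, , ], arr[, index, ], arr[, , index])
}

#' Slice-sampled perceptual loss over a volume
#'
#' Draws `cfg$n_slices` paired slice positions (identical for prediction
#' and target), averages [lpips_2d()] over them. Deterministic under
#' `seed`.
#'
#' @param pred,target volumes or 3D arrays on the same grid.
#' @param cfg a [loss_config()].
#' @param fx a [feature_extractor()].
#' @param seed slice-sampling seed (defaults to `cfg$seed`).
#' @param grad also return the gradient w.r.t. `pred`.
#' @return scalar mean perceptual distance; with `grad = TRUE`, a list
#'   `(value, dx)`.
#' @export
lpips_volume <- function(pred, target, cfg, fx, seed = cfg$seed, grad = FALSE) {
  p <- vol_data(pred); t <- vol_data(target)
  if (!all(dim(p) == dim(t))) stop_mosr("grid mismatch between pred and target")
  sl <- sample_slices(dim(p), cfg, seed)
  S <- length(sl)
  total <- 0
  dx <- if (grad) array(0, dim(p))
  for (s in sl) {
    ps <- extract_slice(p, s[["axis"]], s[["index"]])
    ts <- extract_slice(t, s[["axis"]], s[["index"]])
    if (grad) {
      r <- lpips_2d(ps, ts, fx, grad = TRUE)
      total <- total + r$value
      g <- r$dx / S
      i <- s[["index"]]
      switch(s[["axis"]],
             dx[i, , ] <- dx[i, , ] + g,
             dx[, i, ] <- dx[, i, ] + g,
             dx[, , i] <- dx[, , i] + g)
    } else {
      total <- total + lpips_2d(ps, ts, fx)
    }
  }
  if (grad) list(value = total / S, dx = dx) else total / S
}
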