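# The multi-orientation U-Net: a 3D encoder-decoder taking the three
# isotropically-resampled acquisitions as input channels (fixed order
# axial, coronal, sagittal) and emitting one super-resolved channel
# through a linear 1x1x1 head.
#
# Topology per encoding level: two (conv 3x3x3 -> group-norm -> ReLU)
# sub-blocks, feature widths base * 2^(level-1), 2x2x2 max-pooling between
# levels. The decoder mirrors the encoder: trilinear 2x upsampling
# followed by a 3x3x3 convolution halving the features, concatenation
# with the matching encoder skip, then two conv sub-blocks.

#' Multi-orientation U-Net configuration
#'
#' Defaults follow the full-scale network: three input channels, three
#' encoding levels starting at 64 features, group normalization, a
#' 160-voxel cube. Desk-scale work overrides `base_features` and
#' `cube_side`.
#'
#' @param in_channels input channels (one per acquisition orientation).
#' @param out_channels output channels.
#' @param n_levels encoder depth; `cube_side` must be divisible by
#'   `2^(n_levels - 1)`.
#' @param base_features width of the first level; doubled at each
#'   deeper level; must be divisible by `norm_groups`.
#' @param norm_groups groups for group normalization.
#' @param cube_side training grid side length in voxels.
#' @param n_convs_per_block conv -> norm -> ReLU sub-blocks per level.
#' @return list of class `mosr_unet_config`.
#' @export
mo_unet_config <- function(in_channels = 3L, out_channels = 1L, n_levels = 3L,
                           base_features = 64L, norm_groups = 8L,
                           cube_side = 160L, n_convs_per_block = 2L) {
  if (cube_side %% 2^(n_levels - 1) != 0)
    stop_mosr("cube_side (%d) must be divisible by 2^(n_levels-1) = %d",
              cube_side, 2^(n_levels - 1))
  if (base_features %% norm_groups != 0)
    stop_mosr("base_features (%d) must be divisible by norm_groups (%d)",
              base_features, norm_groups)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_levels = as.integer(n_levels),
                 base_features = as.integer(base_features),
                 norm_groups = as.integer(norm_groups),
                 kernel = 3L,
                 cube_side = as.integer(cube_side),
                 n_convs_per_block = as.integer(n_convs_per_block)),
            class = "mosr_unet_config")
}

level_widths <- function(cfg) cfg$base_features * 2^(seq_len(cfg$n_levels) - 1L)

#' Build (initialize) a multi-orientation U-Net
#'
#' Weights use Kaiming fan-in initialization for convolutions and unit
#' scale / zero shift for the normalization layers; the linear head starts
#' near zero.
#'
#' @param cfg a [mo_unet_config()].
#' @param seed integer seed for weight initialization.
#' @return model handle of class `mosr_model` (config + named parameter
#'   list).
#' @export
build_mo_unet <- function(cfg = mo_unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mosr_unet_config"))
  k <- rep(cfg$kernel, 3L)
  W <- level_widths(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (l in seq_len(cfg$n_levels)) {
      cin <- if (l == 1L) cfg$in_channels else W[l - 1L]
      for (j in seq_len(cfg$n_convs_per_block)) {
        p[[sprintf("enc%d_conv%d", l, j)]] <-
          init_cnr(k, if (j == 1L) cin else W[l], W[l])
      }
    }
    for (l in rev(seq_len(cfg$n_levels - 1L))) {
      p[[sprintf("dec%d_up", l)]] <- init_cnr(k, W[l + 1L], W[l])
      for (j in seq_len(cfg$n_convs_per_block)) {
        p[[sprintf("dec%d_conv%d", l, j)]] <-
          init_cnr(k, if (j == 1L) 2L * W[l] else W[l], W[l])
      }
    }
    # near-zero head: the initial prediction starts close to 0 whatever
    # the seed, so early optimization is not dominated by undoing a
    # large random output scale
    p$head <- init_conv(c(1L, 1L, 1L), W[1L], cfg$out_channels, gain = 0.1)
    p
  })
  structure(list(cfg = cfg, params = params), class = "mosr_model")
}

#' @export
print.mosr_model <- function(x, ...) {
  cat(sprintf("<MO U-Net  levels=%d  widths=(%s)  cube=%d^3  params=%s>\n",
              x$cfg$n_levels, paste(level_widths(x$cfg), collapse = ", "),
              x$cfg$cube_side, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param model an `mosr_model`.
#' @return integer total over all convolution and normalization parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
}

#' Forward pass of the multi-orientation U-Net
#'
#' @param model an `mosr_model`.
#' @param x input array `(D, H, W, in_channels)`; extents must be
#'   divisible by `2^(n_levels - 1)`.
#' @param cache keep intermediate activations for the backward pass.
#' @return the output array `(D, H, W, out_channels)`, or (with
#'   `cache = TRUE`) a list `(out, cache)`.
#' @export
mo_unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$cfg; p <- model$params; g <- cfg$norm_groups
  if (length(dim(x)) != 4L || dim(x)[4] != cfg$in_channels)
    stop_mosr("input must be (D,H,W,%d)", cfg$in_channels)
  if (any(dim(x)[1:3] %% 2^(cfg$n_levels - 1L) != 0))
    stop_mosr("input extents must be divisible by %d", 2^(cfg$n_levels - 1L))
  cc <- list(input_dim = dim(x))
  skips <- list()
  h <- x
  for (l in seq_len(cfg$n_levels)) {
    for (j in seq_len(cfg$n_convs_per_block)) {
      nm <- sprintf("enc%d_conv%d", l, j)
      f <- cnr_fwd(h, p[[nm]], g)
      if (cache) cc[[nm]] <- f
      h <- f$out
    }
    if (l < cfg$n_levels) {
      skips[[l]] <- h
      mp <- cpp_maxpool_fwd(h, dim(h))
      if (cache) cc[[sprintf("pool%d", l)]] <- list(idx = mp$idx, xdim = dim(h))
      h <- mp$out
    }
  }
  for (l in rev(seq_len(cfg$n_levels - 1L))) {
    up <- cpp_upsample2x_fwd(h, dim(h))
    if (cache) cc[[sprintf("up%d", l)]] <- dim(h)
    nm <- sprintf("dec%d_up", l)
    f <- cnr_fwd(up, p[[nm]], g)
    if (cache) cc[[nm]] <- f
    h <- array(c(skips[[l]], f$out), c(dim(f$out)[1:3],
                                       dim(skips[[l]])[4] + dim(f$out)[4]))
    if (cache) cc[[sprintf("cat%d", l)]] <- dim(skips[[l]])[4]
    for (j in seq_len(cfg$n_convs_per_block)) {
      nm <- sprintf("dec%d_conv%d", l, j)
      f <- cnr_fwd(h, p[[nm]], g)
      if (cache) cc[[nm]] <- f
      h <- f$out
    }
  }
  out <- conv_fwd(h, p$head$w, p$head$b)   # linear activation
  if (cache) {
    cc$head_in <- h
    list(out = out, cache = cc)
  } else out
}

# Backward pass: gradient of a scalar loss w.r.t. all parameters (and the
# input). `dout` matches the forward output shape.
mo_unet_backward <- function(model, cache, dout) {
  cfg <- model$cfg; p <- model$params; g <- cfg$norm_groups
  grads <- list()
  hb <- conv_bwd(cache$head_in, p$head$w, dout)
  grads$head <- list(w = hb$dw, b = hb$db)
  dh <- hb$dx
  dskips <- list()
  for (l in seq_len(cfg$n_levels - 1L)) {
    for (j in rev(seq_len(cfg$n_convs_per_block))) {
      nm <- sprintf("dec%d_conv%d", l, j)
      bb <- cnr_bwd(cache[[nm]], p[[nm]], g, dh)
      grads[[nm]] <- bb$grads
      dh <- bb$dx
    }
    ns <- cache[[sprintf("cat%d", l)]]
    d <- dim(dh)
    dskips[[l]] <- array(dh[, , , seq_len(ns), drop = FALSE], c(d[1:3], ns))
    dup_out <- array(dh[, , , (ns + 1):d[4], drop = FALSE], c(d[1:3], d[4] - ns))
    nm <- sprintf("dec%d_up", l)
    bb <- cnr_bwd(cache[[nm]], p[[nm]], g, dup_out)
    grads[[nm]] <- bb$grads
    dh <- cpp_upsample2x_bwd(bb$dx, cache[[sprintf("up%d", l)]])
  }
  for (l in rev(seq_len(cfg$n_levels))) {
    if (l < cfg$n_levels) {
      pc <- cache[[sprintf("pool%d", l)]]
      dh <- cpp_maxpool_bwd(dh, pc$idx, pc$xdim)
      dh <- dh + dskips[[l]]
    }
    for (j in rev(seq_len(cfg$n_convs_per_block))) {
      nm <- sprintf("enc%d_conv%d", l, j)
      bb <- cnr_bwd(cache[[nm]], p[[nm]], g, dh)
      grads[[nm]] <- bb$grads
      dh <- bb$dx
    }
  }
  list(grads = grads, dx = dh)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the configuration and all
#' weights.
#'
#' @param model an `mosr_model`.
#' @param path checkpoint path.
#' @return `path` (save) or the restored `mosr_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), params = model$params,
               format = "mosr_checkpoint_v1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "mosr_checkpoint_v1"))
    stop_mosr("not a recognised checkpoint: %s", path)
  cfg <- do.call(mo_unet_config, ck$cfg[setdiff(names(ck$cfg), "kernel")])
  structure(list(cfg = cfg, params = ck$params), class = "mosr_model")
}
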