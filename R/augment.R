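# Paired spatial augmentation: one transform is sampled per step and
# applied identically to all three inputs and the target (and, with
# nearest-neighbour interpolation, to the label map), so no relative
# motion is ever introduced within a training pair. Applied after
# resampling/padding, i.e. on the canonical cube grid.

#' Training configuration
#'
#' Full-scale defaults: Adam with learning rate 1e-4, batch size 1,
#' augmentation probability 0.5.
#'
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size subjects per optimizer step (the reference protocol
#'   uses 1).
#' @param aug_prob probability of applying each augmentation family per
#'   step.
#' @param aug_mode `"independent"`: affine and elastic are each applied
#'   with probability `aug_prob`; `"either"`: with probability `aug_prob`
#'   one of the two (coin flip) is applied.
#' @param affine_params list `(max_rotation_deg, max_translation_mm,
#'   max_scale_frac)`.
#' @param elastic_params list `(control_spacing, max_displacement)` in
#'   voxels.
#' @param seed master training seed (shuffling, augmentation, slice
#'   sampling).
#' @param val_every validation cadence in epochs.
#' @return list of class `mosr_train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 10L, batch_size = 1L,
                         aug_prob = 0.5, aug_mode = c("independent", "either"),
                         affine_params = list(max_rotation_deg = 10,
                                              max_translation_mm = 4,
                                              max_scale_frac = 0.1),
                         elastic_params = list(control_spacing = 8,
                                               max_displacement = 2),
                         seed = 1L, val_every = 1L) {
  if (aug_prob < 0 || aug_prob > 1) stop_mosr("aug_prob must be in [0, 1]")
  if (lr <= 0) stop_mosr("lr must be positive")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), aug_prob = aug_prob,
                 aug_mode = match.arg(aug_mode),
                 affine_params = affine_params,
                 elastic_params = elastic_params,
                 seed = seed, val_every = as.integer(val_every)),
            class = "mosr_train_config")
}

#' Desk-scale training configuration
#'
#' Short CPU runs on small cubes: a larger learning rate (1e-3) suits the
#' few-hundred-step budget, and augmentation amplitudes are kept gentle.
#'
#' @param epochs training epochs.
#' @param seed master training seed.
#' @param lr learning rate (1e-3 suits few-hundred-step budgets).
#' @param aug_prob augmentation probability.
#' @param ... further overrides passed to [train_config()].
#' @export
desk_train_config <- function(epochs = 25L, seed = 1L, lr = 1e-3,
                              aug_prob = 0.3, ...) {
  train_config(lr = lr, epochs = epochs, aug_prob = aug_prob,
               affine_params = list(max_rotation_deg = 5,
                                    max_translation_mm = 2,
                                    max_scale_frac = 0.05),
               elastic_params = list(control_spacing = 8,
                                     max_displacement = 1),
               seed = seed, ...)
}

# Sample one spatial map for a cube of side n: a function from output
# voxel coordinates to input coordinates (N x 3, 0-based).
sample_transform <- function(n, cfg) {
  use_affine <- use_elastic <- FALSE
  if (cfg$aug_mode == "independent") {
    use_affine <- runif(1) < cfg$aug_prob
    use_elastic <- runif(1) < cfg$aug_prob
  } else if (runif(1) < cfg$aug_prob) {
    if (runif(1) < 0.5) use_affine <- TRUE else use_elastic <- TRUE
  }
  if (!use_affine && !use_elastic) return(NULL)

  A <- diag(3); off <- c(0, 0, 0)
  ctr <- (n - 1) / 2
  if (use_affine) {
    ap <- cfg$affine_params
    ang <- runif(3, -1, 1) * ap$max_rotation_deg * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    s <- 1 + runif(1, -1, 1) * ap$max_scale_frac
    tr <- runif(3, -1, 1) * ap$max_translation_mm
    A <- (Rx %*% Ry %*% Rz) / s           # inverse map: output -> input
    off <- ctr - A %*% rep(ctr, 3) - tr
  }
  disp <- NULL
  if (use_elastic) {
    ep <- cfg$elastic_params
    cp <- ep$control_spacing
    m <- as.integer(ceiling(n / cp)) + 2L
    disp <- lapply(1:3, function(a)
      array(runif(m^3, -1, 1) * ep$max_displacement, rep(m, 3)))
  }
  list(A = A, off = as.numeric(off), disp = disp, cp = if (use_elastic) cfg$elastic_params$control_spacing)
}

# Dense output->input coordinates for a sampled transform on an n^3 grid.
transform_coords <- function(tf, n) {
  ax <- seq_len(n) - 1
  grid <- cbind(rep(ax, times = n * n),
                rep(rep(ax, each = n), times = n),
                rep(ax, each = n * n))
  coords <- grid %*% t(tf$A)
  coords <- sweep(coords, 2, -tf$off)     # add offset
  if (!is.null(tf$disp)) {
    m <- dim(tf$disp[[1]])[1]
    cpc <- grid / tf$cp + 1               # control-grid coordinates
    for (a in 1:3) {
      coords[, a] <- coords[, a] +
        cpp_sample_at(tf$disp[[a]], rep(m, 3L), cpc, FALSE)
    }
  }
  coords
}

apply_transform_array <- function(arr, coords, nearest = FALSE) {
  out <- cpp_sample_at(arr + 0, dim(arr), coords, nearest)
  dim(out) <- dim(arr)
  if (is.integer(arr)) storage.mode(out) <- "integer"
  out
}

#' Paired augmentation of a training tuple
#'
#' With the configured probabilities, samples a random affine and/or
#' elastic deformation ONCE and applies it identically (trilinear) to all
#' input channels and the target, and with nearest-neighbour
#' interpolation to the label map. Deterministic under `step_seed`.
#'
#' @param x input array `(n, n, n, C)` on the canonical cube.
#' @param y target array `(n, n, n)`.
#' @param labels optional integer array `(n, n, n)`.
#' @param cfg a [train_config()].
#' @param step_seed integer seed for this step's transform.
#' @return list `(x, y, labels, transformed)`; `transformed` is FALSE when
#'   no transform was drawn (tuple returned unchanged).
#' @export
augment_pair <- function(x, y, labels = NULL, cfg = train_config(),
                         step_seed = 1L) {
  n <- dim(y)[1]
  tf <- with_seed(step_seed, sample_transform(n, cfg))
  if (is.null(tf))
    return(list(x = x, y = y, labels = labels, transformed = FALSE))
  coords <- transform_coords(tf, n)
  xo <- x
  for (c in seq_len(dim(x)[4])) {
    xc <- array(x[, , , c], dim(x)[1:3])
    xo[, , , c] <- apply_transform_array(xc, coords)
  }
  yo <- apply_transform_array(y, coords)
  lo <- if (!is.null(labels)) apply_transform_array(labels, coords, nearest = TRUE)
  list(x = xo, y = yo, labels = lo, transformed = TRUE)
}
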