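# Grid geometry: resampling, intensity normalization, pad/crop to cube.
#
# Resampling preserves the world extent of the image: the output grid
# covers the same physical slab, with extent floor(old_extent_mm /
# new_spacing) per axis, so no voxel is interpolated outside the input's
# support.

#' Resample a volume or label map to a new voxel spacing
#'
#' Output voxel centres are placed uniformly within the input's world
#' extent: output index j along an axis samples input index coordinate
#' `(j + 0.5) * s_new/s_old - 0.5`. Label maps are always resampled with
#' nearest-neighbour interpolation.
#'
#' @param v `mosr_volume` or `mosr_label_map`.
#' @param new_spacing target spacing in mm (length 1 or 3).
#' @param interp `"trilinear"` or `"nearest"`.
#' @return resampled object of the same class.
#' @export
resample <- function(v, new_spacing, interp = c("trilinear", "nearest")) {
  UseMethod("resample")
}

resample_dims <- function(old_dim, old_sp, new_sp) {
  out <- as.integer(floor(old_dim * old_sp / new_sp + 1e-9))
  if (any(out < 1L))
    stop_mosr("degenerate output extent (%s) for spacing (%s)",
              paste(out, collapse = ","), paste(new_sp, collapse = ","))
  out
}

# Affine for the resampled grid: old_idx = new_idx * r + (0.5 r - 0.5)
resample_affine <- function(affine, r) {
  T <- diag(4)
  diag(T)[1:3] <- r
  T[1:3, 4] <- 0.5 * r - 0.5
  affine %*% T
}

#' @export
resample.mosr_volume <- function(v, new_spacing, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3L)
  if (any(new_spacing <= 0)) stop_mosr("new_spacing must be positive")
  odim <- resample_dims(dim(v$data), v$spacing, new_spacing)
  r <- new_spacing / v$spacing
  dat <- cpp_resample3d(v$data, dim(v$data), odim, r, 0.5 * r - 0.5,
                        interp == "nearest")
  volume(dat, spacing = new_spacing, affine = resample_affine(v$affine, r),
         orientation_tag = v$orientation_tag)
}

#' @export
resample.mosr_label_map <- function(v, new_spacing, interp = "nearest") {
  if (!identical(interp, "nearest"))
    stop_mosr("label maps must be resampled with nearest-neighbour interpolation")
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3L)
  odim <- resample_dims(dim(v$labels), v$spacing, new_spacing)
  r <- new_spacing / v$spacing
  dat <- cpp_resample3d(v$labels + 0, dim(v$labels), odim, r, 0.5 * r - 0.5, TRUE)
  label_map(dat, spacing = new_spacing,
            affine = resample_affine(v$affine, r),
            region_table = v$region_table)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Uses both axis-aligned affines to map reference voxel centres into
#' `v`'s index space. Assumes co-registered, axis-aligned volumes
#' (diagonal affines up to translation).
#'
#' @param v volume (or label map) to resample.
#' @param ref reference volume supplying the output grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return an `mosr_volume` on `ref`'s grid.
#' @export
resample_to_grid <- function(v, ref, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  dat <- vol_data(v)
  rdim <- dim(vol_data(ref))
  # world position of ref voxel j: aff_r %*% (j, 1); index in v:
  # inv(aff_v) %*% world. For axis-aligned affines this reduces per axis to
  # idx_v = j * (s_r / s_v) + (o_r - o_v) / s_v.
  av <- if (is_volume(v) || inherits(v, "mosr_label_map")) v$affine else diag(4)
  ar <- if (is_volume(ref) || inherits(ref, "mosr_label_map")) ref$affine else diag(4)
  sv <- diag(av)[1:3]; sr <- diag(ar)[1:3]
  scale <- sr / sv
  shift <- (ar[1:3, 4] - av[1:3, 4]) / sv
  out <- cpp_resample3d(dat + 0, dim(dat), rdim, scale, shift,
                        interp == "nearest")
  sp <- if (is_volume(ref)) ref$spacing else attr(ref, "spacing") %||% c(1, 1, 1)
  volume(out, spacing = sp, affine = ar,
         orientation_tag = if (is_volume(v)) v$orientation_tag else "none")
}

#' Min-max intensity normalization over brain voxels
#'
#' Maps intensities to `[0, 1]` by the min-max range of the nonzero
#' (brain) voxels; background zeros stay exactly 0. Skull-stripped inputs
#' have a dominant zero background that would otherwise pin the minimum.
#'
#' @param v an `mosr_volume` with at least one nonzero voxel.
#' @return normalized `mosr_volume`.
#' @export
normalize_intensity <- function(v) {
  stopifnot(is_volume(v))
  nz <- v$data != 0
  if (!any(nz)) stop_mosr("cannot normalize an all-zero volume")
  rng <- range(v$data[nz])
  if (diff(rng) < .Machine$double.eps)
    stop_mosr("degenerate intensity range: all brain voxels equal %.4g", rng[1])
  dat <- v$data
  dat[nz] <- (dat[nz] - rng[1]) / (rng[2] - rng[1])
  volume(dat, v$spacing, v$affine, v$orientation_tag)
}

# Centered pad (with `value`) or crop of a 3D/4D array to target 3D dims.
# Returns list(data, start) where start[a] is the 0-based index of output
# voxel 0 in the input grid (negative when padding).
pad_crop_array <- function(dat, target, value = 0) {
  nd <- dim(dat)
  has_c <- length(nd) == 4L
  d3 <- nd[1:3]
  # trunc (round toward zero) makes padding and the cropping that undoes
  # it exact inverses when the size difference is odd
  start <- as.integer(trunc((d3 - target) / 2))
  out_dim <- if (has_c) c(target, nd[4]) else target
  out <- array(value, out_dim)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s0 <- max(start[a], 0L)                # first input voxel used
    d0 <- max(-start[a], 0L)               # where it lands in the output
    len <- min(d3[a] - s0, target[a] - d0)
    src[[a]] <- seq.int(s0 + 1L, s0 + len)
    dst[[a]] <- seq.int(d0 + 1L, d0 + len)
  }
  if (has_c) {
    out[dst[[1]], dst[[2]], dst[[3]], ] <- dat[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- dat[src[[1]], src[[2]], src[[3]]]
  }
  list(data = out, start = start)
}

shift_affine <- function(affine, start) {
  T <- diag(4); T[1:3, 4] <- start
  affine %*% T
}

#' Pad or crop a volume to a centered cube
#'
#' Pads with zeros (centered) when smaller than `side`, crops centrally
#' when larger; the affine is shifted so retained voxels keep their world
#' coordinates. Idempotent at the target side length.
#'
#' @param v `mosr_volume` or `mosr_label_map`.
#' @param side cube side length in voxels (>= 1).
#' @return object of the same class with extents `side^3`.
#' @export
pad_or_crop_to_cube <- function(v, side) {
  crop_to_extent(v, rep(as.integer(side), 3L))
}

#' Pad or crop a volume to arbitrary target extents
#'
#' The general form of [pad_or_crop_to_cube()]; also used to crop
#' predictions back to an input's native extent.
#'
#' @param v `mosr_volume` or `mosr_label_map`.
#' @param target_dim integer extents, length 3.
#' @return object of the same class.
#' @export
crop_to_extent <- function(v, target_dim) {
  target_dim <- as.integer(rep(target_dim, length.out = 3L))
  if (any(target_dim < 1L)) stop_mosr("target extents must be >= 1")
  if (inherits(v, "mosr_label_map")) {
    pc <- pad_crop_array(v$labels, target_dim, value = 0L)
    label_map(pc$data, v$spacing, shift_affine(v$affine, pc$start),
              v$region_table)
  } else {
    stopifnot(is_volume(v))
    pc <- pad_crop_array(v$data, target_dim, value = 0)
    volume(pc$data, v$spacing, shift_affine(v$affine, pc$start),
           v$orientation_tag)
  }
}
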