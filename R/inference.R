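# Inference: super-resolution prediction with 1-3 inputs (missing
# channels filled by cloning the highest-priority available scan,
# priority axial > sagittal > coronal), and a non-learned naive fusion
# reference.

#' Super-resolve a subject from 1-3 anisotropic inputs
#'
#' Inputs are preprocessed exactly as in training (normalize -> resample
#' to 1 mm isotropic -> pad to the model cube); missing orientation slots
#' are filled by cloning, keeping the fixed (axial, coronal, sagittal)
#' channel convention: a single axial scan is presented as
#' (axial, axial, axial), axial + sagittal as (axial, axial, sagittal).
#' The prediction is cropped back to the reference input's world extent
#' and clipped to `[0, 1]` at export.
#'
#' @param model a trained `mosr_model`.
#' @param inputs named list of 1-3 `mosr_volume`s keyed by orientation
#'   (`axial`, `coronal`, `sagittal`), or a [subject_record()].
#' @param iso_mm output isotropic spacing.
#' @param clip clip exported intensities to `[0, 1]` (internal network
#'   values are unbounded through the linear head).
#' @return the super-resolved `mosr_volume` (tag `"isotropic"`).
#' @export
super_resolve <- function(model, inputs, iso_mm = 1, clip = TRUE) {
  if (inherits(inputs, "mosr_subject")) inputs <- inputs$inputs
  if (length(inputs) < 1L) stop_mosr("at least one input volume is required")
  rec <- subject_record(inputs, subject_id = "infer")
  pp <- preprocess_subject(rec, model$cfg$cube_side, iso_mm)
  out <- mo_unet_forward(model, pp$x)
  pred <- volume(array(out, dim(out)[1:3]), spacing = rep(iso_mm, 3L),
                 affine = pp$grid$affine, orientation_tag = "isotropic")
  pred <- resample_to_grid(pred, pp$ref)
  if (clip) pred$data <- pmin(pmax(pred$data, 0), 1)
  pred$orientation_tag <- "isotropic"
  pred
}

#' Naive multi-orientation fusion
#'
#' Non-learned reference: each input is normalized, resampled to
#' isotropic spacing on the grid of the highest-priority input, and the
#' results are voxel-wise averaged.
#'
#' @param inputs named list of 1-3 `mosr_volume`s, or a
#'   [subject_record()].
#' @param iso_mm target isotropic spacing.
#' @return fused `mosr_volume` (tag `"isotropic"`).
#' @export
naive_fuse <- function(inputs, iso_mm = 1) {
  if (inherits(inputs, "mosr_subject")) inputs <- inputs$inputs
  if (length(inputs) < 1L) stop_mosr("at least one input volume is required")
  priority <- c("axial", "sagittal", "coronal")
  avail <- intersect(priority, names(inputs))
  ref <- resample(normalize_intensity(inputs[[avail[1]]]), iso_mm)
  acc <- ref$data
  if (length(avail) > 1L) {
    for (o in avail[-1]) {
      v <- resample(normalize_intensity(inputs[[o]]), iso_mm)
      acc <- acc + resample_to_grid(v, ref)$data
    }
  }
  volume(acc / length(avail), spacing = rep(iso_mm, 3L), affine = ref$affine,
         orientation_tag = "isotropic")
}
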