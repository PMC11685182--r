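# Domain types: Volume, LabelMap, SubjectRecord.
#
# A Volume is a 3D scalar image in a canonical RAS-aligned grid: axis 1 runs
# left-to-right, axis 2 posterior-to-anterior, axis 3 inferior-to-superior.
# The orientation tag names the low-resolution (slice-select) axis of an
# anisotropic acquisition: "axial" scans are thick along axis 3,
# "coronal" along axis 2, "sagittal" along axis 1.

ORIENTATIONS <- c("axial", "coronal", "sagittal", "isotropic", "none")

# 1-based slice axis for each anisotropic orientation
SLICE_AXIS <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Construct a Volume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param affine 4x4 voxel-index-to-world transform (0-based indices,
#'   NIfTI convention). Defaults to a diagonal scaling by `spacing`.
#' @param orientation_tag one of `"axial"`, `"coronal"`, `"sagittal"`,
#'   `"isotropic"`, `"none"`.
#' @return an object of class `mosr_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   orientation_tag = "none") {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop_mosr("Volume data must be a 3D array, got %d dimension(s)",
              length(dim(data)))
  if (any(dim(data) < 1L)) stop_mosr("Volume extents must all be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_mosr("spacing must be 3 positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det(affine)) ||
      abs(det(affine)) < 1e-12)
    stop_mosr("affine must be an invertible 4x4 matrix")
  orientation_tag <- match.arg(orientation_tag, ORIENTATIONS)
  structure(list(data = data, spacing = spacing, affine = affine,
                 orientation_tag = orientation_tag),
            class = "mosr_volume")
}

#' Coerce to Volume
#' @param x array or `mosr_volume`.
#' @param ... passed to [volume()] when `x` is an array.
#' @export
as_volume <- function(x, ...) {
  if (inherits(x, "mosr_volume")) x else volume(x, ...)
}

is_volume <- function(x) inherits(x, "mosr_volume")

vol_data <- function(x) if (is_volume(x)) x$data else
  if (inherits(x, "mosr_label_map")) x$labels else as.array(x)

#' @export
print.mosr_volume <- function(x, ...) {
  cat(sprintf("<Volume %s  %s mm  tag=%s  range=[%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              x$orientation_tag, min(x$data), max(x$data)))
  invisible(x)
}

#' Default region table for the infant-brain phantom
#'
#' Label ids: 0 background (reserved), 1 CSF (shell and ventricles),
#' 2 cortical grey matter, 3 white matter, 11-18 the eight deep grey
#' structures. The `tissue` column groups regions into the four global
#' tissue classes: `csf`, `gm_cortical`, `wm`, `gm_subcortical`.
#'
#' @param n_subcortical number of deep grey structures to include (<= 8).
#' @return data.frame with columns `id`, `name`, `tissue`.
#' @export
region_table_default <- function(n_subcortical = 8L) {
  sub <- c("accumbens", "amygdala", "pallidum", "hippocampus",
           "caudate", "putamen", "thalamus", "ventral_dc")
  if (n_subcortical > length(sub))
    stop_mosr("at most %d subcortical structures supported", length(sub))
  data.frame(
    id = c(1L, 2L, 3L, seq_len(n_subcortical) + 10L),
    name = c("CSF", "GMC", "WM", sub[seq_len(n_subcortical)]),
    tissue = c("csf", "gm_cortical", "wm", rep("gm_subcortical", n_subcortical)),
    stringsAsFactors = FALSE)
}

GLOBAL_TISSUES <- c("CSF", "GMC", "WM", "GMS")

#' Construct a LabelMap
#'
#' @param labels 3D integer array; 0 is reserved for background.
#' @param spacing,affine as in [volume()].
#' @param region_table data.frame with columns `id`, `name` (and optionally
#'   `tissue`), mapping label ids to region names.
#' @return object of class `mosr_label_map`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                      region_table = region_table_default()) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop_mosr("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop_mosr("label ids must be non-negative integers")
  storage.mode(labels) <- "integer"
  v <- volume(array(0, dim(labels)), spacing, affine)  # validates geometry
  stopifnot(is.data.frame(region_table), all(c("id", "name") %in% names(region_table)))
  structure(list(labels = labels, spacing = v$spacing, affine = v$affine,
                 region_table = region_table),
            class = "mosr_label_map")
}

#' @export
print.mosr_label_map <- function(x, ...) {
  cat(sprintf("<LabelMap %s  %s mm  %d regions>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              nrow(x$region_table)))
  invisible(x)
}

# Binary mask for a region id, region name, or one of the four global
# tissue classes (GMS/CSF/GMC/WM aggregate over their member labels).
region_mask <- function(lm, region) {
  rt <- lm$region_table
  ids <- if (is.numeric(region)) {
    region
  } else if (region %in% GLOBAL_TISSUES) {
    tis <- c(CSF = "csf", GMC = "gm_cortical", WM = "wm",
             GMS = "gm_subcortical")[[region]]
    rt$id[rt$tissue == tis]
  } else {
    rt$id[rt$name == region]
  }
  if (length(ids) == 0L) stop_mosr("unknown region '%s'", as.character(region))
  array(lm$labels %in% ids, dim(lm$labels))
}

#' Construct a SubjectRecord
#'
#' Bundles one subject's anisotropic low-field inputs (keyed by
#' orientation), an optional isotropic high-field target, an optional label
#' map, and demographic strata used for stratified fold construction.
#'
#' @param inputs named list of `mosr_volume` with names among
#'   `axial`, `coronal`, `sagittal`; at least one entry.
#' @param target optional isotropic `mosr_volume`.
#' @param labelmap optional `mosr_label_map` on the target grid.
#' @param age_group `"3mo"` or `"6mo"`.
#' @param sex `"M"` or `"F"`.
#' @param subject_id character identifier.
#' @return object of class `mosr_subject`.
#' @export
subject_record <- function(inputs, target = NULL, labelmap = NULL,
                           age_group = c("3mo", "6mo"), sex = c("M", "F"),
                           subject_id = "sub-001") {
  if (!is.list(inputs) || length(inputs) < 1L)
    stop_mosr("at least one input volume is required")
  if (!all(names(inputs) %in% names(SLICE_AXIS)))
    stop_mosr("input names must be among: %s",
              paste(names(SLICE_AXIS), collapse = ", "))
  stopifnot(all(vapply(inputs, is_volume, logical(1))))
  if (!is.null(target)) stopifnot(is_volume(target))
  if (!is.null(labelmap)) stopifnot(inherits(labelmap, "mosr_label_map"))
  structure(list(inputs = inputs, target = target, labelmap = labelmap,
                 age_group = match.arg(age_group), sex = match.arg(sex),
                 subject_id = subject_id),
            class = "mosr_subject")
}

#' @export
print.mosr_subject <- function(x, ...) {
  cat(sprintf("<Subject %s  inputs=%s  target=%s  labels=%s  %s/%s>\n",
              x$subject_id, paste(names(x$inputs), collapse = ","),
              !is.null(x$target), !is.null(x$labelmap), x$age_group, x$sex))
  invisible(x)
}
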