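# NIfTI-1 reading and writing, through RNifti. On load, images are
# reoriented to the canonical RAS axis order so that all internal
# processing shares one grid convention.

#' Read a NIfTI volume
#'
#' Reads a 3D (or trailing-singleton 4D) NIfTI-1 image, applies the header
#' scaling slope/intercept (done by RNifti), reorients to RAS, and returns
#' a [volume()] carrying the header spacing and affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param orientation_tag orientation tag to attach; by default inferred
#'   as the axis with the coarsest spacing if anisotropic, else
#'   `"isotropic"`.
#' @return an `mosr_volume`.
#' @export
read_volume <- function(path, orientation_tag = NULL) {
  if (!file.exists(path)) stop_mosr("file not found: %s", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    RNifti::orientation(img) <- "RAS"   # reorientable headers only
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), d)
  } else {
    stop_mosr("expected a 3D image, got %dD: %s", length(d), path)
  }
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (!is.finite(det(aff)) || abs(det(aff)) < 1e-12)
    stop_mosr("non-invertible affine in %s", path)
  if (is.null(orientation_tag)) {
    orientation_tag <- if (max(sp) / min(sp) > 1.5) {
      names(SLICE_AXIS)[match(which.max(sp), SLICE_AXIS)]
    } else "isotropic"
  }
  volume(img2, spacing = sp, affine = aff, orientation_tag = orientation_tag)
}

#' Write a Volume to NIfTI-1
#'
#' @param v an `mosr_volume` (or `mosr_label_map`, written with an integer
#'   datatype).
#' @param path output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @param datatype NIfTI datatype; `"auto"` uses float32 for volumes and
#'   int16 for label maps.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "auto") {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_mosr("directory does not exist: %s", dir)
  is_labels <- inherits(v, "mosr_label_map")
  dat <- if (is_labels) v$labels else v$data
  if (datatype == "auto") datatype <- if (is_labels) "int16" else "float"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a label map and its region table
#'
#' @param path NIfTI path with integer labels.
#' @param region_table data.frame mapping ids to names, or a path to a
#'   tab-separated file with columns `id`, `name`, `tissue`.
#' @return an `mosr_label_map`.
#' @export
read_label_map <- function(path, region_table = region_table_default()) {
  if (is.character(region_table))
    region_table <- read.delim(region_table, stringsAsFactors = FALSE)
  v <- read_volume(path, orientation_tag = "none")
  lab <- round(v$data)
  label_map(lab, spacing = v$spacing, affine = v$affine,
            region_table = region_table)
}

#' @rdname write_volume
#' @export
write_label_map <- function(v, path) write_volume(v, path, datatype = "int16")
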