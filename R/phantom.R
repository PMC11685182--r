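# Procedural infant-brain phantom and ultra-low-field acquisition
# simulator. The phantom is a nested-ellipsoid T2-weighted head: a bright
# CSF shell and ventricles, a cortical grey-matter ribbon, a white-matter
# interior and up to eight ellipsoidal deep grey structures, all warped by
# a per-subject smooth random deformation so no two subjects share a
# geometry. The degradation model emulates the acquisition geometry of a
# 64 mT scanner: thick-slab excitation along one axis, coarse in-plane
# sampling, a field-strength contrast shift (gamma remap), multiplicative
# bias shading, and Rician magnitude noise.

#' Phantom configuration
#'
#' @param side_mm cube side in mm (default 64: desk scale; 160 matches a
#'   full-size infant head window).
#' @param iso_mm isotropic voxel size in mm.
#' @param age_mode `"3mo"`, `"6mo"` or `"isointense"`; sets the default
#'   grey/white contrast. T2-weighted infant scans show unmyelinated white
#'   matter brighter than grey, a separation that collapses towards the
#'   isointense phase around 6 months.
#' @param gm_wm_contrast grey/white separation dial in `[0, 1]`;
#'   0 = isointense. Defaults by `age_mode`: 0.8 (3mo), 0.3 (6mo),
#'   0 (isointense).
#' @param n_subcortical number of deep grey structures (0-8).
#' @param seed integer seed controlling the subject-specific deformation
#'   and texture.
#' @param deform_amp amplitude of the smooth boundary deformation in
#'   voxels; the default keeps per-structure volume changes within the
#'   voxelization-error budget while still giving every subject a
#'   distinct geometry.
#' @param texture_amp amplitude of intra-tissue texture, intensity units.
#' @return list of class `mosr_phantom_config`.
#' @export
phantom_config <- function(side_mm = 64L, iso_mm = 1, age_mode = c("6mo", "3mo", "isointense"),
                           gm_wm_contrast = NULL, n_subcortical = 8L, seed = 1L,
                           deform_amp = 0.75, texture_amp = 0.02) {
  age_mode <- match.arg(age_mode)
  if (is.null(gm_wm_contrast))
    gm_wm_contrast <- c(`3mo` = 0.8, `6mo` = 0.3, isointense = 0)[[age_mode]]
  if (side_mm < 8 || iso_mm <= 0) stop_mosr("invalid phantom size")
  if (gm_wm_contrast < 0 || gm_wm_contrast > 1)
    stop_mosr("gm_wm_contrast must be in [0, 1]")
  if (n_subcortical < 0 || n_subcortical > 8) stop_mosr("n_subcortical must be 0-8")
  structure(list(side_mm = side_mm, iso_mm = iso_mm, age_mode = age_mode,
                 gm_wm_contrast = gm_wm_contrast,
                 n_subcortical = as.integer(n_subcortical), seed = seed,
                 deform_amp = deform_amp, texture_amp = texture_amp),
            class = "mosr_phantom_config")
}

#' Acquisition specification for the degradation model
#'
#' @param in_plane_mm in-plane resolution (default 1.5 mm).
#' @param slice_mm slice thickness (default 5 mm); must be >=
#'   `in_plane_mm`.
#' @param slice_axis 1-based slice-select axis: 3 = axial
#'   (inferior-superior), 2 = coronal, 1 = sagittal.
#' @param noise_sigma Rician noise scale as a fraction of the intensity
#'   range.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field.
#' @param contrast_gamma exponent of the gamma contrast remap emulating the
#'   field-strength contrast shift (1 = none).
#' @param seed integer seed for bias and noise.
#' @return list of class `mosr_acquisition_spec`.
#' @export
acquisition_spec <- function(in_plane_mm = 1.5, slice_mm = 5, slice_axis = 3L,
                             noise_sigma = 0.05, bias_amplitude = 0.2,
                             contrast_gamma = 0.7, seed = 1L) {
  if (slice_mm < in_plane_mm)
    stop_mosr("slice_mm must be >= in_plane_mm (anisotropy points along the slice axis)")
  if (!slice_axis %in% 1:3) stop_mosr("slice_axis must be 1, 2 or 3")
  if (noise_sigma < 0 || bias_amplitude < 0 || contrast_gamma <= 0)
    stop_mosr("invalid degradation parameters")
  structure(list(in_plane_mm = in_plane_mm, slice_mm = slice_mm,
                 slice_axis = as.integer(slice_axis),
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 contrast_gamma = contrast_gamma, seed = seed),
            class = "mosr_acquisition_spec")
}

# Smooth zero-mean random field, normalized to max |.| = 1.
smooth_field <- function(dims, sigma) {
  f <- cpp_gauss_blur3d(array(rnorm(prod(dims)), dims), dims,
                        rep(sigma, 3L))
  f <- f - mean(f)
  f / max(abs(f))
}

# Template geometry: centres and semi-axes as fractions of the cube side,
# relative to the cube centre; axes ordered (LR, PA, IS).
# Positions chosen so the eight ellipsoids are pairwise disjoint and lie
# fully inside the white-matter shell: voxel-counted volumes then match
# the analytic ellipsoid volumes up to voxelization error.
subcortical_templates <- function() {
  list(
    accumbens   = list(c(+0.13, +0.17, -0.11), c(0.040, 0.045, 0.040)),
    amygdala    = list(c(-0.15, +0.16, -0.11), c(0.050, 0.050, 0.045)),
    pallidum    = list(c(+0.17, +0.01, -0.01), c(0.045, 0.055, 0.045)),
    hippocampus = list(c(-0.16, -0.13, -0.05), c(0.050, 0.080, 0.045)),
    caudate     = list(c(+0.12, +0.13, +0.09), c(0.045, 0.080, 0.050)),
    putamen     = list(c(-0.17, +0.03, +0.09), c(0.050, 0.075, 0.050)),
    thalamus    = list(c(+0.12, -0.15, +0.09), c(0.075, 0.085, 0.065)),
    ventral_dc  = list(c(-0.04, -0.03, -0.15), c(0.055, 0.060, 0.050)))
}

#' Generate an isotropic infant-brain phantom
#'
#' Builds the nested anatomy on an isotropic grid, applies a per-subject
#' smooth random deformation to all boundaries and mild intra-tissue
#' texture, and returns both the T2-weighted intensity volume (in `[0, 1]`)
#' and a label map exactly consistent with the generative geometry.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `volume` (an `mosr_volume`, tag
#'   `"isotropic"`) and `labels` (an `mosr_label_map`). The attribute
#'   `"generative_volumes_cm3"` on `labels` holds the analytic ellipsoid
#'   volume of each subcortical structure.
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "mosr_phantom_config"))
  n <- as.integer(round(cfg$side_mm / cfg$iso_mm))
  dims <- rep(n, 3L)
  with_seed(cfg$seed, {
    centre <- (n - 1) / 2
    ax <- seq_len(n) - 1
    X <- array(rep(ax, times = n * n), dims)
    Y <- array(rep(rep(ax, each = n), times = n), dims)
    Z <- array(rep(ax, each = n * n), dims)
    if (cfg$deform_amp > 0) {
      X <- X + cfg$deform_amp * smooth_field(dims, n / 8)
      Y <- Y + cfg$deform_amp * smooth_field(dims, n / 8)
      Z <- Z + cfg$deform_amp * smooth_field(dims, n / 8)
    }
    ell <- function(cen, rad) {
      ((X - centre - cen[1] * n) / (rad[1] * n))^2 +
      ((Y - centre - cen[2] * n) / (rad[2] * n))^2 +
      ((Z - centre - cen[3] * n) / (rad[3] * n))^2 <= 1
    }
    outer_r <- c(0.38, 0.44, 0.40)
    head   <- ell(c(0, 0, 0), outer_r)
    gm_out <- ell(c(0, 0, 0), outer_r * 0.93)
    wm_out <- ell(c(0, 0, 0), outer_r * 0.80)
    vent_l <- ell(c(-0.06, 0.02, 0.04), c(0.045, 0.13, 0.08))
    vent_r <- ell(c(+0.06, 0.02, 0.04), c(0.045, 0.13, 0.08))

    lab <- array(0L, dims)
    lab[head] <- 1L            # CSF shell
    lab[gm_out] <- 2L          # cortical GM ribbon
    lab[wm_out] <- 3L          # WM interior
    lab[vent_l | vent_r] <- 1L # ventricles are CSF

    tmpl <- subcortical_templates()[seq_len(cfg$n_subcortical)]
    gen_vol <- numeric(0)
    if (cfg$n_subcortical > 0) {
      for (i in seq_along(tmpl)) {
        m <- ell(tmpl[[i]][[1]], tmpl[[i]][[2]])
        lab[m & wm_out] <- 10L + i
        r_mm <- tmpl[[i]][[2]] * n * cfg$iso_mm
        gen_vol[names(tmpl)[i]] <- 4 / 3 * pi * prod(r_mm) / 1000
      }
    }

    # T2w intensities: CSF bright; WM brighter than GM by the contrast dial
    gm_i <- 0.52
    wm_i <- gm_i + 0.25 * cfg$gm_wm_contrast
    ints <- c(`1` = 0.92, `2` = gm_i, `3` = wm_i)
    vol <- array(0, dims)
    vol[lab == 1L] <- ints[["1"]]
    vol[lab == 2L] <- ints[["2"]]
    vol[lab == 3L] <- ints[["3"]]
    vol[lab >= 11L] <- gm_i + 0.02   # deep grey: close to cortical GM
    if (cfg$texture_amp > 0) {
      tex <- cfg$texture_amp * smooth_field(dims, 1.5)
      vol[lab > 0L] <- vol[lab > 0L] + tex[lab > 0L]
    }
    vol <- pmin(pmax(vol, 0), 1)

    aff <- diag(c(rep(cfg$iso_mm, 3), 1))
    aff[1:3, 4] <- -centre * cfg$iso_mm
    rt <- region_table_default(cfg$n_subcortical)
    lm <- label_map(lab, spacing = rep(cfg$iso_mm, 3), affine = aff,
                    region_table = rt)
    attr(lm, "generative_volumes_cm3") <- gen_vol
    list(volume = volume(vol, spacing = rep(cfg$iso_mm, 3), affine = aff,
                         orientation_tag = "isotropic"),
         labels = lm)
  })
}

#' Simulate an anisotropic ultra-low-field acquisition
#'
#' Degrades an isotropic volume through the forward model: (1) boxcar slab
#' average along the slice axis over `slice_mm`; (2) downsampling to the
#' `(in_plane, in_plane, slice)` grid; (3) gamma contrast remap;
#' (4) multiplication by a smooth random bias field; (5) Rician magnitude
#' noise. Deterministic under `spec$seed`.
#'
#' @param hf isotropic `mosr_volume`.
#' @param spec an [acquisition_spec()].
#' @return anisotropic `mosr_volume` with the orientation tag implied by
#'   `spec$slice_axis`.
#' @export
degrade <- function(hf, spec) {
  stopifnot(is_volume(hf), inherits(spec, "mosr_acquisition_spec"))
  iso <- hf$spacing
  if (max(iso) / min(iso) > 1.001)
    stop_mosr("degrade() expects an isotropic input (spacing %s)",
              paste(format(iso, digits = 3), collapse = "x"))
  iso <- iso[1]
  if (spec$slice_mm < iso - 1e-9)
    stop_mosr("slice_mm (%.3g) must be >= input spacing (%.3g)", spec$slice_mm, iso)
  width <- as.integer(round(spec$slice_mm / iso))
  ax <- spec$slice_axis

  slab <- cpp_slab_average(hf$data, dim(hf$data), ax, width)
  # spacing after slab integration
  sp1 <- iso * c(1, 1, 1); sp1[ax] <- iso * width
  # in-plane downsample (slice axis already on its final grid)
  target_sp <- rep(spec$in_plane_mm, 3L); target_sp[ax] <- sp1[ax]
  odim <- resample_dims(dim(slab), sp1, target_sp)
  r <- target_sp / sp1
  dat <- cpp_resample3d(slab, dim(slab), odim, r, 0.5 * r - 0.5, FALSE)

  dat <- pmax(dat, 0)
  if (abs(spec$contrast_gamma - 1) > 0) dat <- dat^spec$contrast_gamma
  with_seed(spec$seed, {
    if (spec$bias_amplitude > 0) {
      dat <- dat * (1 + spec$bias_amplitude * smooth_field(dim(dat), max(dim(dat)) / 4))
    }
    if (spec$noise_sigma > 0) {
      rng <- diff(range(dat))
      s <- spec$noise_sigma * rng
      dat <- sqrt((dat + rnorm(length(dat), 0, s))^2 +
                  rnorm(length(dat), 0, s)^2)
      dim(dat) <- odim
    }
  })

  out_sp <- rep(spec$in_plane_mm, 3L); out_sp[ax] <- spec$slice_mm
  # overall index mapping from hf grid: scale = out_sp / iso
  rr <- out_sp / iso
  tag <- names(SLICE_AXIS)[match(ax, SLICE_AXIS)]
  volume(dat, spacing = out_sp,
         affine = resample_affine(hf$affine, rr),
         orientation_tag = tag)
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an isotropic phantom (its own geometry seed), three
#' orthogonal degraded acquisitions with independent noise seeds, the
#' ground-truth label map, and randomly assigned age/sex strata (3mo:6mo
#' and M:F proportions follow a 16:40 / 26:30 cohort).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cfg a [phantom_config()]; `cfg$seed` is the master seed.
#' @param spec_template an [acquisition_spec()] whose geometry and noise
#'   settings are shared by all acquisitions.
#' @return list of [subject_record()]s.
#' @export
make_dataset <- function(n_subjects, cfg = phantom_config(),
                         spec_template = acquisition_spec()) {
  stopifnot(n_subjects >= 1)
  seeds <- seed_streams(cfg$seed, 5L * n_subjects)
  strata <- with_seed(seeds[1], list(
    age = sample(c("3mo", "6mo"), n_subjects, TRUE, prob = c(16, 40)),
    sex = sample(c("M", "F"), n_subjects, TRUE, prob = c(26, 30))))
  lapply(seq_len(n_subjects), function(i) {
    scfg <- cfg; scfg$seed <- seeds[5 * (i - 1) + 2]
    ph <- make_phantom(scfg)
    inputs <- lapply(seq_along(SLICE_AXIS), function(k) {
      sp <- spec_template
      sp$slice_axis <- SLICE_AXIS[[k]]
      sp$seed <- seeds[5 * (i - 1) + 2 + k]
      degrade(ph$volume, sp)
    })
    names(inputs) <- names(SLICE_AXIS)
    subject_record(inputs = inputs[c("axial", "coronal", "sagittal")],
                   target = ph$volume, labelmap = ph$labels,
                   age_group = strata$age[i], sex = strata$sex[i],
                   subject_id = sprintf("sub-%03d", i))
  })
}

#' Write a dataset to disk with a manifest
#'
#' Writes per-subject NIfTI files plus `manifest.tsv` (tab-separated:
#' subject_id, input paths, target, labelmap, age_group, sex) and
#' `regions.tsv` (the region table). The manifest is the hand-off contract
#' between pipeline stages.
#'
#' @param records list of [subject_record()]s.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    paths <- list()
    for (o in names(r$inputs)) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", r$subject_id, o))
      write_volume(r$inputs[[o]], p)
      paths[[o]] <- p
    }
    tgt <- lab <- NA_character_
    if (!is.null(r$target)) {
      tgt <- file.path(dir, sprintf("%s_hf.nii.gz", r$subject_id))
      write_volume(r$target, tgt)
    }
    if (!is.null(r$labelmap)) {
      lab <- file.path(dir, sprintf("%s_labels.nii.gz", r$subject_id))
      write_label_map(r$labelmap, lab)
    }
    data.frame(subject_id = r$subject_id,
               axial = paths$axial %||% NA_character_,
               coronal = paths$coronal %||% NA_character_,
               sagittal = paths$sagittal %||% NA_character_,
               target = tgt, labelmap = lab,
               age_group = r$age_group, sex = r$sex,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- records[[1]]$labelmap$region_table %||% region_table_default()
  write.table(rt, file.path(dir, "regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(man_path)
}

#' Read a dataset from a manifest
#'
#' @param manifest_path path to a `manifest.tsv` written by
#'   [write_dataset()].
#' @return list of [subject_record()]s.
#' @export
read_dataset <- function(manifest_path) {
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  rt_path <- file.path(dirname(manifest_path), "regions.tsv")
  rt <- if (file.exists(rt_path)) read.delim(rt_path, stringsAsFactors = FALSE)
        else region_table_default()
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    inputs <- list()
    for (o in c("axial", "coronal", "sagittal")) {
      p <- row[[o]]
      if (!is.na(p) && nzchar(p))
        inputs[[o]] <- read_volume(p, orientation_tag = o)
    }
    target <- if (!is.na(row$target)) read_volume(row$target, "isotropic")
    labmap <- if (!is.na(row$labelmap)) read_label_map(row$labelmap, rt)
    subject_record(inputs, target, labmap, row$age_group, row$sex,
                   row$subject_id)
  })
}
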