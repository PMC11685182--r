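# Cohort evaluation. The reference (high-field / ground-truth) label map
# supplies the anatomy; each evaluated image is segmented by per-tissue
# intensity classification within the reference ROI hull, so Dice
# measures how faithfully the image's intensities reproduce the reference
# geometry. An external contrast-agnostic segmenter can be plugged in via
# the `segmenter` argument of evaluate_cohort().

#' Intensity-driven segmentation within the reference ROI hull
#'
#' Global tissue classes (CSF, cortical GM, WM, subcortical GM): every
#' voxel of the brain hull (union of nonzero reference labels) is
#' assigned to the class whose median intensity -- measured on `img`
#' within the reference class mask -- is nearest. Subcortical structures:
#' within a 2-voxel dilation of the reference structure mask, voxels are
#' kept when their intensity is closer to the structure's median than to
#' the surrounding white matter's.
#'
#' @param img `mosr_volume` or 3D array on the reference grid.
#' @param ref_lm reference `mosr_label_map`.
#' @return list with `class_masks` (named logical arrays for the four
#'   global tissues) and `structure_masks` (one per subcortical region).
#' @export
segment_by_intensity <- function(img, ref_lm) {
  dat <- vol_data(img)
  if (!all(dim(dat) == dim(ref_lm$labels))) stop_mosr("grid mismatch")
  hull <- ref_lm$labels > 0L
  classes <- GLOBAL_TISSUES
  ref_masks <- lapply(classes, function(g) region_mask(ref_lm, g))
  names(ref_masks) <- classes
  meds <- vapply(ref_masks, function(m) median(dat[m]), numeric(1))
  # nearest-centroid assignment over the hull
  dist <- vapply(meds, function(m) abs(dat[hull] - m), numeric(sum(hull)))
  assign <- max.col(-dist, ties.method = "first")
  class_masks <- lapply(seq_along(classes), function(i) {
    m <- array(FALSE, dim(dat)); m[hull] <- assign == i; m
  })
  names(class_masks) <- classes

  rt <- ref_lm$region_table
  sub_ids <- rt$id[rt$tissue == "gm_subcortical"]
  structure_masks <- list()
  wm_med <- meds[["WM"]]
  for (id in sub_ids) {
    rm <- ref_lm$labels == id
    if (!any(rm)) next
    dil <- cpp_gauss_blur3d(rm + 0, dim(rm), rep(1, 3L)) > 0.02
    med_s <- median(dat[rm])
    m <- array(FALSE, dim(dat))
    m[dil] <- abs(dat[dil] - med_s) < abs(dat[dil] - wm_med)
    structure_masks[[rt$name[rt$id == id]]] <- m
  }
  list(class_masks = class_masks, structure_masks = structure_masks)
}

# Dice of every region (4 global classes + subcortical structures) of an
# image against the reference label map.
dice_profile <- function(img, ref_lm, segmenter = segment_by_intensity) {
  seg <- segmenter(img, ref_lm)
  out <- c()
  for (g in GLOBAL_TISSUES)
    out[g] <- dice(seg$class_masks[[g]], region_mask(ref_lm, g))
  for (nm in names(seg$structure_masks))
    out[nm] <- dice(seg$structure_masks[[nm]], region_mask(ref_lm, nm))
  out
}

# Derived region volumes (cm^3) of an image's intensity segmentation.
seg_volumes <- function(img, ref_lm, segmenter = segment_by_intensity) {
  seg <- segmenter(img, ref_lm)
  vox <- prod(ref_lm$spacing) / 1000
  v <- vapply(seg$class_masks, sum, numeric(1)) * vox
  if (length(seg$structure_masks) > 0)
    v <- c(v, vapply(seg$structure_masks, sum, numeric(1)) * vox)
  v
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Computes, per subject and method: region Dice (via intensity
#' segmentation against the reference label map), derived region volumes,
#' grey/white intensity differentiation (masks from the reference
#' segmentation; percentage change against the fused ULF baseline), and
#' NMSE/PSNR/SSIM against the target. Cohort level: per-region Pearson r,
#' Lin's CCC, mean volume difference and Bland-Altman limits
#' (prediction-derived vs reference volumes), and pairwise Wilcoxon
#' signed-rank tests between methods on per-region Dice with the
#' family-wise threshold applied.
#'
#' The method name `"ulf"` is computed from the raw inputs: its Dice and
#' intensity rows are the average over the (resampled) axial, coronal
#' and sagittal scans.
#'
#' @param records list of [subject_record()]s with target + label map.
#' @param predictions named list: method name -> list of `mosr_volume`
#'   predictions parallel to `records`. Entries for `"ulf"` may be NULL.
#' @param alpha family-wise error rate basis for pairwise tests.
#' @param segmenter segmentation plug-in, defaulting to
#'   [segment_by_intensity()].
#' @return an `mosr_eval_report`: list of data.frames
#'   `(per_subject, volumes, concordance, wilcoxon, settings)`.
#' @export
evaluate_cohort <- function(records, predictions, alpha = 0.05,
                            segmenter = segment_by_intensity) {
  methods <- names(predictions)
  stopifnot(length(methods) > 0)
  per_subject <- list()
  volumes <- list()
  for (si in seq_along(records)) {
    rec <- records[[si]]
    if (is.null(rec$target) || is.null(rec$labelmap))
      stop_mosr("record %s lacks target or label map", rec$subject_id)
    ref_img <- rec$target
    ref_lm <- rec$labelmap
    gm <- region_mask(ref_lm, "GMC"); wm <- region_mask(ref_lm, "WM")
    ulf_imgs <- lapply(rec$inputs, function(v)
      resample_to_grid(resample(normalize_intensity(v), ref_lm$spacing[1]), ref_img))
    ulf_fuse <- volume(Reduce(`+`, lapply(ulf_imgs, vol_data)) / length(ulf_imgs),
                       ref_img$spacing, ref_img$affine)
    base_diff <- gm_wm_differentiation(ulf_fuse, gm, wm)$abs_diff
    ref_vols <- region_volumes(ref_lm)

    for (m in methods) {
      if (m == "ulf") {
        dms <- lapply(ulf_imgs, dice_profile, ref_lm = ref_lm, segmenter = segmenter)
        dmat <- do.call(rbind, dms)
        dvec <- colMeans(dmat)
        iq <- image_quality(ulf_fuse, ref_img)
        idiff <- gm_wm_differentiation(ulf_fuse, gm, wm, base_diff)
        vols <- seg_volumes(ulf_fuse, ref_lm, segmenter)
      } else {
        pred <- predictions[[m]][[si]]
        pred_al <- resample_to_grid(pred, ref_img)
        dvec <- dice_profile(pred_al, ref_lm, segmenter)
        iq <- image_quality(pred_al, ref_img)
        idiff <- gm_wm_differentiation(pred_al, gm, wm, base_diff)
        vols <- seg_volumes(pred_al, ref_lm, segmenter)
      }
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject_id = rec$subject_id, method = m,
        metric = c(paste0("dice_", names(dvec)), "nmse", "psnr", "ssim",
                   "gmwm_absdiff", "gmwm_pct_vs_ulf"),
        value = c(unname(dvec), iq$nmse, iq$psnr, iq$ssim,
                  idiff$abs_diff, idiff$pct_vs_reference),
        stringsAsFactors = FALSE)
      volumes[[length(volumes) + 1L]] <- data.frame(
        subject_id = rec$subject_id, method = m, region = names(vols),
        volume_cm3 = unname(vols),
        ref_cm3 = ref_vols$volume_cm3[match(names(vols), ref_vols$region)],
        stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, per_subject)
  volumes <- do.call(rbind, volumes)

  # cohort concordance per method x region
  conc <- NULL
  if (length(records) >= 3) {
    conc <- do.call(rbind, lapply(methods, function(m) {
      vm <- volumes[volumes$method == m, ]
      do.call(rbind, lapply(unique(vm$region), function(rg) {
        v <- vm[vm$region == rg, ]
        cc <- suppressWarnings(concordance(v$volume_cm3, v$ref_cm3))
        data.frame(method = m, region = rg, r = cc$r, ccc = cc$ccc,
                   mean_diff_cm3 = cc$mean_diff, ba_lower = cc$ba_lower,
                   ba_upper = cc$ba_upper, n = cc$n, stringsAsFactors = FALSE)
      }))
    }))
  }

  # pairwise Wilcoxon on per-region Dice
  wx <- NULL
  dice_rows <- per_subject[grepl("^dice_", per_subject$metric), ]
  regions <- unique(sub("^dice_", "", dice_rows$metric))
  pairs <- if (length(methods) >= 2) utils::combn(methods, 2, simplify = FALSE) else list()
  thr <- fwer_threshold(alpha, max(1L, length(regions[regions %in% GLOBAL_TISSUES]) * length(pairs)))
  for (pr in pairs) {
    for (rg in regions) {
      xa <- dice_rows$value[dice_rows$method == pr[1] & dice_rows$metric == paste0("dice_", rg)]
      xb <- dice_rows$value[dice_rows$method == pr[2] & dice_rows$metric == paste0("dice_", rg)]
      if (sum(xa - xb != 0) < 5) next
      w <- wilcoxon_signed_rank(xa, xb)
      wx <- rbind(wx, data.frame(method_a = pr[1], method_b = pr[2],
                                 region = rg, W = w$W, p = w$p, rbc = w$rbc,
                                 n = w$n, significant = w$p < thr,
                                 stringsAsFactors = FALSE))
    }
  }
  structure(list(per_subject = per_subject, volumes = volumes,
                 concordance = conc, wilcoxon = wx,
                 settings = data.frame(alpha = alpha, fwer_threshold = thr,
                                       n_subjects = length(records))),
            class = "mosr_eval_report")
}

#' Write an evaluation report as tab-separated tables
#'
#' Writes `per_subject.tsv`, `volumes.tsv`, `concordance.tsv`,
#' `wilcoxon.tsv` and a plain-text `summary.txt` with cohort means.
#'
#' @param report an `mosr_eval_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm) {
    if (is.null(df)) return()
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
    write.table(df, file.path(dir, nm), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(report$per_subject, "per_subject.tsv")
  wr(report$volumes, "volumes.tsv")
  wr(report$concordance, "concordance.tsv")
  wr(report$wilcoxon, "wilcoxon.tsv")
  wr(report$settings, "settings.tsv")
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  ps <- report$per_subject
  for (m in unique(ps$method)) {
    writeLines(sprintf("method: %s", m), con)
    for (met in unique(ps$metric)) {
      v <- ps$value[ps$method == m & ps$metric == met]
      v <- v[is.finite(v)]
      if (length(v) > 0)
        writeLines(sprintf("  %-22s mean %.6g", met, mean(v)), con)
    }
  }
  invisible(dir)
}
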