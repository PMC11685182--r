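# Metric battery: Dice, volumes, concordance, intensity differentiation,
# image quality, cohort report assembly.

test_that("dice matches its closed form on constructed masks", {
  m <- array(FALSE, c(4, 4, 4))
  a <- m; a[1:2, 1, 1] <- TRUE; a[1:2, 2, 1] <- TRUE   # |A| = 4
  b <- m; b[1:2, 2, 1] <- TRUE; b[1:2, 3, 1] <- TRUE   # |B| = 4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  c <- m; c[4, 4, 4] <- TRUE
  expect_equal(dice(a, c), 0)
  expect_equal(dice(m, m), 1)          # both empty
  expect_equal(dice(a, m), 0)          # exactly one empty
  # symmetry and permutation invariance
  expect_equal(dice(a, b), dice(b, a))
  perm <- sample(4)
  expect_equal(dice(a[perm, , ], b[perm, , ]), dice(a, b))
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "mismatch")
})

test_that("region volumes follow voxel size", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1:10] <- 0L
  lab[seq_len(1000)] <- 3L                   # 1000 voxels of WM
  lm <- label_map(lab, spacing = c(1, 1, 1))
  v <- region_volumes(lm)
  expect_equal(v$volume_cm3[v$region == "WM"], 1)
  lm2 <- label_map(lab, spacing = c(1.5, 1.5, 5))
  v2 <- region_volumes(lm2)
  expect_equal(v2$volume_cm3[v2$region == "WM"], 11.25)
  expect_equal(v2$volume_cm3[v2$region == "caudate"], 0)  # empty region
})

test_that("concordance reproduces hand-computed values", {
  perfect <- concordance(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$mean_diff, 0)

  # x=(1,2,3), y=(2,3,4): population moments give CCC = 4/7
  cc <- concordance(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cc$r, 1)
  expect_equal(cc$ccc, 4 / 7, tolerance = 1e-12)
  expect_equal(cc$mean_diff, -1)

  # orthogonalized pair: zero correlation by construction -> CCC ~ 0
  x <- c(1, 2, 3, 4, 5)
  y0 <- c(5, 1, 4, 2, 3)
  y <- y0 - sum((y0 - mean(y0)) * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  cz <- concordance(x, y)
  expect_lt(abs(cz$ccc), 1e-10)

  expect_warning(concordance(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(concordance(1:2, 1:2), "at least 3")
})

test_that("|CCC| <= |r| over many random pairs", {
  res <- vapply(1:1000, function(s) {
    v <- with_seed_test(s, list(x = rnorm(8), y = rnorm(8) + rnorm(1)))
    cc <- concordance(v$x, v$y)
    abs(cc$ccc) <= abs(cc$r) + 1e-12
  }, logical(1))
  expect_true(all(res))
})

test_that("grey/white differentiation matches the percentage convention", {
  img <- array(0, c(6, 6, 6))
  gm <- array(FALSE, dim(img)); wm <- gm
  gm[1:3, , ] <- TRUE; wm[4:6, , ] <- TRUE
  img[gm] <- 0.3; img[wm] <- 0.6
  d <- gm_wm_differentiation(img, gm, wm)
  expect_equal(d$abs_diff, 0.3)
  # equal differentiation -> 0 %
  expect_equal(gm_wm_differentiation(img, gm, wm, 0.3)$pct_vs_reference, 0)
  # 0.0297 vs reference 0.0213 -> +39.4 %
  pct <- gm_wm_differentiation(img * 0.0297 / 0.3, gm, wm,
                               0.0213)$pct_vs_reference
  expect_equal(round(pct, 1), 39.4)
  expect_error(gm_wm_differentiation(img, array(FALSE, dim(img)), wm),
               "empty")
})

test_that("image quality metrics match their definitions", {
  ref <- tiny_phantom(seed = 2L, side = 24L)$volume$data
  iq0 <- image_quality(ref, ref)
  expect_equal(iq0$nmse, 0)
  expect_equal(iq0$ssim, 1)
  expect_identical(iq0$psnr, Inf)

  # zero prediction has NMSE exactly 1
  expect_equal(image_quality(array(0, dim(ref)), ref)$nmse, 1)

  # reference range 1, MSE 0.01 -> PSNR 20 dB
  r2 <- array(rep(c(0, 1), each = 32), c(4, 4, 4))
  p2 <- r2 + 0.1
  expect_equal(image_quality(p2, r2)$psnr, 20, tolerance = 1e-9)

  # NMSE and PSNR are linked through the reference energy
  for (s in 1:20) {
    v <- with_seed_test(s, list(p = array(runif(6^3), c(6, 6, 6)),
                                r = array(runif(6^3), c(6, 6, 6))))
    iq <- image_quality(v$p, v$r)
    mse <- iq$nmse * sum(v$r^2) / length(v$r)
    expect_equal(iq$psnr, 10 * log10(diff(range(v$r))^2 / mse),
                 tolerance = 1e-9)
  }
})

test_that("ssim degrades with noise and is bounded", {
  ref <- tiny_phantom(seed = 2L, side = 24L)$volume$data
  s1 <- image_quality(ref + with_seed_test(1, array(rnorm(length(ref), 0, 0.02), dim(ref))), ref)$ssim
  s2 <- image_quality(ref + with_seed_test(1, array(rnorm(length(ref), 0, 0.2), dim(ref))), ref)$ssim
  expect_gt(s1, s2)
  expect_lte(s1, 1)
  expect_gte(s2, -1)
})

test_that("intensity segmentation recovers the phantom anatomy from clean images", {
  ph <- tiny_phantom(seed = 13L, side = 48L)
  prof <- mosr:::dice_profile(ph$volume, ph$labels)
  # the ground-truth image should segment its own anatomy nearly perfectly
  expect_gt(prof[["WM"]], 0.9)
  expect_gt(prof[["CSF"]], 0.9)
  expect_gt(prof[["GMC"]], 0.85)
  # a degraded, resampled input scores worse
  ulf <- resample(normalize_intensity(
    degrade(ph$volume, acquisition_spec(seed = 3))), 1)
  prof_ulf <- mosr:::dice_profile(mosr:::resample_to_grid(ulf, ph$volume)$data |>
                                    volume(spacing = ph$volume$spacing,
                                           affine = ph$volume$affine),
                                  ph$labels)
  expect_lt(mean(prof_ulf[GLOBAL <- c("CSF", "GMC", "WM", "GMS")]),
            mean(prof[GLOBAL]))
})

test_that("cohort evaluation assembles per-subject, concordance and test tables", {
  recs <- desk_records()[1:5]
  preds <- list(
    perfect = lapply(recs, `[[`, "target"),
    naive = lapply(recs, function(r) naive_fuse(r$inputs)),
    ulf = list())
  rep <- evaluate_cohort(recs, preds)
  expect_s3_class(rep$per_subject, "data.frame")
  expect_setequal(unique(rep$per_subject$method), c("perfect", "naive", "ulf"))
  # all four global tissue classes are reported
  expect_true(all(paste0("dice_", c("CSF", "GMC", "WM", "GMS")) %in%
                  rep$per_subject$metric))
  # the perfect method dominates naive fusion on NMSE
  nm <- function(m) mean(rep$per_subject$value[rep$per_subject$method == m &
                                               rep$per_subject$metric == "nmse"])
  expect_lt(nm("perfect"), nm("naive"))
  # concordance table covers each method and region
  expect_true(all(c("perfect", "naive", "ulf") %in% rep$concordance$method))
  # Wilcoxon ran per region on the paired Dice values (n = 5)
  expect_true(!is.null(rep$wilcoxon))
  expect_true(all(rep$wilcoxon$n == 5))
  # the ulf method is the average over the three orientations
  rec <- recs[[1]]
  per_orient <- vapply(rec$inputs, function(v) {
    al <- mosr:::resample_to_grid(resample(normalize_intensity(v), 1), rec$target)
    mosr:::dice_profile(al, rec$labelmap)[["WM"]]
  }, numeric(1))
  got <- rep$per_subject$value[rep$per_subject$subject_id == rec$subject_id &
                               rep$per_subject$method == "ulf" &
                               rep$per_subject$metric == "dice_WM"]
  expect_equal(got, mean(per_orient), tolerance = 1e-12)
})

test_that("report writing is stable and complete", {
  recs <- desk_records()[1:3]
  preds <- list(naive = lapply(recs, function(r) naive_fuse(r$inputs)))
  rep <- evaluate_cohort(recs, preds)
  td <- withr::local_tempdir()
  write_eval_report(rep, td)
  expect_true(all(file.exists(file.path(td, c("per_subject.tsv", "volumes.tsv",
                                              "concordance.tsv",
                                              "summary.txt")))))
  tab <- read.delim(file.path(td, "per_subject.tsv"))
  expect_identical(nrow(tab), nrow(rep$per_subject))
})
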