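# Domain types, NIfTI round-trips, resampling, normalization, pad/crop.

test_that("volume construction enforces its invariants", {
  expect_error(volume(matrix(1:4, 2)), "3D")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)), "positive")
  bad_aff <- diag(4); bad_aff[1, 1] <- 0
  expect_error(volume(array(1, c(2, 2, 2)), affine = bad_aff), "invertible")
  v <- volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1.5, 1.5, 5),
              orientation_tag = "axial")
  expect_equal(v$spacing, c(1.5, 1.5, 5))
  # trailing singleton 4th dimension is squeezed
  v4 <- volume(array(1, c(2, 2, 2, 1)))
  expect_length(dim(v4$data), 3)
})

test_that("label maps require non-negative integer ids and the core regions", {
  expect_error(label_map(array(-1L, c(2, 2, 2))), "non-negative")
  rt <- region_table_default()
  expect_setequal(rt$name[rt$tissue == "gm_subcortical"],
                  c("accumbens", "amygdala", "pallidum", "hippocampus",
                    "caudate", "putamen", "thalamus", "ventral_dc"))
  expect_true(all(c("CSF", "GMC", "WM") %in% rt$name))
})

test_that("write/read NIfTI round-trips data, spacing and affine", {
  td <- withr::local_tempdir()
  ph <- tiny_phantom()
  aff <- diag(c(1, 1, 1, 1)); aff[1:3, 4] <- c(-23.5, -23.5, -23.5)
  p <- file.path(td, "vol.nii.gz")
  write_volume(ph$volume, p)
  v2 <- read_volume(p)
  expect_equal(v2$data, ph$volume$data, tolerance = 1e-6)
  expect_equal(v2$spacing, ph$volume$spacing)
  expect_equal(v2$affine, ph$volume$affine, tolerance = 1e-6)

  # anisotropic spacing preserved exactly in the header
  an <- degrade(ph$volume, acquisition_spec(seed = 2))
  pa <- file.path(td, "aniso.nii.gz")
  write_volume(an, pa)
  a2 <- read_volume(pa)
  expect_identical(a2$spacing, c(1.5, 1.5, 5))
  expect_identical(a2$orientation_tag, "axial")

  # label map: integer datatype, ids identical after round-trip
  pl <- file.path(td, "lab.nii.gz")
  write_label_map(ph$labels, pl)
  l2 <- read_label_map(pl)
  expect_identical(l2$labels, ph$labels$labels)
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume("no/such/file.nii"), "not found")
  td <- withr::local_tempdir()
  img <- RNifti::asNifti(matrix(rnorm(64), 8, 8))
  p <- file.path(td, "flat.nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(read_volume(p), "3D")
})

test_that("resampling respects world extent and the floor rule", {
  # 32 voxels at 5 mm -> 160 voxels at 1 mm
  v <- volume(array(rnorm(4 * 4 * 32), c(4, 4, 32)), spacing = c(5, 5, 5))
  r <- resample(v, 1)
  expect_identical(dim(r$data)[3], 160L)
  expect_identical(dim(r$data)[1], 20L)
  # 160 mm at 1.5 mm -> 106 voxels
  expect_identical(mosr:::resample_dims(160L, 1, 1.5)[1], 106L)

  # identity resample leaves data unchanged
  ph <- tiny_phantom()
  same <- resample(ph$volume, 1)
  expect_equal(same$data, ph$volume$data, tolerance = 1e-12)

  # constant volume stays constant under any resampling
  cv <- volume(array(2.5, c(12, 12, 12)), spacing = c(2, 2, 2))
  rc <- resample(cv, 1.3)
  expect_equal(range(rc$data), c(2.5, 2.5))

  # degenerate extent errors
  expect_error(resample(cv, 100), "degenerate")

  # label maps refuse trilinear interpolation
  expect_error(resample(tiny_phantom()$labels, 2, interp = "trilinear"),
               "nearest")
})

test_that("resample then resample-back is near-lossless on a smooth phantom", {
  n <- 32
  ax <- seq(0, 2 * pi, length.out = n)
  sm <- array(0.5 + 0.3 * outer(outer(sin(ax), cos(ax)), sin(2 * ax)),
              c(n, n, n))
  v <- volume(sm, spacing = c(1, 1, 1))
  back <- resample(resample(v, 1.5), 1)
  common <- pmin(dim(back$data), dim(v$data))
  a <- back$data[1:common[1], 1:common[2], 1:common[3]]
  b <- v$data[1:common[1], 1:common[2], 1:common[3]]
  rms <- sqrt(mean((a - b)^2))
  expect_lt(rms, 0.05 * diff(range(v$data)))
})

test_that("intensity normalization maps brain voxels to [0,1] and keeps background", {
  dat <- array(0, c(4, 4, 4))
  dat[2:3, 2:3, 2:3] <- seq(10, 20, length.out = 8)
  v <- normalize_intensity(volume(dat))
  expect_equal(min(v$data[dat != 0]), 0)
  expect_equal(max(v$data), 1)
  expect_true(all(v$data[dat == 0] == 0))

  # an already-normalized realistic volume is (near-)unchanged: only the
  # single brain voxel that landed exactly on 0 merges with background
  ph <- tiny_phantom()$volume
  vn <- normalize_intensity(ph)
  vn2 <- normalize_intensity(vn)
  expect_lt(max(abs(vn2$data - vn$data)), 1e-3)

  expect_error(normalize_intensity(volume(array(0, c(3, 3, 3)))), "all-zero")
})

test_that("pad/crop to cube is centered, world-preserving and idempotent", {
  set.seed(9)
  dat <- array(rnorm(15 * 18 * 21), c(15, 18, 21))
  v <- volume(dat, spacing = c(1, 1, 1))
  c20 <- pad_or_crop_to_cube(v, 20)
  expect_identical(dim(c20$data), rep(20L, 3))
  # padding is centered: 15 -> 20 puts old voxel 1 at new index 3 (offset
  # trunc((15-20)/2) = -2)
  expect_equal(c20$data[3:17, 2:19, 1:20][, , 1], dat[, , 1])
  # cropping is centered: 21 -> 20 keeps voxels 1:20
  expect_equal(c20$data[3, 2, 1:20], dat[1, 1, 1:20])
  # idempotent at the target side
  again <- pad_or_crop_to_cube(c20, 20)
  expect_identical(again$data, c20$data)
  expect_identical(again$affine, c20$affine)
  # world coordinates of retained voxels are preserved: corner voxel of
  # the original maps to the same world position
  w_orig <- v$affine %*% c(0, 0, 0, 1)
  w_new <- c20$affine %*% c(2, 1, 0, 1)
  expect_equal(w_orig, w_new)
  # crop back restores the original where data survived (axis 3 lost its
  # last slice to the crop and comes back zero-padded)
  back <- crop_to_extent(c20, dim(dat))
  expect_equal(back$data[, , 1:20], dat[, , 1:20])
  expect_true(all(back$data[, , 21] == 0))
  expect_equal(back$affine, v$affine)
})

test_that("subject records validate their inputs", {
  ph <- tiny_phantom()
  an <- degrade(ph$volume, acquisition_spec(seed = 1))
  expect_error(subject_record(list()), "at least one")
  expect_error(subject_record(list(oblique = an)), "must be among")
  r <- subject_record(list(axial = an), target = ph$volume,
                      labelmap = ph$labels, age_group = "6mo", sex = "F",
                      subject_id = "s1")
  expect_s3_class(r, "mosr_subject")
})
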