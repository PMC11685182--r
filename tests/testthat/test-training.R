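# Fold construction, paired augmentation, optimization loop.

make_mock_cohort <- function(n, seed = 1L) {
  # lightweight records carrying only ids and strata (fold logic needs
  # nothing else)
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    structure(list(subject_id = sprintf("s%02d", i),
                   age_group = sample(c("3mo", "6mo"), 1, prob = c(16, 40)),
                   sex = sample(c("M", "F"), 1, prob = c(26, 30))),
              class = "mosr_subject")
  }))
}

test_that("56 subjects split 42/7/7 across 4 stratified folds", {
  recs <- make_mock_cohort(56L, seed = 7L)
  folds <- make_folds(recs, k = 4L, ratio = c(42L, 7L, 7L), seed = 3L)
  expect_length(folds, 4L)
  strata <- paste(vapply(recs, `[[`, character(1), "age_group"),
                  vapply(recs, `[[`, character(1), "sex"))
  names(strata) <- vapply(recs, `[[`, character(1), "subject_id")
  cohort_frac <- table(strata) / 56
  for (f in folds) {
    expect_length(f$train_ids, 42L)
    expect_length(f$val_ids, 7L)
    expect_length(f$test_ids, 7L)
    expect_length(intersect(f$val_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids),
                    names(strata))
    # stratification contract: each split deviates from cohort
    # proportions by at most one subject per stratum
    for (split in list(f$train_ids, f$val_ids, f$test_ids)) {
      got <- table(factor(strata[split], levels = names(cohort_frac)))
      expected <- length(split) * cohort_frac
      expect_true(all(abs(got - expected) <= 1),
                  label = sprintf("stratum deviation fold %d", f$fold_id))
    }
  }
  # val and test sets are disjoint across folds
  all_val <- unlist(lapply(folds, `[[`, "val_ids"))
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_identical(anyDuplicated(all_val), 0L)
  expect_identical(anyDuplicated(all_test), 0L)
  expect_length(intersect(all_val, all_test), 0L)

  # determinism
  folds2 <- make_folds(recs, k = 4L, ratio = c(42L, 7L, 7L), seed = 3L)
  expect_identical(folds, folds2)
  folds3 <- make_folds(recs, k = 4L, ratio = c(42L, 7L, 7L), seed = 4L)
  expect_false(identical(folds, folds3))
})

test_that("degenerate and infeasible fold requests are handled", {
  recs <- make_mock_cohort(10L)
  f <- make_folds(recs, k = 1L, ratio = c(10L, 0L, 0L), seed = 1L)
  expect_length(f[[1]]$train_ids, 10L)
  expect_length(f[[1]]$val_ids, 0L)
  expect_error(make_folds(recs, k = 4L, ratio = c(4L, 3L, 3L)), "infeasible")
  expect_error(make_folds(recs, k = 1L, ratio = c(5L, 1L, 1L)), "sum")
})

test_that("augmentation honours probability, identity limits and seeds", {
  rec <- desk_records()[[1]]
  pp <- preprocess_subject(rec, 32L)
  # aug_prob = 0: untouched
  cfg0 <- train_config(aug_prob = 0)
  a0 <- augment_pair(pp$x, pp$y, pp$labels, cfg0, step_seed = 5L)
  expect_identical(a0$x, pp$x)
  expect_false(a0$transformed)

  # identity-range affine: voxelwise change below 1e-6
  cfgI <- train_config(aug_prob = 1, aug_mode = "independent",
                       affine_params = list(max_rotation_deg = 0,
                                            max_translation_mm = 0,
                                            max_scale_frac = 0),
                       elastic_params = list(control_spacing = 8,
                                             max_displacement = 0))
  aI <- augment_pair(pp$x, pp$y, NULL, cfgI, step_seed = 6L)
  expect_lt(max(abs(aI$x - pp$x)), 1e-6)
  expect_lt(max(abs(aI$y - pp$y)), 1e-6)

  # determinism under step seed
  cfg <- desk_train_config()
  cfg$aug_prob <- 1
  a1 <- augment_pair(pp$x, pp$y, pp$labels, cfg, step_seed = 11L)
  a2 <- augment_pair(pp$x, pp$y, pp$labels, cfg, step_seed = 11L)
  expect_identical(a1$x, a2$x)
  expect_identical(a1$labels, a2$labels)
  a3 <- augment_pair(pp$x, pp$y, pp$labels, cfg, step_seed = 12L)
  expect_false(identical(a1$x, a3$x))
})

test_that("augmentation is rigidly paired: no relative motion, labels track", {
  rec <- desk_records()[[2]]
  pp <- preprocess_subject(rec, 32L)
  cfg <- train_config(aug_prob = 1, aug_mode = "independent",
                      affine_params = list(max_rotation_deg = 5,
                                           max_translation_mm = 2,
                                           max_scale_frac = 0.03),
                      elastic_params = list(control_spacing = 8,
                                            max_displacement = 0))
  base_nmse <- vapply(1:3, function(c)
    sum((pp$x[, , , c] - pp$y)^2) / sum(pp$y^2), numeric(1))
  a <- augment_pair(pp$x, pp$y, pp$labels, cfg, step_seed = 21L)
  aug_nmse <- vapply(1:3, function(c)
    sum((a$x[, , , c] - a$y)^2) / sum(a$y^2), numeric(1))
  expect_true(all(aug_nmse < 2 * base_nmse))

  # dual-path check: transforming a binary mask as an image and
  # thresholding agrees with the nearest-neighbour label path
  wm_mask <- (pp$labels == 3L) + 0
  tf <- with_seed_test(21L, mosr:::sample_transform(32L, cfg))
  coords <- mosr:::transform_coords(tf, 32L)
  soft <- mosr:::apply_transform_array(wm_mask, coords) > 0.5
  hard <- a$labels == 3L
  d <- 2 * sum(soft & hard) / (sum(soft) + sum(hard))
  expect_gt(d, 0.95)
})

test_that("a desk model overfits a single subject", {
  recs <- make_dataset(1L, phantom_config(side_mm = 16L, seed = 31L))
  model <- build_mo_unet(mo_unet_config(base_features = 8L, cube_side = 16L),
                         seed = 2L)
  fx <- feature_extractor(seed = 2L)
  split <- list(train_ids = recs[[1]]$subject_id, val_ids = character(0))
  cfg <- desk_train_config(epochs = 200L, aug_prob = 0, seed = 5L)
  fit <- train_mo_unet(model, recs, split, cfg, loss_config(seed = 5L), fx)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.5 * h$train_loss[1])
})

test_that("training is deterministic and checkpoints on best validation", {
  recs <- make_dataset(3L, phantom_config(side_mm = 16L, seed = 41L))
  split <- list(train_ids = c("sub-001", "sub-002"), val_ids = "sub-003")
  cfg <- desk_train_config(epochs = 4L, seed = 9L)
  run <- function() {
    model <- build_mo_unet(mo_unet_config(base_features = 8L, cube_side = 16L),
                           seed = 3L)
    train_mo_unet(model, recs, split, cfg, loss_config(seed = 9L),
                  feature_extractor(seed = 3L))
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_identical(f1$model$params, f2$model$params)
  # best checkpoint no worse than the first validated epoch
  v <- f1$history$val_loss
  expect_lte(f1$best_val, v[!is.na(v)][1])
  # training decreased the loss
  expect_lt(f1$history$train_loss[4], f1$history$train_loss[1])
})

test_that("training rejects records without targets", {
  recs <- make_dataset(1L, phantom_config(side_mm = 16L, seed = 51L))
  recs[[1]]$target <- NULL
  model <- build_mo_unet(mo_unet_config(base_features = 8L, cube_side = 16L),
                         seed = 1L)
  expect_error(train_mo_unet(model, recs,
                             list(train_ids = recs[[1]]$subject_id),
                             desk_train_config(epochs = 1L),
                             loss_config(), tiny_fx()),
               "target")
})

test_that("the trained desk model generalizes better than single inputs", {
  fit <- desk_trained()
  test_recs <- fold_records(desk_records(), desk_fold()$test_ids)
  wins <- vapply(test_recs, function(rec) {
    pred <- super_resolve(fit$model, rec$inputs)
    nmse_vs(pred, rec$target) < min(input_nmse(rec))
  }, logical(1))
  expect_gte(sum(wins), 4L)
})
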