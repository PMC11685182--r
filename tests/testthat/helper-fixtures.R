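# Shared fixtures. Everything is generated in code; expensive objects
# (the small phantom cohort and the desk-scale trained model) are built
# once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# seed an expression locally without disturbing the session RNG
with_seed_test <- function(seed, expr) mosr:::with_seed(as.integer(seed), expr)

tiny_phantom <- function(seed = 3L, side = 48L) {
  memo(sprintf("phantom_%d_%d", seed, side),
       make_phantom(phantom_config(side_mm = side, seed = seed)))
}

# 12-subject desk cohort at 32^3 (the study-condition cohort for the
# scaled-down efficacy checks)
desk_records <- function() {
  memo("desk_records", {
    seeds <- seed_streams(1L, 4L, c("data", "weights", "train", "fold"))
    make_dataset(12L, phantom_config(side_mm = 32L, seed = seeds[["data"]]))
  })
}

desk_fold <- function() {
  memo("desk_fold", {
    seeds <- seed_streams(1L, 4L, c("data", "weights", "train", "fold"))
    make_folds(desk_records(), k = 1L, ratio = c(7L, 0L, 5L),
               seed = seeds[["fold"]])[[1]]
  })
}

# Desk-scale trained model under fixed seeds: 7 training subjects,
# 20 epochs (140 optimizer steps). Shared by the training-properties,
# inference and acceptance tests so the cohort is trained exactly once
# per test session.
desk_trained <- function() {
  memo("desk_trained", {
    seeds <- seed_streams(1L, 4L, c("data", "weights", "train", "fold"))
    model <- build_mo_unet(mo_unet_config(base_features = 8L, cube_side = 32L),
                           seed = seeds[["weights"]])
    fx <- feature_extractor(seed = seeds[["weights"]])
    train_mo_unet(model, desk_records(), desk_fold(),
                  desk_train_config(epochs = 20L, seed = seeds[["train"]]),
                  loss_config(seed = seeds[["train"]]), fx)
  })
}

tiny_fx <- function(seed = 5L) {
  memo(sprintf("fx_%d", seed),
       feature_extractor(n_layers = 3L, widths = c(4L, 6L, 6L),
                         strides = c(2L, 2L, 1L), seed = seed))
}

# NMSE of an image against a reference volume, after alignment to the
# reference grid (used throughout the efficacy checks).
nmse_vs <- function(img, ref) {
  image_quality(mosr:::resample_to_grid(img, ref), ref)$nmse
}

# NMSE of each raw input after 1 mm resampling, against the target.
input_nmse <- function(rec) {
  vapply(rec$inputs, function(v)
    nmse_vs(resample(normalize_intensity(v), 1), rec$target), numeric(1))
}
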