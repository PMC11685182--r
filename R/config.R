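# YAML configuration: one nested bundle with the reference protocol's
# hyperparameters pre-filled. Unknown keys are rejected with their full
# key path, so typos (`lamda`) fail loudly.

#' Default configuration bundle
#'
#' Reference-protocol defaults: learning rate 1e-4, batch size 1,
#' lambda = 100, 6 loss slices, 160-voxel cube, 64 base features,
#' augmentation probability 0.5.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    phantom = list(side_mm = 64L, iso_mm = 1, age_mode = "6mo",
                   gm_wm_contrast = NULL, n_subcortical = 8L,
                   deform_amp = 0.75, texture_amp = 0.02),
    acquisition = list(in_plane_mm = 1.5, slice_mm = 5, noise_sigma = 0.05,
                       bias_amplitude = 0.2, contrast_gamma = 0.7),
    model = list(in_channels = 3L, out_channels = 1L, n_levels = 3L,
                 base_features = 64L, norm_groups = 8L, cube_side = 160L,
                 n_convs_per_block = 2L),
    loss = list(lambda_l2 = 100, n_slices = 6L, feature_layers = 5L,
                slice_axes_policy = "balanced", central_frac = 0.8,
                extractor = "random"),
    train = list(lr = 1e-4, epochs = 10L, batch_size = 1L, aug_prob = 0.5,
                 aug_mode = "independent",
                 affine = list(max_rotation_deg = 10, max_translation_mm = 4,
                               max_scale_frac = 0.1),
                 elastic = list(control_spacing = 8, max_displacement = 2),
                 val_every = 1L),
    evaluate = list(alpha = 0.05),
    seed = 1L)
}

check_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref))
      stop_mosr("unknown configuration key: '%s'", full)
    if (is.list(ref[[k]]) && !is.null(cfg[[k]]) && is.list(cfg[[k]]))
      check_keys(cfg[[k]], ref[[k]], full)
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[k] <- list(override[[k]])   # keeps explicit NULLs in place
    }
  }
  base
}

#' Load and validate a YAML configuration
#'
#' Missing keys fall back to [default_config()]; unknown keys are
#' rejected with their key path. An empty file yields the full default
#' bundle.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param echo print the resolved configuration (YAML) to the console.
#' @return validated nested list.
#' @export
load_config <- function(path = NULL, echo = FALSE) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_mosr("config file not found: %s", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  ref <- default_config()
  check_keys(user, ref)
  cfg <- merge_config(ref, user)
  if (echo) cat(yaml::as.yaml(cfg))
  cfg
}

# Materialize typed configuration records from the bundle.
config_phantom <- function(cfg, seed = cfg$seed) {
  ph <- cfg$phantom
  phantom_config(side_mm = ph$side_mm, iso_mm = ph$iso_mm,
                 age_mode = ph$age_mode, gm_wm_contrast = ph$gm_wm_contrast,
                 n_subcortical = ph$n_subcortical, seed = seed,
                 deform_amp = ph$deform_amp, texture_amp = ph$texture_amp)
}

config_acquisition <- function(cfg, seed = cfg$seed) {
  aq <- cfg$acquisition
  acquisition_spec(in_plane_mm = aq$in_plane_mm, slice_mm = aq$slice_mm,
                   noise_sigma = aq$noise_sigma,
                   bias_amplitude = aq$bias_amplitude,
                   contrast_gamma = aq$contrast_gamma, seed = seed)
}

config_model <- function(cfg) do.call(mo_unet_config, cfg$model)

config_loss <- function(cfg, seed = cfg$seed) {
  lo <- cfg$loss
  loss_config(lambda_l2 = lo$lambda_l2, n_slices = lo$n_slices,
              feature_layers = lo$feature_layers,
              slice_axes_policy = lo$slice_axes_policy,
              central_frac = lo$central_frac, seed = seed)
}

config_train <- function(cfg, seed = cfg$seed) {
  tr <- cfg$train
  train_config(lr = tr$lr, epochs = tr$epochs, batch_size = tr$batch_size,
               aug_prob = tr$aug_prob, aug_mode = tr$aug_mode,
               affine_params = tr$affine, elastic_params = tr$elastic,
               seed = seed, val_every = tr$val_every)
}
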