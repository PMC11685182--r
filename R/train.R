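# Training loop: per step, preprocess (normalize -> resample to 1 mm
# isotropic -> pad to the canonical cube) -> paired augmentation ->
# forward -> composite loss -> Adam update. Validation loss is tracked
# every `val_every` epochs and the best-validation weights are retained.

CHANNEL_ORDER <- c("axial", "coronal", "sagittal")

#' Preprocess a subject onto the canonical training cube
#'
#' Each input is min-max normalized, resampled to `iso_mm` isotropic and
#' padded/cropped to the cube; channels are stacked in the fixed
#' (axial, coronal, sagittal) order. Missing orientations are filled by
#' cloning the highest-priority available scan (axial > sagittal >
#' coronal), mirroring the reduced-input inference scheme.
#'
#' @param rec a [subject_record()].
#' @param cube_side canonical cube side in voxels.
#' @param iso_mm target isotropic spacing.
#' @return list `(x, y, labels, ref, grid)`: input array `(side^3, 3)`,
#'   target array (or NULL), label array (or NULL), the reference
#'   (resampled highest-priority input) volume used for crop-back, and the
#'   canonical cube grid (an `mosr_volume` carrying its affine).
#' @export
preprocess_subject <- function(rec, cube_side, iso_mm = 1) {
  filled <- fill_channels(rec$inputs)
  ref_name <- intersect(c("axial", "sagittal", "coronal"), names(rec$inputs))[1]
  ref <- resample(normalize_intensity(rec$inputs[[ref_name]]), iso_mm)
  # the canonical cube grid: the (padded) target grid when a target is
  # present, else the padded reference-input grid. Every channel is then
  # sampled onto this one grid through its affine, so all channels and
  # the target are voxel-aligned by world coordinates (count-centered
  # padding of each channel separately would shift each orientation by
  # its own slab-axis remainder).
  if (!is.null(rec$target)) {
    tv <- rec$target
    if (max(tv$data) > 1 + 1e-6 || min(tv$data) < 0) tv <- normalize_intensity(tv)
    grid <- pad_or_crop_to_cube(resample(tv, iso_mm), cube_side)
    y <- grid$data
  } else {
    grid <- pad_or_crop_to_cube(ref, cube_side)
    y <- NULL
  }
  x <- array(0, c(rep(cube_side, 3L), 3L))
  for (i in seq_along(CHANNEL_ORDER)) {
    v <- resample(normalize_intensity(filled[[CHANNEL_ORDER[i]]]), iso_mm)
    x[, , , i] <- resample_to_grid(v, grid)$data
  }
  labels <- NULL
  if (!is.null(rec$labelmap)) {
    lm_iso <- resample(rec$labelmap, iso_mm)
    labels <- array(as.integer(resample_to_grid(lm_iso, grid,
                                                interp = "nearest")$data),
                    rep(cube_side, 3L))
  }
  list(x = x, y = y, labels = labels, ref = ref, grid = grid)
}

# Fill missing orientation slots by cloning the highest-priority
# available scan, priority axial > sagittal > coronal (the scanning-
# protocol order), keeping the fixed channel-slot convention.
fill_channels <- function(inputs) {
  if (length(inputs) < 1L) stop_mosr("at least one input volume is required")
  priority <- c("axial", "sagittal", "coronal")
  avail <- intersect(priority, names(inputs))
  if (length(avail) == 0L) stop_mosr("inputs must be keyed by orientation")
  clone_src <- inputs[[avail[1]]]
  out <- list()
  for (o in CHANNEL_ORDER) out[[o]] <- inputs[[o]] %||% clone_src
  out
}

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      g <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[f]] / bc1
      vhat <- state$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train the multi-orientation U-Net
#'
#' @param model an `mosr_model` from [build_mo_unet()].
#' @param records list of [subject_record()]s (each training record needs
#'   all three inputs and a target).
#' @param split list with `train_ids` and optional `val_ids` (e.g. one
#'   fold from [make_folds()]).
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param fx a [feature_extractor()].
#' @param verbose print per-epoch progress.
#' @return list `(model, final_model, history, best_val)`: `model` holds
#'   the best-validation weights (the final weights when no validation
#'   set is given), `history` is a data.frame with per-epoch mean train
#'   loss and periodic validation loss.
#' @export
train_mo_unet <- function(model, records, split, cfg = desk_train_config(),
                          loss_cfg = loss_config(), fx = feature_extractor(),
                          verbose = FALSE) {
  side <- model$cfg$cube_side
  tr <- fold_records(records, split$train_ids)
  va <- if (length(split$val_ids %||% character(0)) > 0)
    fold_records(records, split$val_ids)
  for (r in tr) {
    if (is.null(r$target)) stop_mosr("training record %s has no target", r$subject_id)
    if (length(r$inputs) < 3L)
      stop_mosr("training record %s needs all three orientations", r$subject_id)
  }
  ptr <- lapply(tr, preprocess_subject, cube_side = side)
  pva <- if (!is.null(va)) lapply(va, preprocess_subject, cube_side = side)

  seeds <- seed_streams(cfg$seed, 2L + cfg$epochs,
                        c("order", "val", paste0("epoch", seq_len(cfg$epochs))))
  params <- model$params
  # intercept warm start: shift the head bias so the initial prediction
  # matches the mean target intensity. Without it the scalar bias must
  # crawl to the target mean at ~lr per step, and an unlucky head
  # initialization can spend most of a short budget on a constant-output
  # plateau.
  m0 <- structure(list(cfg = model$cfg, params = params), class = "mosr_model")
  mean_pred <- mean(mo_unet_forward(m0, ptr[[1]]$x))
  mean_targ <- mean(vapply(ptr, function(s) mean(s$y), numeric(1)))
  params$head$b <- params$head$b + (mean_targ - mean_pred)
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_lpips = numeric(0), train_l2 = numeric(0),
                     val_loss = numeric(0))
  best <- list(val = Inf, params = params)

  eval_val <- function(params) {
    mm <- structure(list(cfg = model$cfg, params = params), class = "mosr_model")
    mean(vapply(pva, function(s) {
      out <- mo_unet_forward(mm, s$x)
      total_loss(array(out, dim(out)[1:3]), s$y, loss_cfg, fx,
                 seed = seeds[["val"]])$total
    }, numeric(1)))
  }

  for (ep in seq_len(cfg$epochs)) {
    ep_seed <- seeds[[sprintf("epoch%d", ep)]]
    order_idx <- with_seed(ep_seed, sample(seq_along(ptr)))
    step_seeds <- seed_streams(ep_seed, 2L * length(ptr))
    losses <- lpips_v <- l2_v <- numeric(length(ptr))
    for (j in seq_along(order_idx)) {
      s <- ptr[[order_idx[j]]]
      aug <- augment_pair(s$x, s$y, NULL, cfg, step_seeds[2 * j - 1])
      mm <- structure(list(cfg = model$cfg, params = params), class = "mosr_model")
      fwd <- mo_unet_forward(mm, aug$x, cache = TRUE)
      pred <- array(fwd$out, dim(fwd$out)[1:3])
      lg <- total_loss_grad(pred, aug$y, loss_cfg, fx, seed = step_seeds[2 * j])
      if (!is.finite(lg$total))
        stop_mosr("non-finite loss at epoch %d step %d (subject %s)",
                  ep, j, tr[[order_idx[j]]]$subject_id)
      losses[j] <- lg$total; lpips_v[j] <- lg$lpips; l2_v[j] <- lg$l2
      dout <- array(lg$dx, c(dim(lg$dx), 1L))
      bw <- mo_unet_backward(mm, fwd$cache, dout)
      upd <- adam_step(params, bw$grads, state, cfg$lr)
      params <- upd$params; state <- upd$state
    }
    vloss <- NA_real_
    if (!is.null(pva) && (ep %% cfg$val_every == 0L || ep == cfg$epochs)) {
      vloss <- eval_val(params)
      if (vloss < best$val) best <- list(val = vloss, params = params)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   train_lpips = mean(lpips_v),
                                   train_l2 = mean(l2_v), val_loss = vloss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", ep, mean(losses),
                      ifelse(is.na(vloss), "-", sprintf("%.5f", vloss))))
  }
  final <- structure(list(cfg = model$cfg, params = params), class = "mosr_model")
  best_model <- if (is.finite(best$val))
    structure(list(cfg = model$cfg, params = best$params), class = "mosr_model")
  else final
  list(model = best_model, final_model = final, history = hist,
       best_val = if (is.finite(best$val)) best$val else NA_real_)
}
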