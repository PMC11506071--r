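# Generator/discriminator co-optimisation.
#
# The encoder plus its affine heads form the discriminator; the skip residual
# units, attention gates and decoder form the generator. The two learn side
# by side: with the default (1, 1) frequency pair both update on every batch
# (the generator first; the discriminator reuses its synthesis as the
# adversarial fake), and unequal frequencies run the busier optimiser every
# batch and the other on a proportional quota of batches. After every
# discriminator update all discriminator parameters are clamped to [-c, c];
# the generator is never clipped. Validation MSE drives the checkpoint
# policy: `last.ckpt` is always overwritten, and the three best epochs (by
# validation MSE) are kept side by side.

#' Training configuration
#'
#' @param epochs Number of epochs (`>= 1`).
#' @param batch_size Samples per optimisation step.
#' @param lr_gen,lr_disc Learning rates for the two optimisers.
#' @param optimizer `"rmsprop"` (canonical for weight-clipped adversarial
#'   training) or `"adam"`.
#' @param frequency `c(gen, disc)` execution-frequency pair; `c(1, 1)`
#'   updates both on every batch, `c(1, 5)` gives five discriminator
#'   executions per generator execution.
#' @param noise_sigma Std dev of the Gaussian noise mixed into
#'   discriminator "fake" inputs (on the `[0, 1]` image scale).
#' @param affine_bounds `c(max_rotation_deg, max_translate_frac,
#'   max_shear_deg)` for the latent-consistency distortion.
#' @param seed Master seed for shuffling, noise and distortions.
#' @param checkpoint_dir,log_dir Output directories (created if needed).
#' @param keep_best_k Number of best checkpoints retained (default 3).
#' @param grid_samples Number of validation samples in the per-epoch
#'   progress grid (0 disables the grid).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 4L,
                         lr_gen = 5e-5, lr_disc = 5e-5,
                         optimizer = c("rmsprop", "adam"),
                         frequency = c(1L, 1L),
                         noise_sigma = 0.5,
                         affine_bounds = c(15, 0.1, 5),
                         seed = 1L,
                         checkpoint_dir = file.path(tempdir(), "ckpt"),
                         log_dir = file.path(tempdir(), "logs"),
                         keep_best_k = 3L,
                         grid_samples = 4L) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1, batch_size >= 1, all(frequency >= 1))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_gen = lr_gen, lr_disc = lr_disc, optimizer = optimizer,
                 frequency = as.integer(frequency), noise_sigma = noise_sigma,
                 affine_bounds = affine_bounds, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, log_dir = log_dir,
                 keep_best_k = as.integer(keep_best_k),
                 grid_samples = as.integer(grid_samples)),
            class = "train_config")
}

# ---- optimiser --------------------------------------------------------------

optim_state_new <- function() new.env(parent = emptyenv())

# A small epsilon matters here: discriminator gradients are tiny in the
# weight-clipped regime, and a larger epsilon would damp their adaptive
# normalisation to nothing.
optim_update <- function(model, grads, names, state, lr, optimizer,
                         rho = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (optimizer == "rmsprop") {
      v <- state[[nm]]
      if (is.null(v)) v <- g * 0
      v <- rho * v + (1 - rho) * g * g
      state[[nm]] <- v
      model$params[[nm]][] <- model$params[[nm]] - lr * g / (sqrt(v) + eps)
    } else {
      st <- state[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0, t = 0)
      st$t <- st$t + 1
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[nm]] <- st
      mhat <- st$m / (1 - beta1^st$t)
      vhat <- st$v / (1 - beta2^st$t)
      model$params[[nm]][] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  model
}

# Read accumulated gradients off wrapped leaves (losses are already batch
# means, so no further normalisation is applied).
collect_grads <- function(P, names) {
  out <- list()
  for (nm in names) if (!is.null(P[[nm]]$g)) out[[nm]] <- P[[nm]]$g
  out
}

# Stack sample images (or masks) into an (H, W, 3, N) batch array.
stack_batch <- function(batch, field = "image") {
  d <- dim(batch[[1]][[field]])
  x <- array(0, dim = c(d, length(batch)))
  for (i in seq_along(batch)) x[, , , i] <- batch[[i]][[field]]
  x
}

# Auxiliary class target for one sample: its dominant lesion class, or the
# dedicated dummy class for lesion-free images.
aux_target <- function(sample, cfg, eps) {
  k <- cfg$aux_output_nodes
  one <- rep(0, k)
  cls <- if (isTRUE(sample$is_dummy) || length(sample$present_classes) == 0L)
    cfg$num_lesion_classes else sample$primary_class
  one[cls + 1L] <- 1
  smooth_labels(one, eps)
}

dominant_class <- function(sample) {
  if (length(sample$present_classes) == 0L) return(NA_integer_)
  ids <- classify_image(sample$mask)
  counts <- table(factor(ids[ids >= 0], levels = sample$present_classes))
  as.integer(names(counts)[which.max(counts)])
}

#' One discriminator update
#'
#' Per batch sample the encoder sees the clean image (validity target 1.0,
#' label-smoothed auxiliary class target), a Gaussian-noise-mixed copy
#' (validity target 0.0), an affine-distorted copy (latent consistency), and
#' the generator's current segmentation next to the real image for the
#' adversarial head. Discriminator weights are clipped to `[-c, c]`
#' afterwards.
#'
#' @param model A `larynet_model`.
#' @param batch List of samples (each with `image`, `mask`, `is_dummy`,
#'   `primary_class`).
#' @param tcfg A [train_config()].
#' @param weights A [loss_weights()].
#' @param state Optimiser state environment (from `optim_state_new()`).
#' @param epoch Zero-based epoch (unused by the discriminator terms; kept
#'   for a symmetric interface).
#' @return List with the updated `model` and a `record` of loss components.
#' @export
discriminator_step <- function(model, batch, tcfg = train_config(),
                               weights = loss_weights(), state = optim_state_new(),
                               epoch = 0, .fake_override = NULL) {
  if (length(batch) == 0L) stop("empty batch")
  P <- wrap_params(model)
  cfg <- model$config
  x <- stack_batch(batch, "image")
  xn <- mix_gaussian_noise(x, tcfg$noise_sigma)
  xa <- x
  for (i in seq_along(batch))
    xa[, , , i] <- apply_random_affine(batch[[i]]$image, tcfg$affine_bounds[1],
                                       tcfg$affine_bounds[2], tcfg$affine_bounds[3])
  enc <- encoder_graph(P, ag_const(x), cfg)
  enc_n <- encoder_graph(P, ag_const(xn), cfg)
  enc_a <- encoder_graph(P, ag_const(xa), cfg)
  l_val <- ag_scale(ag_add(ag_bce_logits(enc$validity, 1),
                           ag_bce_logits(enc_n$validity, 0)), 0.5)
  targets <- vapply(batch, aux_target, numeric(cfg$aux_output_nodes),
                    cfg, weights$smoothing_eps)
  l_aux <- ag_softmax_ce(enc$aux, targets)
  l_con <- ag_mse(enc$latent, enc_a$latent)
  # adversarial: real photograph vs the generator's current synthesis
  # (reuses the generator step's output when available; always detached)
  fake <- if (is.null(.fake_override)) decoder_graph(P, enc, cfg)$v
          else .fake_override
  enc_f <- encoder_graph(P, ag_const(fake), cfg)
  if (weights$wasserstein) {
    l_adv <- ag_sub(ag_mean(enc_f$adv), ag_mean(enc$adv))
  } else {
    l_adv <- ag_scale(ag_add(ag_bce_logits(enc$adv, 1),
                             ag_bce_logits(enc_f$adv, 0)), 0.5)
  }
  total <- ag_add(ag_add(ag_scale(l_val, weights$w_validity),
                         ag_scale(l_aux, weights$w_auxiliary)),
                  ag_add(ag_scale(l_con, weights$w_consistency),
                         ag_scale(l_adv, weights$w_adversarial)))
  ag_backward(total)
  rec <- c(validity = l_val$v, auxiliary = l_aux$v, consistency = l_con$v,
           adversarial = l_adv$v)
  grads <- collect_grads(P, model$groups$discriminator)
  model <- optim_update(model, grads, model$groups$discriminator, state,
                        tcfg$lr_disc, tcfg$optimizer)
  model <- clip_weights(model, weights$clip_value)
  rec["total"] <- weights$w_validity * rec[["validity"]] +
    weights$w_auxiliary * rec[["auxiliary"]] +
    weights$w_consistency * rec[["consistency"]] +
    weights$w_adversarial * rec[["adversarial"]]
  list(model = model, record = as.list(rec))
}

#' One generator update
#'
#' Reconstruction (epoch-scheduled MSE/SSIM blend against the color-coded
#' ground truth) plus the adversarial term; decoder-side parameters only, no
#' clipping.
#'
#' @inheritParams discriminator_step
#' @param .pred_override Test hook: use this array instead of the decoder
#'   output inside the reconstruction term.
#' @return List with the updated `model` and a `record` holding `mse`,
#'   `ssim`, `adversarial`, `reconstruction` and `total`.
#' @export
generator_step <- function(model, batch, tcfg = train_config(),
                           weights = loss_weights(), state = optim_state_new(),
                           epoch = 0, .pred_override = NULL) {
  if (length(batch) == 0L) stop("empty batch")
  P <- wrap_params(model)
  cfg <- model$config
  x <- stack_batch(batch, "image")
  gt <- ag_const(stack_batch(batch, "mask"))
  enc <- encoder_graph(P, ag_const(x), cfg)
  seg <- decoder_graph(P, enc, cfg)
  pred <- if (is.null(.pred_override)) seg else ag_const(.pred_override)
  l_mse <- ag_mse(pred, gt)
  ssim_v <- ag_ssim(pred, gt)
  l_rec <- ag_reconstruction(pred, gt, epoch, weights, ssim_node = ssim_v)
  if (weights$w_adversarial > 0) {
    enc_f <- encoder_graph(P, seg, cfg)
    l_adv <- if (weights$wasserstein) ag_scale(ag_mean(enc_f$adv), -1)
             else ag_bce_logits(enc_f$adv, 1)
  } else l_adv <- ag_const(0)
  total <- ag_add(ag_scale(l_rec, weights$w_reconstruction),
                  ag_scale(l_adv, weights$w_adversarial))
  ag_backward(total)
  rec <- c(mse = l_mse$v, ssim = ssim_v$v, adversarial = l_adv$v,
           reconstruction = l_rec$v)
  seg_value <- seg$v
  grads <- collect_grads(P, model$groups$generator)
  model <- optim_update(model, grads, model$groups$generator, state,
                        tcfg$lr_gen, tcfg$optimizer)
  rec["total"] <- weights$w_reconstruction * rec[["reconstruction"]] +
    weights$w_adversarial * rec[["adversarial"]]
  list(model = model, record = as.list(rec), seg = seg_value)
}

# ---- checkpoint policy ------------------------------------------------------

ckpt_best_path <- function(dir, epoch, metric)
  file.path(dir, sprintf("best-epoch%03d-mse%.6f.ckpt", epoch, metric))

# Keep `last.ckpt` plus at most k best files, sorted by the metric embedded
# in their names.
apply_checkpoint_policy <- function(model, dir, epoch, metric, k = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(model, file.path(dir, "last.ckpt"), epoch, metric)
  best <- list.files(dir, pattern = "^best-epoch", full.names = TRUE)
  metrics <- as.numeric(sub(".*-mse([0-9.]+)\\.ckpt$", "\\1", best))
  if (length(best) < k || metric < max(metrics)) {
    save_checkpoint(model, ckpt_best_path(dir, epoch, metric), epoch, metric)
    best <- list.files(dir, pattern = "^best-epoch", full.names = TRUE)
    metrics <- as.numeric(sub(".*-mse([0-9.]+)\\.ckpt$", "\\1", best))
    if (length(best) > k) file.remove(best[order(metrics)][-seq_len(k)])
  }
  invisible(NULL)
}

# ---- dataset plumbing -------------------------------------------------------

# Load a generated dataset from its manifest into memory, adding the
# dominant-class annotation the auxiliary loss needs.
load_manifest_samples <- function(data_dir, split = NULL) {
  manifest <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    s <- list(image = png::readPNG(file.path(data_dir, row$image_path)),
              mask = png::readPNG(file.path(data_dir, row$mask_path)),
              is_dummy = isTRUE(row$is_dummy) | row$is_dummy == "TRUE",
              present_classes = if (nzchar(as.character(row$classes)))
                as.integer(strsplit(as.character(row$classes), ";")[[1]])
              else integer(0),
              path = row$image_path)
    s$primary_class <- if (s$is_dummy) NA_integer_ else dominant_class(s)
    s
  })
}

prepare_samples <- function(samples) {
  lapply(samples, function(s) {
    if (is.null(s$primary_class))
      s$primary_class <- if (isTRUE(s$is_dummy)) NA_integer_ else dominant_class(s)
    if (is.null(s$path)) s$path <- sprintf("sample_%04d", s$index %||% 0L)
    s
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validation_metrics <- function(model, val_samples, tcfg, chunk = 8L) {
  P <- wrap_params(model)
  cfg <- model$config
  mses <- vclean <- vnoise <- numeric(length(val_samples))
  for (start in seq(1L, length(val_samples), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(val_samples))
    x <- stack_batch(val_samples[idx], "image")
    gt <- stack_batch(val_samples[idx], "mask")
    enc <- encoder_graph(P, ag_const(x), cfg)
    seg <- decoder_graph(P, enc, cfg)$v
    mses[idx] <- colMeans(matrix((seg - gt)^2, ncol = length(idx)))
    vclean[idx] <- stable_sigmoid(as.numeric(enc$validity$v))
    xn <- mix_gaussian_noise(x, tcfg$noise_sigma)
    enc_n <- encoder_graph(P, ag_const(xn), cfg)
    vnoise[idx] <- stable_sigmoid(as.numeric(enc_n$validity$v))
  }
  list(mse = mean(mses), validity_clean = mean(vclean),
       validity_noise = mean(vnoise), validity_clean_sd = stats::sd(vclean))
}

# [ground truth | segmentation | synthesis overlay | input] progress grid.
write_epoch_grid <- function(model, samples, path) {
  rows <- lapply(samples, function(s) {
    seg <- model_forward(model, s$image)$seg_image
    overlay <- 0.5 * s$image + 0.5 * seg
    panels <- list(s$mask, seg, overlay, s$image)
    sapply(1:3, function(ch) do.call(cbind, lapply(panels, function(p) p[, , ch])),
           simplify = "array")
  })
  grid <- sapply(1:3, function(ch)
    do.call(rbind, lapply(rows, function(r) r[, , ch])), simplify = "array")
  png::writePNG(pmin(pmax(grid, 0), 1), path)
  invisible(path)
}

#' Fit the adversarial segmentation model
#'
#' Runs generator and discriminator updates side by side per the frequency
#' pair (both on every batch by default),
#' evaluates MSE against the color-coded ground truth on the held-out split
#' after every epoch, applies the checkpoint policy (overwritten
#' `last.ckpt` + three best by validation MSE), logs per-step and per-epoch
#' scalars (including `mse_loss` and `validity`) to CSV, and writes a
#' per-epoch progress grid. Fully reproducible for a fixed seed.
#'
#' @param tcfg A [train_config()].
#' @param data Either a directory containing a `manifest.csv` produced by
#'   [generate_dataset()], or a list with `train` and `val` lists of samples.
#' @param model Optional prebuilt `larynet_model`; by default one is built
#'   from `model_cfg` with the training seed.
#' @param model_cfg A [model_config()] used when `model` is `NULL`.
#' @param weights A [loss_weights()]; its schedule horizon defaults to the
#'   configured epochs.
#' @return A list of class `larynet_history`: `history` (one row per epoch),
#'   `steps` (one row per optimisation step), the trained `model`, and the
#'   checkpoint directory.
#' @export
fit <- function(tcfg = train_config(), data, model = NULL,
                model_cfg = model_config(), weights = NULL) {
  if (is.null(weights)) weights <- loss_weights(total_epochs = tcfg$epochs)
  if (is.character(data)) {
    train <- load_manifest_samples(data, "train")
    val <- load_manifest_samples(data, "test")
  } else {
    train <- prepare_samples(data$train)
    val <- prepare_samples(data$val)
  }
  if (length(train) == 0L) stop("no training samples")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tcfg$seed)
  if (is.null(model)) model <- build_model(model_cfg, seed = tcfg$seed)
  dir.create(tcfg$log_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(tcfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  state_d <- optim_state_new(); state_g <- optim_state_new()
  # Quota scheduling: generator and discriminator learn side by side; with
  # frequencies (g, d) the busier optimiser runs every batch and the other
  # every (max/frequency)-th batch, so executions stay in the d:g ratio.
  fg <- tcfg$frequency[1]; fd <- tcfg$frequency[2]
  fmax <- max(fg, fd)
  pos <- 0L  # batch counter carried across epochs so the ratio holds globally
  quota_hit <- function(t, f) (floor((t + 1) * f / fmax) - floor(t * f / fmax)) >= 1
  epoch_rows <- vector("list", tcfg$epochs)
  step_rows <- list()
  result <- tryCatch({
    for (epoch in seq_len(tcfg$epochs) - 1L) {
      idx <- sample(length(train))
      nb <- max(1L, length(idx) %/% tcfg$batch_size)
      rec_d <- rec_g <- NULL; nd <- ng <- 0L
      for (b in seq_len(nb)) {
        take <- idx[((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size,
                                                          length(idx))]
        batch <- train[take]
        run_d <- quota_hit(pos, fd); run_g <- quota_hit(pos, fg)
        pos <- pos + 1L
        fake <- NULL
        if (run_g) {
          st <- generator_step(model, batch, tcfg, weights, state_g, epoch)
          model <- st$model; ng <- ng + 1L
          fake <- st$seg  # reused by the discriminator's adversarial term
          rec_g <- if (is.null(rec_g)) st$record
                   else Map(`+`, rec_g, st$record)
          step_rows[[length(step_rows) + 1L]] <-
            data.frame(epoch = epoch, step = b, role = "g",
                       term = names(st$record),
                       value = as.numeric(unlist(st$record)),
                       stringsAsFactors = FALSE)
        }
        if (run_d) {
          st <- discriminator_step(model, batch, tcfg, weights, state_d, epoch,
                                   .fake_override = fake)
          model <- st$model; nd <- nd + 1L
          rec_d <- if (is.null(rec_d)) st$record
                   else Map(`+`, rec_d, st$record)
          step_rows[[length(step_rows) + 1L]] <-
            data.frame(epoch = epoch, step = b, role = "d",
                       term = names(st$record),
                       value = as.numeric(unlist(st$record)),
                       stringsAsFactors = FALSE)
        }
      }
      vm <- validation_metrics(model, val, tcfg)
      apply_checkpoint_policy(model, tcfg$checkpoint_dir, epoch, vm$mse,
                              tcfg$keep_best_k)
      if (tcfg$grid_samples > 0 && length(val) > 0)
        write_epoch_grid(model, val[seq_len(min(tcfg$grid_samples, length(val)))],
                         file.path(tcfg$log_dir,
                                   sprintf("epoch%03d-grid.png", epoch)))
      epoch_rows[[epoch + 1L]] <- data.frame(
        epoch = epoch,
        disc_steps = nd, gen_steps = ng,
        disc_total = if (nd > 0) rec_d$total / nd else NA_real_,
        gen_total = if (ng > 0) rec_g$total / ng else NA_real_,
        gen_mse = if (ng > 0) rec_g$mse / ng else NA_real_,
        mse_loss = vm$mse,
        validity = vm$validity_clean,
        validity_noise = vm$validity_noise,
        validity_sd = vm$validity_clean_sd)
      message(sprintf(
        "epoch %d/%d  val mse_loss %.5f  validity %.6f (noise %.6f)",
        epoch + 1L, tcfg$epochs, vm$mse, vm$validity_clean, vm$validity_noise))
    }
    history <- do.call(rbind, epoch_rows)
    steps <- do.call(rbind, step_rows)
    utils::write.csv(history, file.path(tcfg$log_dir, "epochs.csv"),
                     row.names = FALSE)
    utils::write.csv(steps, file.path(tcfg$log_dir, "steps.csv"),
                     row.names = FALSE)
    structure(list(history = history, steps = steps, model = model,
                   checkpoint_dir = tcfg$checkpoint_dir), class = "larynet_history")
  }, error = function(e) {
    save_checkpoint(model, file.path(tcfg$checkpoint_dir, "last.ckpt"))
    stop("training aborted (state saved to last.ckpt): ",
         conditionMessage(e), call. = FALSE)
  })
  result
}
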