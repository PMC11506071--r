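# Training objectives.
#
# Reconstruction blends MSE with structural dissimilarity (1 - SSIM); the
# blend weight alpha starts at 1 (pure MSE) and decreases linearly over
# training so structural agreement gains weight as learning progresses.
# Classification targets are label-smoothed; real/noise "validity" targets
# and the adversarial real/synthetic target use numerically stable binary
# cross-entropy with logits. Discriminator parameters are clamped to
# [-c, c] after every discriminator update (WGAN-style weight clipping); the
# generator is never clipped.

#' Loss weights and schedules
#'
#' @param alpha_floor Final value of the MSE/SSIM blend weight alpha; alpha
#'   decreases linearly from 1 at epoch 0 to `alpha_floor` at `total_epochs`.
#' @param total_epochs Horizon of the alpha schedule.
#' @param smoothing_eps Label-smoothing mass redistributed uniformly.
#' @param clip_value WGAN clipping constant `c > 0`.
#' @param w_reconstruction,w_adversarial,w_auxiliary,w_validity,w_consistency
#'   Term weights in the generator/discriminator objectives.
#' @param wasserstein If `TRUE` the adversarial objective is the raw critic
#'   score difference (no sigmoid) instead of BCE-with-logits.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha_floor = 0.5, total_epochs = 15L,
                         smoothing_eps = 0.1, clip_value = 0.01,
                         w_reconstruction = 1, w_adversarial = 0.05,
                         w_auxiliary = 1, w_validity = 1, w_consistency = 1,
                         wasserstein = FALSE) {
  stopifnot(clip_value > 0, alpha_floor >= 0, alpha_floor <= 1,
            smoothing_eps >= 0, smoothing_eps < 1)
  structure(list(alpha_floor = alpha_floor, total_epochs = as.integer(total_epochs),
                 smoothing_eps = smoothing_eps, clip_value = clip_value,
                 w_reconstruction = w_reconstruction,
                 w_adversarial = w_adversarial, w_auxiliary = w_auxiliary,
                 w_validity = w_validity, w_consistency = w_consistency,
                 wasserstein = isTRUE(wasserstein)),
            class = "loss_weights")
}

#' MSE/SSIM blend weight at a given epoch
#'
#' Linear from 1.0 at epoch 0 down to `alpha_floor` at `total_epochs`
#' (clamped thereafter); monotone non-increasing.
#'
#' @param epoch Zero-based epoch.
#' @param weights A [loss_weights()].
#' @return Alpha in `[alpha_floor, 1]`.
#' @export
alpha_schedule <- function(epoch, weights = loss_weights()) {
  if (epoch < 0) stop("epoch must be >= 0")
  frac <- min(1, epoch / max(1L, weights$total_epochs))
  1 - (1 - weights$alpha_floor) * frac
}

#' Structural similarity index (SSIM)
#'
#' Mean windowed SSIM with a uniform `window x window` filter over valid
#' positions, computed per channel and averaged. Identical images score
#' exactly 1.
#'
#' @param a,b Arrays `H x W x C` (or `H x W` matrices) on the same scale.
#' @param window Odd window size.
#' @param k1,k2 Stabilisation constants (standard 0.01 / 0.03).
#' @param range Declared dynamic range of the inputs.
#' @return Scalar `<= 1`.
#' @export
ssim <- function(a, b, window = 7L, k1 = 0.01, k2 = 0.03, range = 1) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (is.matrix(b)) b <- array(b, dim = c(dim(b), 1L))
  if (!identical(dim(a), dim(b))) stop("`a` and `b` must have the same shape")
  ag_ssim(ag_const(a), ag_const(b), window, k1, k2, range)$v
}

# SSIM as an autodiff graph (used directly inside the reconstruction loss).
ag_ssim <- function(a, b, window = 7L, k1 = 0.01, k2 = 0.03, range = 1) {
  C1 <- (k1 * range)^2
  C2 <- (k2 * range)^2
  mu_a <- ag_boxfilter(a, window)
  mu_b <- ag_boxfilter(b, window)
  qa <- ag_boxfilter(ag_mul(a, a), window)
  qb <- ag_boxfilter(ag_mul(b, b), window)
  r <- ag_boxfilter(ag_mul(a, b), window)
  va <- ag_sub(qa, ag_mul(mu_a, mu_a))
  vb <- ag_sub(qb, ag_mul(mu_b, mu_b))
  cab <- ag_sub(r, ag_mul(mu_a, mu_b))
  num <- ag_mul(ag_add_scalar(ag_scale(ag_mul(mu_a, mu_b), 2), C1),
                ag_add_scalar(ag_scale(cab, 2), C2))
  den <- ag_mul(ag_add_scalar(ag_add(ag_mul(mu_a, mu_a), ag_mul(mu_b, mu_b)), C1),
                ag_add_scalar(ag_add(va, vb), C2))
  ag_mean(ag_div(num, den))
}

#' Blended reconstruction loss
#'
#' `alpha(epoch) * MSE + (1 - alpha(epoch)) * (1 - SSIM)`, both terms
#' computed between the predicted segmentation and the color-coded ground
#' truth (range `[0, 1]`).
#'
#' @param pred_seg,gt_mask Arrays `H x W x 3` in `[0, 1]`.
#' @param epoch Zero-based epoch (drives the blend schedule).
#' @param weights A [loss_weights()].
#' @param window SSIM window.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(pred_seg, gt_mask, epoch = 0,
                                weights = loss_weights(), window = 7L) {
  ag_reconstruction(ag_const(pred_seg), ag_const(gt_mask), epoch, weights,
                    window)$v
}

ag_reconstruction <- function(pred, gt, epoch, weights, window = 7L,
                              ssim_node = NULL) {
  alpha <- alpha_schedule(epoch, weights)
  mse <- ag_mse(pred, gt)
  if (alpha >= 1) return(mse)
  if (is.null(ssim_node)) ssim_node <- ag_ssim(pred, gt, window)
  dssim <- ag_sub(ag_const(1), ssim_node)
  ag_add(ag_scale(mse, alpha), ag_scale(dssim, 1 - alpha))
}

#' Label smoothing
#'
#' `(1 - eps) * one_hot + eps / K` per component; the result always sums
#' to 1.
#'
#' @param one_hot Valid one-hot vector.
#' @param eps Smoothing mass in `[0, 1)`.
#' @return Smoothed target distribution.
#' @export
smooth_labels <- function(one_hot, eps = 0.1) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (!isTRUE(all.equal(sum(one_hot), 1)) || any(one_hot < 0))
    stop("`one_hot` must be a valid one-hot (or probability) vector")
  (1 - eps) * one_hot + eps / length(one_hot)
}

#' Validity loss (BCE with logits)
#'
#' Numerically stable binary cross-entropy applied to the raw validity
#' logit: informative inputs are trained toward 1.0, Gaussian-noise inputs
#' toward 0.0.
#'
#' @param validity_logit Raw scalar logit.
#' @param target 1.0 (valid) or 0.0 (fake); smoothed targets are accepted.
#' @return Non-negative scalar.
#' @export
validity_loss <- function(validity_logit, target) {
  if (!is.finite(validity_logit)) stop("validity logit must be finite")
  stopifnot(target >= 0, target <= 1)
  ag_bce_logits(ag_const(validity_logit), target)$v
}

#' Latent consistency loss
#'
#' Mean squared difference between the latent vectors of an image and its
#' affine-distorted copy; the encoder learns to embed both identically.
#'
#' @param z_original,z_distorted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
latent_consistency_loss <- function(z_original, z_distorted) {
  if (length(z_original) != length(z_distorted))
    stop("latent vectors must have equal length")
  mean((z_original - z_distorted)^2)
}

#' Clip discriminator weights
#'
#' Clamps every parameter in `param_names` to `[-c, c]`. Idempotent;
#' parameters outside the set are untouched.
#'
#' @param model A `larynet_model`.
#' @param c Positive clipping constant.
#' @param param_names Names of parameters to clip (default: the model's
#'   discriminator group).
#' @return The model with clipped parameters.
#' @export
clip_weights <- function(model, c = 0.01,
                         param_names = model$groups$discriminator) {
  if (c <= 0) stop("clipping constant must be > 0")
  for (nm in param_names)
    model$params[[nm]][] <- pmin(pmax(model$params[[nm]], -c), c)
  model
}
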