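# Training objectives: SSIM, blended reconstruction, smoothing, validity,
# consistency and weight clipping.

test_that("ssim is 1 for identical images and negative for inversions", {
  set.seed(3)
  x <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  const <- array(0.4, c(10, 10, 1))
  expect_equal(ssim(const, const), 1, tolerance = 1e-9)
  # binary checkerboard against its inversion: structure anti-correlates
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_lt(ssim(chk, 1 - chk, window = 3), 0)
  expect_lte(ssim(x, array(runif(12 * 12 * 3), c(12, 12, 3))), 1)
  expect_error(ssim(x, x[1:10, 1:10, , drop = FALSE]), "shape")
})

test_that("ssim agrees with a direct windowed reference computation", {
  set.seed(9)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  k <- 3; C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (i in 1:(8 - k + 1)) for (j in 1:(8 - k + 1)) {
    wa <- as.vector(a[i:(i + k - 1), j:(j + k - 1)])
    wb <- as.vector(b[i:(i + k - 1), j:(j + k - 1)])
    ma <- mean(wa); mb <- mean(wb)
    va <- mean(wa^2) - ma^2; vb <- mean(wb^2) - mb^2
    cab <- mean(wa * wb) - ma * mb
    vals <- c(vals, (2 * ma * mb + C1) * (2 * cab + C2) /
                ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  expect_equal(ssim(a, b, window = 3), mean(vals), tolerance = 1e-12)
})

test_that("reconstruction loss blends MSE and structural dissimilarity", {
  set.seed(4)
  gt <- array(runif(16 * 16 * 3), c(16, 16, 3))
  w <- loss_weights(alpha_floor = 0, total_epochs = 10)
  expect_equal(reconstruction_loss(gt, gt, epoch = 0, w), 0, tolerance = 1e-12)
  expect_equal(reconstruction_loss(gt, gt, epoch = 10, w), 0, tolerance = 1e-9)
  pred <- pmin(gt + 0.1, 1)
  # alpha = 1 (epoch 0) reduces exactly to MSE
  expect_equal(reconstruction_loss(pred, gt, 0, w), mean((pred - gt)^2),
               tolerance = 1e-12)
  # alpha = 0 (final epoch) equals 1 - ssim of the pair
  expect_equal(reconstruction_loss(pred, gt, 10, w), 1 - ssim(pred, gt),
               tolerance = 1e-12)
  expect_error(reconstruction_loss(pred, gt, -1, w), "epoch")
})

test_that("the blend weight schedule is monotone non-increasing", {
  w <- loss_weights(alpha_floor = 0.5, total_epochs = 15)
  a <- vapply(0:20, alpha_schedule, numeric(1), weights = w)
  expect_identical(a[1], 1)
  expect_true(all(diff(a) <= 1e-12))
  expect_equal(min(a), 0.5)
})

test_that("label smoothing redistributes mass and keeps a distribution", {
  one <- c(0, 1, 0, 0, 0, 0, 0)
  expect_identical(smooth_labels(one, 0), one)
  sm <- smooth_labels(one, 0.1)
  expect_equal(sm[2], 0.9 + 0.1 / 7, tolerance = 1e-12)
  expect_equal(sm[1], 0.1 / 7, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  set.seed(2)
  for (k in c(2, 5, 9)) {
    oh <- diag(k)[sample(k, 1), ]
    expect_equal(sum(smooth_labels(oh, runif(1, 0, 0.9))), 1, tolerance = 1e-12)
  }
  expect_error(smooth_labels(one, 1))
  expect_error(smooth_labels(c(0.5, 0.7), 0.1))
})

test_that("validity loss is stable BCE-with-logits", {
  expect_equal(validity_loss(0, 1), log(2), tolerance = 1e-12)
  expect_equal(validity_loss(0, 0), log(2), tolerance = 1e-12)
  expect_lt(validity_loss(30, 1), 1e-12)   # large logit, matching target
  expect_lt(validity_loss(-30, 0), 1e-12)
  expect_gt(validity_loss(-30, 1), 20)     # large logit, wrong target
  expect_true(is.finite(validity_loss(800, 0)))
  expect_error(validity_loss(Inf, 1), "finite")
})

test_that("latent consistency is a symmetric mean squared difference", {
  z <- rnorm(32)
  expect_identical(latent_consistency_loss(z, z), 0)
  expect_equal(latent_consistency_loss(z, z + 1), 1, tolerance = 1e-12)
  a <- rnorm(32); b <- rnorm(32)
  expect_identical(latent_consistency_loss(a, b), latent_consistency_loss(b, a))
  expect_error(latent_consistency_loss(a, rnorm(5)), "length")
})

test_that("weight clipping clamps the discriminator set and is idempotent", {
  m <- tiny_model(seed = 8)
  m$params[["l7.W"]][1, 1] <- 5
  m$params[["u1.c1.w"]][1] <- 5  # generator-side: must stay untouched
  c1 <- clip_weights(m, 0.01)
  expect_identical(c1$params[["l7.W"]][1, 1], 0.01)
  expect_identical(c1$params[["u1.c1.w"]][1], 5)
  expect_true(all(vapply(c1$params[c1$groups$discriminator],
                         function(p) max(abs(p)) <= 0.01, logical(1))))
  expect_identical(clip_weights(c1, 0.01)$params, c1$params)
  # already-in-range parameters are unchanged
  m2 <- tiny_model(seed = 9)
  shrunk <- lapply(m2$params, function(p) p * 0)
  m2$params <- shrunk
  expect_identical(clip_weights(m2, 0.01)$params, shrunk)
  expect_error(clip_weights(m, 0), "> 0")
})

test_that("all loss terms are finite and non-negative on finite inputs", {
  set.seed(6)
  gt <- array(runif(8 * 32 * 3), c(8, 32, 3))
  pred <- array(runif(8 * 32 * 3), c(8, 32, 3))
  vals <- c(reconstruction_loss(pred, gt, 3, loss_weights()),
            validity_loss(rnorm(1), 1),
            latent_consistency_loss(rnorm(8), rnorm(8)))
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
})

test_that("reconstruction loss decreases as predictions approach the target", {
  set.seed(8)
  gt <- array(runif(16 * 16 * 3), c(16, 16, 3))
  start <- array(runif(16 * 16 * 3), c(16, 16, 3))
  losses <- vapply(c(0, 0.5, 0.9, 1), function(t)
    reconstruction_loss((1 - t) * start + t * gt, gt, 5, loss_weights()),
    numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_equal(losses[4], 0, tolerance = 1e-9)
})
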