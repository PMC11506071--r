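# Adversarial optimisation loop: step contracts, clipping, frequency,
# checkpoint policy and reproducibility. All runs here are tiny (32 x 32).

make_toy_run <- function(n = 12, epochs = 2L, frequency = c(1L, 1L),
                         seed = 3L, dir = NULL) {
  if (is.null(dir)) dir <- tempfile("toyrun")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- tiny_scene_samples(n, size = 32, seed = 17)
  ntr <- n - 4L
  tcfg <- train_config(epochs = epochs, batch_size = 4L, lr_gen = 1e-3,
                       lr_disc = 1e-3, frequency = frequency, seed = seed,
                       checkpoint_dir = file.path(dir, "ck"),
                       log_dir = file.path(dir, "lg"), grid_samples = 2L)
  mcfg <- model_config(latent_dim = 8L, encoder_channels = c(4L, 4L, 4L, 6L, 6L),
                       residual_units_per_skip = 1L)
  list(fit = fit(tcfg, list(train = samples[seq_len(ntr)],
                            val = samples[(ntr + 1L):n]),
                 model_cfg = mcfg),
       tcfg = tcfg)
}

test_that("discriminator steps clip weights and honour dummy targets", {
  samples <- tiny_scene_samples(4, size = 32, seed = 5)
  samples <- larynet:::prepare_samples(samples)
  m <- tiny_model(seed = 2, channels = c(4L, 4L, 4L, 6L, 6L))
  w <- loss_weights()
  set.seed(1)
  st <- discriminator_step(m, samples, train_config(batch_size = 4L), w)
  expect_true(all(vapply(st$model$params[st$model$groups$discriminator],
                         function(p) max(abs(p)) <= w$clip_value, logical(1))))
  expect_named(st$record, c("validity", "auxiliary", "consistency",
                            "adversarial", "total"))
  expect_true(all(is.finite(unlist(st$record))))
  expect_error(discriminator_step(m, list(), train_config()), "empty")
  # a batch of only dummy images targets the dedicated dummy class
  dummies <- lapply(tiny_scene_samples(3, size = 32, seed = 6,
                                       dummy_fraction = 1),
                    function(s) { s$primary_class <- NA_integer_; s })
  tgt <- larynet:::aux_target(dummies[[1]], m$config, 0.1)
  expect_identical(which.max(tgt) - 1L, m$config$num_lesion_classes)
  set.seed(2)
  st2 <- discriminator_step(m, dummies, train_config(batch_size = 4L), w)
  expect_true(is.finite(st2$record$auxiliary))
})

test_that("generator steps skip clipping and report their loss schema", {
  samples <- larynet:::prepare_samples(tiny_scene_samples(4, size = 32, seed = 5))
  m <- tiny_model(seed = 2, channels = c(4L, 4L, 4L, 6L, 6L))
  # plant an out-of-box generator weight: it must survive (no clipping)
  m$params[["out.w"]][1] <- 3
  set.seed(1)
  st <- generator_step(m, samples, train_config(batch_size = 4L))
  expect_gt(max(abs(st$model$params[["out.w"]])), 0.011)
  expect_named(st$record, c("mse", "ssim", "adversarial", "reconstruction",
                            "total"))
  # test hook: overwriting predictions with the ground truth zeroes the
  # reconstruction component
  gtstack <- larynet:::stack_batch(samples, "mask")
  set.seed(1)
  st0 <- generator_step(m, samples, train_config(batch_size = 4L),
                        .pred_override = gtstack)
  expect_lt(st0$record$reconstruction, 1e-12)
  expect_lt(st0$record$mse, 1e-12)
})

test_that("fit runs, checkpoints and logs on a toy problem", {
  run <- make_toy_run(n = 12, epochs = 2L)
  h <- run$fit
  expect_s3_class(h, "larynet_history")
  expect_identical(nrow(h$history), 2L)
  files <- list.files(run$tcfg$checkpoint_dir)
  expect_true("last.ckpt" %in% files)
  expect_lte(length(files), 4L)  # last + at most 3 best
  expect_true(all(c("epochs.csv", "steps.csv") %in%
                  list.files(run$tcfg$log_dir)))
  expect_true(any(grepl("grid\\.png$", list.files(run$tcfg$log_dir))))
  expect_true(all(c("mse_loss", "validity") %in% names(h$history)))
  # discriminator end state is clipped; generator is not forced into the box
  m <- h$model
  expect_true(all(vapply(m$params[m$groups$discriminator],
                         function(p) max(abs(p)) <= 0.01, logical(1))))
})

test_that("the frequency pair controls the step ratio", {
  run <- make_toy_run(n = 16, epochs = 3L, frequency = c(1L, 5L))
  h <- run$fit$history
  nd <- sum(h$disc_steps); ng <- sum(h$gen_steps)
  expect_identical(nd, 9L)  # every batch: 3 batches/epoch x 3 epochs
  # one generator execution per five discriminator executions
  expect_lte(abs(nd - 5L * ng), 5L)
  expect_gte(nd, ng)
  # the default pair trains both optimisers side by side on every batch
  run11 <- make_toy_run(n = 12, epochs = 1L, frequency = c(1L, 1L))
  expect_identical(run11$fit$history$disc_steps, run11$fit$history$gen_steps)
})

test_that("training is reproducible for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- make_toy_run(n = 8, epochs = 2L, seed = 11, dir = d1)
  r2 <- make_toy_run(n = 8, epochs = 2L, seed = 11, dir = d2)
  expect_equal(r1$fit$history, r2$fit$history, tolerance = 1e-12)
  expect_identical(r1$fit$model$params, r2$fit$model$params)
})

test_that("the checkpoint policy retains only the top-k best files", {
  dir <- withr::local_tempdir()
  m <- tiny_model()
  metrics <- c(0.5, 0.3, 0.7, 0.2, 0.4, 0.6)
  for (e in seq_along(metrics))
    larynet:::apply_checkpoint_policy(m, dir, e, metrics[e], k = 3L)
  best <- list.files(dir, pattern = "^best-")
  expect_length(best, 3L)
  kept <- sort(as.numeric(sub(".*-mse([0-9.]+)\\.ckpt$", "\\1", best)))
  expect_equal(kept, c(0.2, 0.3, 0.4), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "last.ckpt")))
})
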