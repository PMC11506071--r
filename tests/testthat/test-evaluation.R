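# Pixel-level evaluation stack: confusion cells, derived metrics, IoU,
# mAUC sweep, Gram scores, polygon extraction and dataset aggregation.

test_that("confusion cells match constructed fixtures and conserve pixels", {
  gt <- paint_rect(blank_image(4, 4), 1, 1:4, 6)
  gt <- paint_rect(gt, 3, 2, 6)               # 5 Cancer pixels
  cells <- confusion_cells(gt, gt, 6)
  expect_equal(cells, c(tp = 5, tn = 11, fp = 0, fn = 0))
  black <- blank_image(4, 4)
  cells2 <- confusion_cells(black, gt, 6)
  expect_equal(cells2, c(tp = 0, tn = 11, fp = 0, fn = 5))
  expect_error(confusion_cells(blank_image(3, 3), gt, 6), "shape")
})

test_that("cells, F1 and IoU agree with brute-force oracles on random pairs", {
  set.seed(23)
  for (rep in 1:20) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    pred <- random_label_image(h, w)
    gt <- random_label_image(h, w)
    for (cid in sample(0:6, 2)) {
      cells <- confusion_cells(pred, gt, cid)
      expect_identical(cells, oracle_cells(pred, gt, cid))
      expect_identical(sum(cells), as.integer(h * w))  # conservation
      pm <- class_mask(pred, cid); gm <- class_mask(gt, cid)
      # IoU from cells must equal IoU on masks
      if (sum(pm | gm) > 0)
        expect_equal(as.numeric(iou_pixels(pm, gm)),
                     cells[["tp"]] / (cells[["tp"]] + cells[["fp"]] + cells[["fn"]]),
                     tolerance = 1e-12)
      # per-image identity IoU = F1 / (2 - F1)
      f1 <- as.numeric(f1_per_image(cells))
      if (sum(pm | gm) > 0)
        expect_equal(as.numeric(iou_pixels(pm, gm)), f1 / (2 - f1),
                     tolerance = 1e-12)
    }
  }
})

test_that("accuracy, precision and recall compute the textbook ratios", {
  cells <- c(tp = 2417.41, tn = 94777.63, fp = 432.32, fn = 676.65)
  expect_equal(round(accuracy(cells), 3), 0.989)
  pr <- precision_recall(c(tp = 2417.41, tn = 0, fp = 432.32, fn = 676.65))
  expect_equal(round(as.numeric(pr), 2), c(0.85, 0.78))
  expect_identical(accuracy(c(tp = 0, tn = 100, fp = 0, fn = 0)), 1)
  expect_error(accuracy(c(tp = 0, tn = 0, fp = 0, fn = 0)), "all-zero")
  pr2 <- precision_recall(c(tp = 3, tn = 1, fp = 3, fn = 3))
  expect_equal(as.numeric(pr2), c(0.5, 0.5))
  deg <- precision_recall(c(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(isTRUE(attr(deg, "degenerate")))
  expect_identical(as.numeric(deg), c(0, 0))
  expect_identical(as.numeric(f1_per_image(c(tp = 0, tn = 5, fp = 0, fn = 3))), 0)
  expect_true(isTRUE(attr(f1_per_image(c(tp = 0, tn = 5, fp = 0, fn = 0)),
                          "degenerate")))
})

test_that("pixel and box IoU handle overlap, disjoint and empty cases", {
  a <- matrix(FALSE, 20, 30); a[6:15, 6:15] <- TRUE
  b <- matrix(FALSE, 20, 30); b[6:15, 11:20] <- TRUE
  expect_equal(as.numeric(iou_pixels(a, b)), 50 / 150, tolerance = 1e-12)
  expect_equal(iou_boxes(a, b), 50 / 150, tolerance = 1e-12)
  expect_identical(as.numeric(iou_pixels(a, a)), 1)
  expect_equal(iou_boxes(a, a), 1, tolerance = 1e-12)
  d <- matrix(FALSE, 20, 30); d[1:2, 1:2] <- TRUE
  expect_identical(as.numeric(iou_pixels(a, d)), 0)
  expect_identical(iou_boxes(a, d), 0)
  e <- matrix(FALSE, 20, 30)
  expect_true(isTRUE(attr(iou_pixels(e, e), "degenerate")))
  expect_true(isTRUE(attr(iou_boxes(e, e), "degenerate")))
  # boxes use the largest connected component only
  f <- a; f[1, 25] <- TRUE  # stray pixel must not stretch the box
  expect_equal(iou_boxes(f, a), 1, tolerance = 1e-12)
})

test_that("mAUC behaves at its ceiling, floor and matches the sweep oracle", {
  gt <- paint_rect(blank_image(12, 12), 3:8, 3:8, 6)
  expect_gt(mauc(gt, gt, 6), 0.9)                       # perfect prediction
  expect_lte(mauc(blank_image(12, 12), gt, 6), 0.5)     # no-signal bound
  expect_true(is.na(mauc(gt, blank_image(12, 12), 6)))  # empty ground truth
  set.seed(31)
  for (rep in 1:3) {
    pred <- random_label_image(10, 10)
    gt2 <- random_label_image(10, 10)
    cid <- 6
    got <- mauc(pred, gt2, cid)
    want <- oracle_mauc(pred, gt2, cid)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("gram differences scale bilinearly and match hand arithmetic", {
  set.seed(17)
  f <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  expect_identical(gram_difference(f, f), 0)
  # doubling features quadruples the Gram matrix
  gram <- function(x) tcrossprod(t(matrix(x, ncol = dim(x)[3]))) / length(x)
  expect_equal(gram_difference(2 * f, f),
               3 * sqrt(sum(gram(f)^2)), tolerance = 1e-12)
  # tiny hand-computed case
  fa <- array(c(1, 0, 0, 0, 0, 1, 0, 0), c(2, 2, 2))
  fb <- array(0, c(2, 2, 2))
  ga <- matrix(c(1, 0, 0, 1), 2, 2) / 8
  expect_equal(gram_difference(fa, fb), sqrt(sum(ga^2)), tolerance = 1e-12)
  expect_error(gram_difference(f, array(0, c(2, 2, 3))), "shape")
})

test_that("extract_max_polygon finds areas, centroids and ratios", {
  img <- paint_rect(blank_image(64, 64), 21:30, 21:30, 6)  # 10x10 at (20,20)
  got <- extract_max_polygon(img, 6)
  expect_identical(got$area, 100L)
  expect_equal(unname(got$centroid), c(24.5, 24.5), tolerance = 1e-12)
  expect_identical(got$area_ratio, 1)
  expect_identical(got$n_colors, 1L)
  expect_gte(nrow(got$vertices), 4)
  # two classes: ratio of the larger polygon is 100 / 160
  img2 <- paint_rect(img, 41:50, 41:46, 0)  # 10x6 = 60 px of class 0
  got2 <- extract_max_polygon(img2, 6)
  expect_equal(got2$area_ratio, 100 / 160, tolerance = 1e-12)
  expect_identical(got2$n_colors, 2L)
  empty <- extract_max_polygon(blank_image(16, 16), 6)
  expect_identical(empty$area, 0)
  expect_null(empty$vertices)
})

test_that("evaluating ground truth against itself is a perfect ceiling", {
  samples <- larynet:::prepare_samples(
    tiny_scene_samples(6, size = 64, seed = 13, dummy_fraction = 0))
  # identity "model": score each mask against itself via the metric path
  per <- lapply(samples, function(s)
    larynet:::image_class_metrics(s$mask, s$mask, hue_band_rule()))
  for (k in seq_along(per)) {
    for (rec in per[[k]]) {
      if (!rec$present) next
      expect_identical(as.numeric(rec$f1), 1)
      expect_identical(as.numeric(rec$iou), 1)
      expect_equal(rec$bb_iou, 1, tolerance = 1e-12)
      pr <- precision_recall(rec$cells)
      expect_identical(as.numeric(pr), c(1, 1))
    }
  }
})

test_that("evaluate_dataset writes the full table and 13-column CSV", {
  dir <- withr::local_tempdir()
  samples <- larynet:::prepare_samples(
    tiny_scene_samples(5, size = 32, seed = 19, dummy_fraction = 0))
  m <- tiny_model(seed = 6, channels = c(4L, 4L, 4L, 6L, 6L))
  withr::local_envvar(LARYNET_DATE = "20260101", LARYNET_DATASET = "toy")
  set.seed(2)
  ev <- evaluate_dataset(m, samples, dir)
  expect_identical(nrow(ev$metrics), 7L)
  expect_identical(names(ev$metrics),
                   c("Cls", "Count", "F1", "TP", "TN", "FP", "FN", "ACC",
                     "IoU", "bbIoU", "mAUC", "Precision", "Recall"))
  expect_identical(ev$metrics$Cls, 6:0)  # class 6 first, like the tables
  expect_true(all(ev$metrics$Count == 5L))
  # conservation of averaged cells
  sums <- with(ev$metrics, TP + TN + FP + FN)
  expect_equal(sums, rep(32 * 32, 7), tolerance = 1e-9)
  preds <- ev$predictions
  expect_identical(ncol(preds), 13L)
  expect_identical(nrow(preds), 5L)
  expect_true(all(preds$area_ratio >= 0 & preds$area_ratio <= 1))
  expect_true(all(preds$latent_idx1 >= 0 &
                  preds$latent_idx1 < m$config$latent_dim))
  expect_true(file.exists(file.path(ev$out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(ev$out_dir, "predictions.csv")))
  expect_identical(basename(ev$out_dir), "20260101-toy")
  expect_length(list.files(file.path(ev$out_dir, "JPG")), 5L)
  expect_length(list.files(file.path(ev$out_dir, "PNG")), 5L)
  expect_length(ev$validity, 2)
})

test_that("dataset evaluation is permutation-invariant over image order", {
  samples <- larynet:::prepare_samples(
    tiny_scene_samples(4, size = 32, seed = 29, dummy_fraction = 0))
  m <- tiny_model(seed = 8, channels = c(4L, 4L, 4L, 6L, 6L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  set.seed(3)
  e1 <- evaluate_dataset(m, samples, d1, write_images = FALSE)
  set.seed(3)
  e2 <- evaluate_dataset(m, rev(samples), d2, write_images = FALSE)
  expect_equal(e1$metrics, e2$metrics, tolerance = 1e-9)
})
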