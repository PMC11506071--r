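# Pixel-level evaluation stack.
#
# Predicted segmentations and ground-truth masks are decoded per pixel with
# the hue-band rule, and a confusion matrix (TP/TN/FP/FN pixel counts) is
# accumulated separately for each of the seven colors. From the cells come
# accuracy, precision, recall and F1; IoU is computed on pixel sets and
# bbIoU on the axis-aligned bounding boxes of the largest connected
# component of each mask. An AUC approximation (mAUC) sweeps the hue-band
# half-width. Dataset-level reporting mirrors the published table layout:
# precision/recall/accuracy from dataset-averaged cells, F1/IoU as per-image
# means, validity with its standard deviation, a top-3 latent-index
# histogram, and CSV/JPG/PNG outputs per image.

#' Identity model for oracle-ceiling evaluations
#'
#' A pseudo-model whose "segmentation" is its input, unchanged, with
#' all-zero latent outputs. Feeding it ground-truth masks as images turns
#' [evaluate_dataset()] into a self-consistency check: every present class
#' must score precision = recall = F1 = IoU = 1.
#'
#' @param latent_dim Length of the zero latent vector it reports.
#' @return An object of class `larynet_identity`.
#' @export
identity_model <- function(latent_dim = 32L) {
  structure(list(config = list(latent_dim = as.integer(latent_dim),
                               aux_output_nodes = 9L)),
            class = "larynet_identity")
}

# Uniform forward interface over real models and the identity pseudo-model.
forward_any <- function(model, image) {
  if (inherits(model, "larynet_identity")) {
    list(seg_image = image,
         latent = numeric(model$config$latent_dim),
         validity_logit = 0,
         aux_logits = numeric(model$config$aux_output_nodes),
         features = image)
  } else model_forward(model, image)
}

encode_any <- function(model, image) {
  if (inherits(model, "larynet_identity")) {
    list(latent = numeric(model$config$latent_dim), features = image)
  } else model_encode(model, image)
}

#' Per-class pixel confusion cells
#'
#' @param pred_img,gt_img RGB arrays of identical shape (`[0, 1]` or 8-bit).
#' @param class_id Class id in `0:6`.
#' @param rule A [hue_band_rule()].
#' @return Named numeric `c(tp, tn, fp, fn)`; the four cells always sum to
#'   the image pixel count.
#' @export
confusion_cells <- function(pred_img, gt_img, class_id, rule = hue_band_rule()) {
  if (!identical(dim(pred_img), dim(gt_img)))
    stop("prediction and ground truth must have the same shape")
  cells_from_ids(classify_image(pred_img, rule = rule),
                 classify_image(gt_img, rule = rule), class_id)
}

cells_from_ids <- function(pred_ids, gt_ids, class_id) {
  p <- pred_ids == class_id
  g <- gt_ids == class_id
  c(tp = sum(p & g), tn = sum(!p & !g), fp = sum(p & !g), fn = sum(!p & g))
}

#' Accuracy from confusion cells
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cells Named numeric with `tp`, `tn`, `fp`, `fn` (non-negative;
#'   fractional values from dataset averaging are fine).
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' accuracy(c(tp = 2417.41, tn = 94777.63, fp = 432.32, fn = 676.65)) # ~0.989
accuracy <- function(cells) {
  tot <- cells[["tp"]] + cells[["tn"]] + cells[["fp"]] + cells[["fn"]]
  if (tot <= 0) stop("all-zero confusion cells")
  (cells[["tp"]] + cells[["tn"]]) / tot
}

#' Precision and recall from confusion cells
#'
#' `TP/(TP+FP)` and `TP/(TP+FN)`. Degenerate denominators yield 0 with a
#' `degenerate` attribute.
#'
#' @inheritParams accuracy
#' @return Named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(cells) {
  pd <- cells[["tp"]] + cells[["fp"]]
  rd <- cells[["tp"]] + cells[["fn"]]
  out <- c(precision = if (pd > 0) cells[["tp"]] / pd else 0,
           recall = if (rd > 0) cells[["tp"]] / rd else 0)
  if (pd <= 0 || rd <= 0) attr(out, "degenerate") <- TRUE
  out
}

#' Per-image F1 score from confusion cells
#'
#' `2 TP / (2 TP + FP + FN)`; the dataset-level F1 is the mean of per-image
#' values. Degenerate (no positives anywhere) yields 0 with a flag.
#'
#' @inheritParams accuracy
#' @return F1 in `[0, 1]`.
#' @export
f1_per_image <- function(cells) {
  den <- 2 * cells[["tp"]] + cells[["fp"]] + cells[["fn"]]
  if (den <= 0) return(structure(0, degenerate = TRUE))
  2 * cells[["tp"]] / den
}

#' Pixel and bounding-box intersection over union
#'
#' `iou_pixels` is |intersection| / |union| over pixel sets. `iou_boxes`
#' compares the axis-aligned bounding boxes of the largest connected
#' component of each mask. Both return 0 (flagged) when the union is empty.
#'
#' @param pred_mask,gt_mask Logical matrices of identical shape.
#' @return IoU in `[0, 1]`.
#' @export
iou_pixels <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("shape mismatch")
  u <- sum(pred_mask | gt_mask)
  if (u == 0) return(structure(0, degenerate = TRUE))
  sum(pred_mask & gt_mask) / u
}

largest_component <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1)
  counts <- tabulate(lab[lab > 0])
  mask & (lab == which.max(counts))
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(r1 = min(idx[, 1]), r2 = max(idx[, 1]), c1 = min(idx[, 2]), c2 = max(idx[, 2]))
}

#' @rdname iou_pixels
#' @export
iou_boxes <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("shape mismatch")
  pc <- largest_component(pred_mask)
  gc <- largest_component(gt_mask)
  if (is.null(pc) && is.null(gc)) return(structure(0, degenerate = TRUE))
  if (is.null(pc) || is.null(gc)) return(0)
  a <- mask_bbox(pc); b <- mask_bbox(gc)
  ir <- min(a["r2"], b["r2"]) - max(a["r1"], b["r1"]) + 1
  ic <- min(a["c2"], b["c2"]) - max(a["c1"], b["c1"]) + 1
  inter <- max(0, ir) * max(0, ic)
  area <- function(x) (x["r2"] - x["r1"] + 1) * (x["c2"] - x["c1"] + 1)
  as.numeric(inter / (area(a) + area(b) - inter))
}

#' Hue-band-sweep AUC approximation (mAUC)
#'
#' An approximation of the per-image AUC: the hue-band half-width applied to
#' the *prediction* is swept over a fixed grid; each width gives one
#' (FPR, TPR) point against the fixed-rule ground truth, and the curve
#' (anchored at (0,0) and (1,1)) is integrated by the trapezoidal rule.
#'
#' @inheritParams confusion_cells
#' @param widths Half-width grid on the 0-179 unit hue scale.
#' @return Value in `[0, 1]`; `NA` (flagged) when the ground truth has no
#'   pixels of the class.
#' @export
mauc <- function(pred_img, gt_img, class_id, rule = hue_band_rule(),
                 widths = seq(0, 90, by = 6)) {
  gt_ids <- classify_image(gt_img, rule = rule)
  g <- gt_ids == class_id
  if (!any(g)) return(structure(NA_real_, degenerate = TRUE))
  pts <- vapply(widths, function(w) {
    if (w <= 0) {
      p <- matrix(FALSE, nrow(g), ncol(g))
    } else {
      r <- hue_band_rule(w, rule$min_saturation, rule$min_value)
      p <- classify_image(pred_img, rule = r) == class_id
    }
    c(fpr = sum(p & !g) / max(1, sum(!g)), tpr = sum(p & g) / sum(g))
  }, numeric(2))
  fpr <- c(0, pts["fpr", ], 1)
  tpr <- c(0, pts["tpr", ], 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Gram-matrix difference between two feature maps
#'
#' Frobenius norm of `G(a) - G(b)` where `G` is the channel-by-channel
#' inner-product matrix of the flattened feature maps, normalised by the
#' total element count of the map. Used as the "encoder error" between an
#' image and its affine-distorted copy.
#'
#' @param features_a,features_b `H x W x C` arrays of identical shape.
#' @return Non-negative scalar; 0 for identical features.
#' @export
gram_difference <- function(features_a, features_b) {
  if (!identical(dim(features_a), dim(features_b))) stop("shape mismatch")
  gram <- function(f) {
    m <- t(matrix(f, ncol = dim(f)[3]))  # C x (H*W)
    tcrossprod(m) / length(f)
  }
  sqrt(sum((gram(features_a) - gram(features_b))^2))
}

#' Largest detected polygon of a class
#'
#' Finds the largest connected component of the class in a predicted
#' segmentation, its contour, pixel area, centroid (0-based pixel
#' coordinates, `(x, y)`), the ratio of its area to the total area detected
#' across all classes, and the number of distinct classes detected.
#'
#' @param pred_img RGB array.
#' @param class_id Class id in `0:6`.
#' @param rule A [hue_band_rule()].
#' @return List with `vertices` (two-column `(x, y)` contour matrix or
#'   `NULL`), `area`, `centroid`, `area_ratio`, `n_colors`.
#' @export
extract_max_polygon <- function(pred_img, class_id, rule = hue_band_rule()) {
  ids <- classify_image(pred_img, rule = rule)
  total <- sum(ids >= 0)
  n_colors <- length(unique(ids[ids >= 0]))
  comp <- largest_component(ids == class_id)
  if (is.null(comp) || total == 0)
    return(list(vertices = NULL, area = 0, centroid = c(x = 0, y = 0),
                area_ratio = 0, n_colors = n_colors))
  idx <- which(comp, arr.ind = TRUE)
  oc <- EBImage::ocontour(comp * 1)[[1]]
  list(vertices = cbind(x = oc[, 2] - 1, y = oc[, 1] - 1),
       area = nrow(idx),
       centroid = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
       area_ratio = nrow(idx) / total,
       n_colors = n_colors)
}

# Metrics for one prediction/ground-truth pair across all classes.
image_class_metrics <- function(pred_img, gt_img, rule, table = lesion_color_table(),
                                widths = seq(0, 90, by = 6)) {
  pred_ids <- classify_image(pred_img, rule = rule)
  gt_ids <- classify_image(gt_img, rule = rule)
  lapply(table$class_id, function(cid) {
    cells <- cells_from_ids(pred_ids, gt_ids, cid)
    p <- pred_ids == cid; g <- gt_ids == cid
    list(class_id = cid, cells = cells,
         present = any(g),
         f1 = f1_per_image(cells),
         iou = iou_pixels(p, g),
         bb_iou = iou_boxes(p, g),
         mauc = mauc(pred_img, gt_img, cid, rule, widths))
  })
}

#' Evaluate a trained model on a dataset
#'
#' Runs the model over every test image, accumulates per-class pixel
#' confusion matrices via the hue-band rule and reports the standard table
#' layout: `Cls, Count, F1, TP, TN, FP, FN, ACC, IoU, bbIoU, mAUC,
#' Precision, Recall`. Precision, recall and accuracy are computed from
#' dataset-averaged cells; F1 and IoU are means of per-image values over the
#' images where the class appears in the ground truth (set
#' `f1_mode = "averaged_cells"` for the pooled alternative). Also writes the
#' 13-column per-image prediction CSV, a JPG directory of input/output
#' overlays, a PNG directory of max-polygon images, the top-3 latent-index
#' histogram, and the validity mean with its standard deviation.
#'
#' @param model A `larynet_model` or a checkpoint file path.
#' @param data A dataset directory with `manifest.csv` (its `test` split is
#'   used) or a list of samples.
#' @param out_dir Output directory; a `date-dataset` subdirectory is created
#'   (override the two name parts with environment variables `LARYNET_DATE`
#'   and `LARYNET_DATASET`).
#' @param rule A [hue_band_rule()].
#' @param f1_mode `"per_image"` (default, matches the table layout) or
#'   `"averaged_cells"`.
#' @param write_images Write the JPG/PNG directories (default `TRUE`).
#' @return A list of class `larynet_evaluation`: `metrics` (7-row data
#'   frame), `predictions` (13-column data frame), `latent_top3` histogram,
#'   `validity` (mean and sd) and `out_dir`.
#' @export
evaluate_dataset <- function(model, data, out_dir = tempdir(),
                             rule = hue_band_rule(),
                             f1_mode = c("per_image", "averaged_cells"),
                             write_images = TRUE) {
  f1_mode <- match.arg(f1_mode)
  if (is.character(model)) model <- load_checkpoint(model)$model
  samples <- if (is.character(data)) load_manifest_samples(data, "test")
             else prepare_samples(data)
  if (length(samples) == 0L) stop("no evaluation samples")
  tag <- paste0(Sys.getenv("LARYNET_DATE", format(Sys.Date(), "%Y%m%d")), "-",
                Sys.getenv("LARYNET_DATASET", "dataset"))
  run_dir <- file.path(out_dir, tag)
  jpg_dir <- file.path(run_dir, "JPG"); png_dir <- file.path(run_dir, "PNG")
  if (write_images) {
    dir.create(jpg_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(png_dir, recursive = TRUE, showWarnings = FALSE)
  } else dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- lesion_color_table()
  per_image <- vector("list", length(samples))
  pred_rows <- vector("list", length(samples))
  validity <- numeric(length(samples))
  top3 <- matrix(NA_integer_, length(samples), 3)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    out <- forward_any(model, s$image)
    per_image[[i]] <- image_class_metrics(out$seg_image, s$mask, rule, tab)
    xa <- apply_random_affine(s$image)
    enc_a <- encode_any(model, xa)
    validity[i] <- stable_sigmoid(out$validity_logit)
    ord <- order(out$latent, decreasing = TRUE)
    top3[i, ] <- ord[1:3] - 1L
    pred_ids <- classify_image(out$seg_image, rule = rule)
    detected <- sort(unique(pred_ids[pred_ids >= 0]))
    dom <- if (length(detected)) {
      counts <- vapply(detected, function(cid) sum(pred_ids == cid), numeric(1))
      detected[which.max(counts)]
    } else NA_integer_
    poly <- if (!is.na(dom)) extract_max_polygon(out$seg_image, dom, rule)
            else list(area = 0, centroid = c(x = 0, y = 0), area_ratio = 0,
                      n_colors = 0)
    pred_rows[[i]] <- data.frame(
      predicted_class = which.max(out$aux_logits) - 1L,
      latent_idx1 = top3[i, 1], latent_idx2 = top3[i, 2],
      latent_idx3 = top3[i, 3],
      latent_difference = sqrt(sum((out$latent - enc_a$latent)^2)),
      validity = validity[i],
      encoder_error = gram_difference(out$features, enc_a$features),
      n_colors = poly$n_colors,
      polygon_area = poly$area,
      area_ratio = poly$area_ratio,
      center_x = poly$centroid[["x"]], center_y = poly$centroid[["y"]],
      input_path = s$path %||% sprintf("sample_%04d", i),
      stringsAsFactors = FALSE)
    if (write_images) {
      overlay <- pmin(pmax(0.5 * s$image + 0.5 * out$seg_image, 0), 1)
      EBImage::writeImage(EBImage::Image(aperm(overlay, c(2, 1, 3)),
                                         colormode = "Color"),
                          file.path(jpg_dir, sprintf("overlay_%04d.jpg", i)),
                          quality = 90)
      polyimg <- array(0, dim = dim(out$seg_image))
      if (!is.na(dom)) {
        comp <- largest_component(pred_ids == dom)
        col <- unlist(tab[tab$class_id == dom, c("r", "g", "b")]) / 255
        for (ch in 1:3) { m <- polyimg[, , ch]; m[comp] <- col[ch]
                          polyimg[, , ch] <- m }
      }
      png::writePNG(polyimg, file.path(png_dir, sprintf("polygon_%04d.png", i)))
    }
  }
  metrics <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    cid <- tab$class_id[k]
    recs <- lapply(per_image, `[[`, k)
    cells <- rowMeans(vapply(recs, `[[`, numeric(4), "cells"))
    present <- vapply(recs, `[[`, logical(1), "present")
    pick <- function(fld) vapply(recs, function(r) as.numeric(r[[fld]]), numeric(1))
    sel <- if (any(present)) present else rep(TRUE, length(recs))
    pr <- precision_recall(cells)
    f1 <- if (f1_mode == "per_image") mean(pick("f1")[sel])
          else as.numeric(f1_per_image(cells))
    data.frame(Cls = cid, Count = length(recs), F1 = f1,
               TP = cells[["tp"]], TN = cells[["tn"]], FP = cells[["fp"]],
               FN = cells[["fn"]], ACC = accuracy(cells),
               IoU = mean(pick("iou")[sel]),
               bbIoU = mean(pick("bb_iou")[sel]),
               mAUC = mean(pick("mauc")[sel], na.rm = TRUE),
               Precision = pr[["precision"]], Recall = pr[["recall"]])
  }))
  metrics <- metrics[order(metrics$Cls, decreasing = TRUE), ]
  predictions <- do.call(rbind, pred_rows)
  top3_hist <- lapply(1:3, function(j) sort(table(top3[, j]), decreasing = TRUE))
  utils::write.csv(metrics, file.path(run_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(predictions, file.path(run_dir, "predictions.csv"),
                   row.names = FALSE)
  structure(list(metrics = metrics, predictions = predictions,
                 latent_top3 = top3_hist,
                 validity = c(mean = mean(validity), sd = stats::sd(validity)),
                 out_dir = run_dir),
            class = "larynet_evaluation")
}

#' @export
print.larynet_evaluation <- function(x, ...) {
  cat("<larynet_evaluation>\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat(sprintf("validity %.4f (sd %.4f)  |  outputs: %s\n",
              x$validity[["mean"]], x$validity[["sd"]], x$out_dir))
  invisible(x)
}

#' Predict the segmentation for one image
#'
#' @param model A `larynet_model` or checkpoint path.
#' @param image RGB array or PNG file path.
#' @param rule A [hue_band_rule()].
#' @return List with `seg_image`, decoded `class_ids` matrix, `validity`
#'   (sigmoid), `latent` and `aux_logits`.
#' @export
predict_image <- function(model, image, rule = hue_band_rule()) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  if (is.character(image)) image <- png::readPNG(image)
  out <- model_forward(model, image)
  list(seg_image = out$seg_image,
       class_ids = classify_image(out$seg_image, rule = rule),
       validity = stable_sigmoid(out$validity_logit),
       latent = out$latent, aux_logits = out$aux_logits)
}
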