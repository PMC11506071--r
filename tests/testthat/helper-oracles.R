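# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small fixture builders. Everything here is written
# as plainly as possible (per-pixel loops, direct formulas) and never calls
# the code paths it checks.

# per-pixel hue-band classification straight from the definition
oracle_classify_rgb <- function(r, g, b, rule = hue_band_rule(),
                                table = lesion_color_table()) {
  mx <- max(r, g, b); mn <- min(r, g, b)
  v <- mx
  s <- if (mx == 0) 0 else (mx - mn) / mx * 255
  if (s < rule$min_saturation || v < rule$min_value) return(-1L)
  d <- mx - mn
  h_deg <- if (d == 0) 0 else if (mx == r) 60 * (((g - b) / d) %% 6)
           else if (mx == g) 60 * ((b - r) / d + 2) else 60 * ((r - g) / d + 4)
  h <- h_deg / 2
  best <- -1L; bestd <- Inf
  for (k in seq_len(nrow(table))) {
    ctr <- table$hue_deg[k] / 2
    dd <- abs(h - ctr) %% 180
    dd <- min(dd, 180 - dd)
    if (dd < bestd - 1e-12) { bestd <- dd; best <- table$class_id[k] }
  }
  if (bestd > rule$half_width_units) -1L else as.integer(best)
}

oracle_classify_image <- function(img, rule = hue_band_rule()) {
  if (max(img) <= 1) img <- img * 255
  out <- matrix(-1L, nrow(img), ncol(img))
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      out[i, j] <- oracle_classify_rgb(img[i, j, 1], img[i, j, 2], img[i, j, 3],
                                       rule)
  out
}

oracle_cells <- function(pred_img, gt_img, cid, rule = hue_band_rule()) {
  p <- oracle_classify_image(pred_img, rule) == cid
  g <- oracle_classify_image(gt_img, rule) == cid
  c(tp = sum(p & g), tn = sum(!p & !g), fp = sum(p & !g), fn = sum(!p & g))
}

# even-odd point-in-polygon for a single pixel center
oracle_point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]; xj <- verts[j, 1]; yj <- verts[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# sweep-based AUC approximation recomputed from first principles
oracle_mauc <- function(pred_img, gt_img, cid, rule = hue_band_rule(),
                        widths = seq(0, 90, by = 6)) {
  g <- oracle_classify_image(gt_img, rule) == cid
  if (!any(g)) return(NA_real_)
  fpr <- tpr <- numeric(length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    p <- if (w <= 0) matrix(FALSE, nrow(g), ncol(g))
         else oracle_classify_image(pred_img,
                hue_band_rule(w, rule$min_saturation, rule$min_value)) == cid
    fpr[k] <- sum(p & !g) / max(1, sum(!g))
    tpr[k] <- sum(p & g) / sum(g)
  }
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  o <- order(fpr, tpr); fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# a random small RGB image mixing exact class colors, black and noise
random_label_image <- function(h = 8, w = 8, classes = 0:6, p_color = 0.5) {
  tab <- lesion_color_table()
  img <- array(0, dim = c(h, w, 3))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    u <- runif(1)
    if (u < p_color) {
      cid <- sample(classes, 1)
      img[i, j, ] <- unlist(tab[tab$class_id == cid, c("r", "g", "b")]) / 255
    } else if (u < p_color + 0.2) {
      img[i, j, ] <- runif(3)
    } # else black
  }
  img
}

# paint a filled axis-aligned rectangle (row/col ranges, 1-based) in a class color
paint_rect <- function(img, rows, cols, cid, tab = lesion_color_table()) {
  col <- unlist(tab[tab$class_id == cid, c("r", "g", "b")]) / 255
  for (ch in 1:3) img[rows, cols, ch] <- col[ch]
  img
}

blank_image <- function(h = 16, w = 16) array(0, dim = c(h, w, 3))

tiny_scene_samples <- function(n, size = 32L, seed = 99L, ...) {
  cfg <- scene_config(image_size = c(size, size), seed = seed, ...)
  lapply(seq_len(n), function(i) generate_sample(cfg, i))
}

tiny_model <- function(seed = 1L, units = 1L, channels = c(4L, 4L, 6L, 6L, 8L)) {
  build_model(model_config(latent_dim = 8L, encoder_channels = channels,
                           residual_units_per_skip = units), seed = seed)
}
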