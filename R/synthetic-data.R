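# Synthetic laryngoscopy-like scenes.
#
# Each sample pairs an endoscopy-like photograph (dark reddish mucosa with a
# shaded circular "lumen" and speckle) with a ground-truth mask: lesion
# polygons painted in the exact seven canonical colors on black. The
# photograph carries a tinted copy of every lesion polygon so the mapping
# from image to mask is learnable. A configurable fraction of samples are
# "dummy" lesion-free images (all-black mask), which the training scheme uses
# as an explicit nothing-here class. Images are (H, W, 3) double arrays in
# [0, 1]; origin top-left, x rightward (columns), y downward (rows), pixel
# centers at (ix + 0.5, iy + 0.5), half-open polygon convention.

#' Scene generator configuration
#'
#' @param image_size `c(H, W)`, both divisible by 32. `c(384, 256)` matches
#'   the clinical frame geometry implied by per-image pixel totals of
#'   published confusion tables (H*W = 98,304); the default 256 x 256 keeps
#'   fixtures fast.
#' @param classes_per_image Integer range `c(min, max)` of lesion classes per
#'   non-dummy sample.
#' @param vertex_range Range of polygon vertex counts.
#' @param area_frac_range Range of per-lesion area as a fraction of the frame.
#' @param tint_strength How strongly a lesion's class color tints the
#'   photograph over the polygon (0 = invisible, 1 = painted solid).
#' @param speckle_sd Amplitude of the multiplicative speckle texture.
#' @param dummy_fraction Fraction of samples generated lesion-free.
#' @param seed Master seed; each sample derives its own RNG stream from
#'   `(seed, index)` so generation order does not matter.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(256, 256),
                         classes_per_image = c(1, 3),
                         vertex_range = c(5, 9),
                         area_frac_range = c(0.01, 0.06),
                         tint_strength = 0.55,
                         speckle_sd = 0.02,
                         dummy_fraction = 0.15,
                         seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size %% 32 == 0),
            dummy_fraction >= 0, dummy_fraction <= 1,
            tint_strength >= 0, tint_strength <= 1,
            classes_per_image[1] >= 1, classes_per_image[2] <= 7)
  structure(list(image_size = as.integer(image_size),
                 classes_per_image = as.integer(classes_per_image),
                 vertex_range = as.integer(vertex_range),
                 area_frac_range = area_frac_range,
                 tint_strength = tint_strength,
                 speckle_sd = speckle_sd,
                 dummy_fraction = dummy_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Deterministic per-sample seed below 2^31.
sample_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' Rasterize a filled polygon into an RGB mask
#'
#' Even-odd (crossing-parity) fill; a pixel belongs to the polygon when its
#' center `(ix + 0.5, iy + 0.5)` lies inside, which yields the half-open
#' convention for integer-aligned rectangles.
#'
#' @param vertices Two-column matrix of `(x, y)` vertex coordinates.
#' @param size `c(H, W)` canvas size.
#' @param color Length-3 RGB color in `[0, 1]` (or 0-255).
#' @return RGB array `H x W x 3`, black outside the polygon.
#' @export
rasterize_polygon <- function(vertices, size, color) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (max(color) > 1) color <- color / 255
  H <- size[1]; W <- size[2]
  out <- array(0, dim = c(H, W, 3))
  area2 <- abs(sum(vertices[, 1] * (vertices[c(2:nrow(vertices), 1), 2] -
                                      vertices[c(nrow(vertices), 1:(nrow(vertices) - 1)), 2])))
  if (area2 < 1e-9) {
    warning("degenerate polygon (zero area); returning empty mask")
    return(out)
  }
  inside <- polygon_inside(vertices, H, W)
  for (ch in 1:3) out[, , ch][inside] <- color[ch]
  out
}

# Crossing-parity point-in-polygon for all pixel centers at once.
polygon_inside <- function(vertices, H, W) {
  px <- rep(seq_len(W) - 0.5, each = H)   # column-major order: rows fastest
  py <- rep(seq_len(H) - 0.5, times = W)
  n <- nrow(vertices)
  inside <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = H, ncol = W)
}

# Draw one integer uniformly from [lo, hi] (safe when lo == hi, unlike
# sample() on a scalar).
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Random star-convex polygon with roughly the requested area.
random_polygon <- function(cfg, rng_unused = NULL) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  nv <- sample_range(cfg$vertex_range[1], cfg$vertex_range[2])
  frac <- runif(1, cfg$area_frac_range[1], cfg$area_frac_range[2])
  target_area <- frac * H * W
  r0 <- sqrt(target_area / pi)
  cx <- runif(1, r0 + 2, W - r0 - 2)
  cy <- runif(1, r0 + 2, H - r0 - 2)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- r0 * runif(nv, 0.65, 1.35)
  cbind(x = pmin(pmax(cx + rad * cos(ang), 1), W - 1),
        y = pmin(pmax(cy + rad * sin(ang), 1), H - 1))
}

# Endoscopy-like background: dark reddish mucosa, radial lumen shading,
# mild speckle.
scene_background <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  cx <- W / 2 + runif(1, -W / 10, W / 10)
  cy <- H / 2 + runif(1, -H / 10, H / 10)
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  r <- sqrt((x - cx)^2 + (y - cy)^2) / (0.6 * min(H, W))
  shade <- pmax(0, 1 - r^2)
  base <- c(0.55, 0.25, 0.22) * runif(1, 0.85, 1.15)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] * (0.35 + 0.65 * shade)
  if (cfg$speckle_sd > 0)
    img <- img * (1 + array(rnorm(H * W * 3, 0, cfg$speckle_sd), dim = dim(img)))
  pmin(pmax(img, 0), 1)
}

#' Generate one paired image/mask sample
#'
#' Deterministic given `(cfg, index)`: the sample's RNG stream is derived
#' from the master seed and the sample index.
#'
#' @param cfg A [scene_config()].
#' @param index Sample index (drives the per-sample RNG stream).
#' @param force_dummy Optional logical overriding the dummy draw.
#' @return A list of class `seg_sample` with `image`, `mask` (both
#'   `H x W x 3` in `[0, 1]`), `is_dummy`, `present_classes` and `index`.
#' @export
generate_sample <- function(cfg, index = 1L, force_dummy = NULL) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(sample_seed(cfg$seed, index))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  img <- scene_background(cfg)
  mask <- array(0, dim = c(H, W, 3))
  is_dummy <- if (is.null(force_dummy)) runif(1) < cfg$dummy_fraction else force_dummy
  present <- integer(0)
  if (!is_dummy) {
    tab <- lesion_color_table()
    k <- sample_range(cfg$classes_per_image[1], cfg$classes_per_image[2])
    present <- sort(sample(tab$class_id, k))
    occupied <- matrix(FALSE, H, W)
    for (cid in present) {
      col <- unlist(tab[tab$class_id == cid, c("r", "g", "b")]) / 255
      # lesions of different classes do not overlap in the labeling scheme;
      # retry placement so no earlier polygon is painted over
      for (try in 1:20) {
        poly <- random_polygon(cfg)
        pm <- rasterize_polygon(poly, c(H, W), col)
        hit <- pm[, , 1] + pm[, , 2] + pm[, , 3] > 0  # no class color is black
        if (!any(hit & occupied)) break
      }
      occupied <- occupied | hit
      # paint mask with the exact color; tint the photograph
      tau <- cfg$tint_strength * runif(1, 0.85, 1.1)
      tau <- min(tau, 1)
      for (ch in 1:3) {
        m <- mask[, , ch]; m[hit] <- col[ch]; mask[, , ch] <- m
        im <- img[, , ch]; im[hit] <- (1 - tau) * im[hit] + tau * col[ch]
        img[, , ch] <- im
      }
    }
    # recompute presence from the painted mask (later polygons may occlude)
    present <- sort(unique(as.integer(classify_image(mask))))
    present <- present[present >= 0]
    if (length(present) == 0L) is_dummy <- TRUE
  }
  structure(list(image = img, mask = mask, is_dummy = is_dummy,
                 present_classes = present, index = index),
            class = "seg_sample")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a dataset on disk
#'
#' Writes paired PNGs under `out_dir/images` and `out_dir/masks` plus a
#' manifest CSV (`split, image_path, mask_path, is_dummy, classes`). The
#' train/test split is disjoint and exhaustive: the first `split[1]` samples
#' are train, the rest test.
#'
#' @param cfg A [scene_config()].
#' @param n Total number of samples.
#' @param split `c(train, test)` with `train + test = n`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(cfg, n, split = c(round(0.8 * n), n - round(0.8 * n)),
                             out_dir) {
  stopifnot(sum(split) == n)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(cfg, i)
    ip <- file.path("images", sprintf("sample_%04d.png", i))
    mp <- file.path("masks", sprintf("sample_%04d.png", i))
    png::writePNG(s$image, file.path(out_dir, ip))
    png::writePNG(s$mask, file.path(out_dir, mp))
    rows[[i]] <- data.frame(
      split = if (i <= split[1]) "train" else "test",
      image_path = ip, mask_path = mp, is_dummy = s$is_dummy,
      classes = paste(s$present_classes, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Random affine distortion of an image
#'
#' Rotation, translation and shear about the image center, sampled uniformly
#' within the given bounds; resampling is nearest-neighbour with
#' clamp-to-edge (border color) padding. All-zero bounds give the identity.
#'
#' @param image `H x W x C` array.
#' @param max_rotation Max absolute rotation in degrees.
#' @param max_translate Max absolute translation as a fraction of each dim.
#' @param max_shear Max absolute shear in degrees.
#' @return Distorted image, same shape.
#' @export
apply_random_affine <- function(image, max_rotation = 15, max_translate = 0.1,
                                max_shear = 5) {
  d <- dim(image)
  affine_transform(image,
                   rotation = runif(1, -max_rotation, max_rotation),
                   translate = c(runif(1, -max_translate, max_translate) * d[2],
                                 runif(1, -max_translate, max_translate) * d[1]),
                   shear = runif(1, -max_shear, max_shear))
}

#' Deterministic affine distortion
#'
#' The transform behind [apply_random_affine()]: shear, then rotation, then
#' translation, all about the image center `((W-1)/2, (H-1)/2)` in 0-based
#' pixel coordinates, resampled nearest-neighbour with clamp-to-edge padding.
#'
#' @param image `H x W x C` array.
#' @param rotation Rotation in degrees.
#' @param translate `c(tx, ty)` translation in pixels.
#' @param shear Shear in degrees.
#' @return Transformed image, same shape.
#' @export
affine_transform <- function(image, rotation = 0, translate = c(0, 0),
                             shear = 0) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  th <- rotation * pi / 180
  sh <- tan(shear * pi / 180)
  tx <- translate[1]; ty <- translate[2]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  A <- R %*% S
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Ainv <- solve(A)
  ix <- rep(seq_len(W) - 1, each = H)
  iy <- rep(seq_len(H) - 1, times = W)
  sx <- Ainv[1, 1] * (ix - cx - tx) + Ainv[1, 2] * (iy - cy - ty) + cx
  sy <- Ainv[2, 1] * (ix - cx - tx) + Ainv[2, 2] * (iy - cy - ty) + cy
  # nearest neighbour, clamped to the border
  sxi <- pmin(pmax(round(sx), 0), W - 1) + 1
  syi <- pmin(pmax(round(sy), 0), H - 1) + 1
  out <- array(0, dim = d)
  idx <- cbind(syi, sxi)
  for (ch in seq_len(d[3])) out[, , ch] <- matrix(image[, , ch][idx], H, W)
  out
}

#' Mix Gaussian noise into an image
#'
#' Adds i.i.d. `N(0, sigma^2)` noise and clamps to `[0, 1]`. `sigma` is on
#' the image's own `[0, 1]` scale (so `sigma = 1` corresponds to 255 on an
#' 8-bit scale); `sigma = 0` is the identity.
#'
#' @param image `H x W x C` array in `[0, 1]`.
#' @param sigma Noise standard deviation, `>= 0`.
#' @return Noisy image, same shape, clamped to `[0, 1]`.
#' @export
mix_gaussian_noise <- function(image, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(image)
  pmin(pmax(image + array(rnorm(length(image), 0, sigma), dim = dim(image)), 0), 1)
}
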