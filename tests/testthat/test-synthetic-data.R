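# Synthetic laryngoscopy-like scenes: rasterisation, determinism, corruptions.

test_that("rasterize_polygon fills with the half-open pixel-center rule", {
  rect <- cbind(c(10, 20, 20, 10), c(10, 10, 15, 15))
  pm <- rasterize_polygon(rect, c(32, 32), c(1, 0, 0))
  expect_identical(sum(pm[, , 1] > 0), 50L)  # 10 x 5
  expect_warning(z <- rasterize_polygon(cbind(c(1, 5, 9), c(1, 5, 9)),
                                        c(16, 16), c(1, 0, 0)),
                 "degenerate")
  expect_true(all(z == 0))
})

test_that("random convex polygons match the point-in-polygon oracle", {
  set.seed(7)
  for (rep in 1:3) {
    ang <- sort(runif(5, 0, 2 * pi))
    verts <- cbind(8 + 5 * cos(ang), 8 + 5 * sin(ang))
    pm <- rasterize_polygon(verts, c(16, 16), c(1, 0, 1))
    painted <- pm[, , 1] > 0
    for (i in 1:16) for (j in 1:16) {
      expect_identical(painted[i, j],
                       oracle_point_in_polygon(j - 0.5, i - 0.5, verts))
    }
  }
})

test_that("generate_sample is deterministic and honours its config", {
  cfg <- scene_config(image_size = c(64, 64), seed = 5)
  s1 <- generate_sample(cfg, 9)
  s2 <- generate_sample(cfg, 9)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  # dummy_fraction = 1 -> every mask all-black
  cfg_d <- scene_config(image_size = c(64, 64), dummy_fraction = 1, seed = 5)
  for (i in 1:3) {
    s <- generate_sample(cfg_d, i)
    expect_true(s$is_dummy)
    expect_true(all(s$mask == 0))
    expect_length(s$present_classes, 0)
  }
  # fixed classes_per_image -> present set has that size
  cfg2 <- scene_config(image_size = c(64, 64), classes_per_image = c(2, 2),
                       dummy_fraction = 0, seed = 6)
  for (i in 1:4) {
    s <- generate_sample(cfg2, i)
    ids <- larynet:::classify_image(s$mask)
    expect_identical(sort(unique(ids[ids >= 0])), s$present_classes)
    expect_length(s$present_classes, 2)
  }
})

test_that("generated mask pixels are exact table colors on black", {
  cfg <- scene_config(image_size = c(64, 64), dummy_fraction = 0, seed = 3)
  tab <- lesion_color_table()
  s <- generate_sample(cfg, 2)
  px <- unique(round(matrix(s$mask, ncol = 3) * 255))
  for (k in seq_len(nrow(px))) {
    r <- px[k, ]
    expect_true(all(r == 0) ||
                any(tab$r == r[1] & tab$g == r[2] & tab$b == r[3]))
  }
})

test_that("generate_dataset writes a disjoint, exhaustive, reproducible split", {
  dir1 <- withr::local_tempdir()
  cfg <- scene_config(image_size = c(32, 32), seed = 21)
  man <- generate_dataset(cfg, 10, c(8, 2), dir1)
  expect_identical(nrow(man), 10L)
  expect_identical(sum(man$split == "train"), 8L)
  expect_identical(sum(man$split == "test"), 2L)
  expect_length(intersect(man$image_path[man$split == "train"],
                          man$image_path[man$split == "test"]), 0)
  expect_true(all(file.exists(file.path(dir1, man$image_path))))
  expect_error(generate_dataset(cfg, 10, c(9, 2), dir1))
  # same seed -> byte-identical files
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, 10, c(8, 2), dir2)
  h1 <- tools::md5sum(file.path(dir1, man$image_path))
  h2 <- tools::md5sum(file.path(dir2, man$image_path))
  expect_identical(unname(h1), unname(h2))
})

test_that("random affine bounds of zero give the identity", {
  img <- tiny_scene_samples(1, size = 32)[[1]]$image
  expect_identical(apply_random_affine(img, 0, 0, 0), img)
})

test_that("a 180-degree rotation maps a symmetric disk onto itself", {
  H <- 33
  img <- array(0, dim = c(H, H, 3))
  ctr <- (H - 1) / 2
  for (i in 1:H) for (j in 1:H)
    if ((i - 1 - ctr)^2 + (j - 1 - ctr)^2 <= 100) img[i, j, ] <- 1
  rot <- affine_transform(img, rotation = 180)
  expect_identical(rot, img)
})

test_that("random affine is reproducible under a fixed seed", {
  img <- tiny_scene_samples(1, size = 32)[[1]]$image
  set.seed(12); a1 <- apply_random_affine(img)
  set.seed(12); a2 <- apply_random_affine(img)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
})

test_that("gaussian noise mixing is clamped, seeded and info-destroying", {
  img <- tiny_scene_samples(1, size = 64, seed = 2)[[1]]$image
  expect_identical(mix_gaussian_noise(img, 0), img)
  set.seed(5); n1 <- mix_gaussian_noise(img, 0.5)
  set.seed(5); n2 <- mix_gaussian_noise(img, 0.5)
  expect_identical(n1, n2)
  expect_true(min(n1) >= 0 && max(n1) <= 1)
  # sigma at four times the full dynamic range wipes the content
  set.seed(6); big <- mix_gaussian_noise(img, 4)
  expect_lt(abs(cor(as.vector(img), as.vector(big))), 0.1)
  expect_error(mix_gaussian_noise(img, -1))
})
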