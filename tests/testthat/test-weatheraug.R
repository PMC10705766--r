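test_that("fog with zero concentration is the identity", {
  img <- flat_image(100, 8)
  out <- add_fog(img, fog_params(L = 200, theta0 = 0))
  expect_identical(out$pixels, img$pixels)
})

test_that("fog matches the scalar hand evaluation on a 4x4 grey image", {
  img <- flat_image(100, 4)
  out <- add_fog(img, fog_params(L = 200, theta0 = -0.25))
  # centre pixel (0-based i=j=2): d = size = 4, td = exp(-1)
  expect_equal(out$pixels[3, 3, 1], 163)
  td <- exp(-1)
  expect_equal(out$pixels[3, 3, 2], floor(td * 100 + (1 - td) * 200 + 0.5))
})

test_that("fogged pixels are convex combinations bounded by L", {
  set.seed(4)
  img <- annotated_image(array(round(runif(12 * 12 * 3, 0, 255)),
                               dim = c(12, 12, 3)))
  out <- add_fog(img, fog_params(L = 220, theta0 = -0.1))
  lo <- pmin(img$pixels, 220) - 1  # rounding slack
  hi <- pmax(img$pixels, 220) + 1
  expect_true(all(out$pixels >= lo & out$pixels <= hi))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
})

test_that("fog is monotone in |theta0|: every pixel moves weakly toward L", {
  img <- flat_image(80, 10)
  L <- 210
  prev <- img$pixels
  for (th in c(-0.02, -0.05, -0.1, -0.2)) {
    out <- add_fog(img, fog_params(L = L, theta0 = th))$pixels
    expect_true(all(abs(L - out) <= abs(L - prev) + 1))  # rounding slack
    prev <- out
  }
})

test_that("fog parameters are validated and clamped", {
  expect_error(fog_params(L = 300), "255")
  expect_warning(p <- fog_params(theta0 = 0.5), "clamping")
  expect_equal(p$theta0, 0)
})

test_that("precipitation: zero density is identity, same seed is bit-identical", {
  img <- flat_image(90, 32)
  expect_identical(add_precipitation(img, precip_params("rain",
                                                        density = 0)),
                   img)
  p <- precip_params("rain", seed = 11)
  a <- add_precipitation(img, p)
  b <- add_precipitation(img, p)
  expect_identical(a$pixels, b$pixels)
  # rain at this density must actually add something
  expect_gt(sum(a$pixels), sum(img$pixels))
  # a different seed gives a different particle field
  c2 <- add_precipitation(img, precip_params("rain", seed = 12))
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("rain and snow presets keep rasters valid and boxes untouched", {
  img <- generate_scene(scene_params(image_size = 128, n_sheep = 4,
                                     n_aggression = 1, seed = 2))
  for (kind in c("rain", "snow")) {
    out <- add_precipitation(img, precip_params(kind, seed = 5))
    expect_true(all(out$pixels >= 0 & out$pixels <= 255))
    expect_identical(out$boxes, img$boxes)
  }
})

test_that("mirroring transforms boxes by coordinate reflection", {
  img <- generate_scene(scene_params(image_size = 96, n_sheep = 2,
                                     n_aggression = 1, seed = 8))
  b <- img$boxes[1, ]
  h <- mirror(img, "horizontal")$boxes[1, ]
  expect_equal(h$cx, 1 - b$cx)
  expect_equal(h$cy, b$cy)
  expect_equal(c(h$bw, h$bh), c(b$bw, b$bh))
  v <- mirror(img, "vertical")$boxes[1, ]
  expect_equal(v$cy, 1 - b$cy)
  d <- mirror(img, "diagonal")$boxes[1, ]
  expect_equal(c(d$cx, d$cy), c(1 - b$cx, 1 - b$cy))
  expect_error(mirror(img, "sideways"))
})

test_that("every mirror mode is an involution on pixels and boxes", {
  img <- generate_scene(scene_params(image_size = 96, n_sheep = 3,
                                     n_aggression = 1, seed = 13))
  for (mode in c("horizontal", "vertical", "diagonal")) {
    back <- mirror(mirror(img, mode), mode)
    expect_identical(back$pixels, img$pixels)
    expect_equal(back$boxes, img$boxes)
  }
})

test_that("mirror box algebra matches the corner-transform oracle on 1000 boxes", {
  set.seed(77)
  px <- array(128, dim = c(8, 8, 3))
  for (rep in 1:1000) {
    b <- data.frame(class = 0L,
                    cx = runif(1, 0.1, 0.9), cy = runif(1, 0.1, 0.9),
                    bw = runif(1, 0.02, 0.2), bh = runif(1, 0.02, 0.2))
    mode <- sample(c("horizontal", "vertical", "diagonal"), 1)
    got <- mirror(annotated_image(px, b), mode)$boxes
    want <- mirror_box_oracle(b, mode)
    expect_equal(as.numeric(got[1, c("cx", "cy", "bw", "bh")]),
                 as.numeric(want[1, c("cx", "cy", "bw", "bh")]),
                 tolerance = 1e-12)
  }
})

test_that("rotation-scaling: identity, quarter-turn algebra, scaling", {
  img <- generate_scene(scene_params(image_size = 96, n_sheep = 2,
                                     n_aggression = 1, seed = 21))
  same <- rotate_scale(img, 0, 1)
  expect_identical(same$pixels, img$pixels)
  expect_equal(same$boxes, img$boxes)
  b <- img$boxes[1, ]
  q <- rotate_scale(img, 90, 1)$boxes[1, ]
  expect_equal(as.numeric(q[c("cx", "cy", "bw", "bh")]),
               c(b$cy, 1 - b$cx, b$bh, b$bw), tolerance = 1e-8)
  # small centred box: scale 2 doubles extents before clipping
  ctr <- annotated_image(img$pixels,
                         data.frame(class = 0L, cx = 0.5, cy = 0.5,
                                    bw = 0.1, bh = 0.2))
  z <- rotate_scale(ctr, 0, 2)$boxes[1, ]
  expect_equal(c(z$bw, z$bh), c(0.2, 0.4), tolerance = 1e-8)
  expect_error(rotate_scale(img, 10, 0), "scale")
})

test_that("boxes pushed almost entirely out of frame are dropped", {
  px <- array(100, dim = c(64, 64, 3))
  edge <- annotated_image(px, data.frame(class = 0L, cx = 0.95, cy = 0.5,
                                         bw = 0.08, bh = 0.08))
  out <- rotate_scale(edge, 0, 3)   # centre maps to x = 1.85: fully outside
  expect_equal(nrow(out$boxes), 0)
})

test_that("box transforms are resolution independent", {
  b <- data.frame(class = 0L, cx = 0.3, cy = 0.6, bw = 0.2, bh = 0.1)
  small <- annotated_image(array(100, dim = c(32, 32, 3)), b)
  large <- annotated_image(array(100, dim = c(128, 128, 3)), b)
  for (mode in c("horizontal", "vertical", "diagonal"))
    expect_equal(mirror(small, mode)$boxes, mirror(large, mode)$boxes)
  expect_equal(rotate_scale(small, 35, 1.2)$boxes,
               rotate_scale(large, 35, 1.2)$boxes)
})

test_that("dataset augmentation drives a seeded random half", {
  imgs <- lapply(1:20, function(i)
    generate_scene(scene_params(image_size = 96, n_sheep = 3,
                                n_aggression = 1, seed = 200 + i)))
  expect_identical(augment_dataset(imgs, fraction = 0), imgs)
  aug <- augment_dataset(imgs, fraction = 0.5, seed = 3)
  expect_length(aug, 20)
  changed <- sum(!mapply(identical, aug, imgs))
  expect_equal(changed, 10)
  aug2 <- augment_dataset(imgs, fraction = 0.5, seed = 3)
  expect_identical(aug, aug2)
  kept <- augment_dataset(imgs, fraction = 0.5, seed = 3,
                          keep_originals = TRUE)
  expect_length(kept, 30)
  expect_identical(kept[1:20], imgs)
})

test_that("augmented images remain valid rasters with valid boxes", {
  imgs <- lapply(1:10, function(i)
    generate_scene(scene_params(image_size = 96, n_sheep = 4,
                                n_aggression = 2, seed = 300 + i)))
  aug <- augment_dataset(imgs, fraction = 1, seed = 9)
  for (im in aug) {
    expect_true(all(im$pixels >= 0 & im$pixels <= 255))
    if (nrow(im$boxes) > 0) {
      expect_true(all(im$boxes$cx >= 0 & im$boxes$cx <= 1))
      expect_true(all(im$boxes$bw > 0 & im$boxes$bh > 0))
    }
  }
})
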