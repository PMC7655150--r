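avg_lightness <- function(img) mean(vitalcam:::rgb_to_hsl(img / 255)[, , 3])

test_that("lighting model recovers interval centroids of a uniform corpus", {
  corpus <- lapply(seq(0.0125, 0.9875, length.out = 80),
                   function(l) array(l * 255, c(4, 4, 3)))
  lm <- fit_lighting_model(corpus)
  expect_equal(lm$interval_means, c(0.125, 0.375, 0.625, 0.875),
               tolerance = 0.02)
  expect_true(all(diff(lm$interval_means) > 0))
})

test_that("degenerate corpora are rejected; sparse corpora use the edge rule", {
  corpus <- replicate(5, array(128, c(4, 4, 3)), simplify = FALSE)
  expect_error(fit_lighting_model(corpus), "degenerate")
  # two images at lightness 0.2 and 0.8: edges at 0.2 + k * 0.15, empty
  # middle intervals fall back to their midpoints
  two <- lapply(c(0.2, 0.8), function(l) array(l * 255, c(4, 4, 3)))
  lm <- fit_lighting_model(two)
  expect_equal(lm$edges, seq(0.2, 0.8, length.out = 5), tolerance = 1e-6)
  expect_equal(lm$interval_means[2:3], c(0.425, 0.575), tolerance = 1e-6)
})

test_that("lighting variants hit the interval-2..4 target means", {
  corpus <- lapply(seq(0.05, 0.85, length.out = 40),
                   function(l) array(l * 255, c(4, 4, 3)))
  lm <- fit_lighting_model(corpus)
  withr::with_seed(3, img <- array(runif(16 * 16 * 3) * 120 + 20,
                                   c(16, 16, 3)))
  lv <- lighting_variants(img, lm)
  expect_length(lv, 3)
  got <- vapply(lv, avg_lightness, 0)
  expect_equal(got, lm$interval_means[2:4], tolerance = 0.02)
  # scaling is the ratio of means: an image whose average lightness
  # already equals the interval-2 mean is returned unchanged there
  flat <- array(lm$interval_means[2] * 255, c(8, 8, 3))
  v <- lighting_variants(flat, lm)
  expect_equal(avg_lightness(v[[1]]), lm$interval_means[2],
               tolerance = 1e-6)
})

test_that("geometric variants: 7 rotations + 2 mirrors on the same canvas", {
  withr::with_seed(4, {
    img <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
    mask <- matrix(rbinom(1024, 1, 0.3), 32)
  })
  gv <- geometric_variants(img, mask)
  expect_length(gv$images, 9)
  expect_length(grep("^rot", names(gv$images)), 7)
  expect_length(grep("^mirror", names(gv$images)), 2)
  expect_true(all(vapply(gv$images, function(x)
    identical(dim(x)[1:2], c(32L, 32L)), TRUE)))
  # masks stay binary under the identical transform
  expect_true(all(vapply(gv$masks, function(m) all(m %in% 0:1), TRUE)))
  # total deterministic variants per original: 3 lighting + 7 + 2 = 12
  corpus <- lapply(seq(0.1, 0.9, length.out = 10),
                   function(l) array(l * 255, c(8, 8, 3)))
  lm <- fit_lighting_model(corpus)
  expect_equal(length(lighting_variants(img, lm)) + length(gv$images), 12)
})

test_that("four 90-degree rotations compose to the identity", {
  m <- matrix(0, 32, 32)
  m[5:12, 3:20] <- 1
  r <- m
  for (i in 1:4) r <- geometric_variants(r)$images$rot90
  expect_equal(r, m)
})

test_that("rotation without resizing requires square input", {
  expect_error(geometric_variants(array(0, c(16, 20, 3))), "square")
})

test_that("mask augmentation commutes with image augmentation", {
  withr::with_seed(9, {
    mask <- matrix(0L, 32, 32)
    mask[8:20, 10:25] <- 1L
    img <- array(0, c(32, 32, 3))
    for (c in 1:3) img[, , c] <- mask * 200
  })
  cfg <- augment_preset("intervention_net")
  j <- random_jitter(img, cfg, rng_seed = 7, mask = mask)
  # transforming the mask as an image gives the same pixels
  as_img <- apply(j$image, c(1, 2), max) > 100
  expect_gt(mean((j$mask > 0) == as_img), 0.98)
})

test_that("random jitter is reproducible and the null config is identity", {
  img <- array(seq_len(16 * 16 * 3), c(16, 16, 3))
  null_cfg <- jitter_config(0, c(1, 1), c(0, 0), FALSE)
  expect_identical(random_jitter(img, null_cfg, 1)$image, img)
  cfg <- augment_preset("skin_net")
  a <- random_jitter(img, cfg, rng_seed = 42)
  b <- random_jitter(img, cfg, rng_seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$params, b$params)
})

test_that("jitter scale draws follow the configured uniform range", {
  cfg <- augment_preset("skin_net")
  withr::with_seed(10, {
    draws <- replicate(10000, {
      p <- random_jitter(matrix(0, 2, 2), cfg)$params
      p$s
    })
  })
  expect_gte(min(draws), 0.90)
  expect_lte(max(draws), 1.10)
  expect_equal(mean(draws), 1.0, tolerance = 0.005)
  # intervention preset ranges
  icfg <- augment_preset("intervention_net")
  expect_equal(icfg$scale_range, c(1.00, 1.25))
  expect_equal(icfg$rotate_range, c(-45, 45))
  expect_true(icfg$mirror)
})
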