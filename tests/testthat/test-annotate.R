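test_that("graph-cut segmentation recovers a two-tone disk", {
  tt <- two_tone_disk(24, 7)
  seeds <- seed_set(skin = cbind(c(12, 13, 11), c(13, 12, 14)),
                    nonskin = cbind(c(2, 3, 22), c(2, 20, 3)))
  lab <- gsc_segment(tt$image, seeds)
  # brute-force two-region oracle: nearest seed-class mean color
  X <- vitalcam:::pixel_colors(tt$image)
  mu_s <- colMeans(X[c(12 + 12 * 24, 13 + 11 * 24, 11 + 13 * 24), ])
  mu_n <- colMeans(X[c(2 + 1 * 24, 3 + 19 * 24, 22 + 2 * 24), ])
  oracle <- matrix(as.integer(colSums((t(X) - mu_s)^2) <
                                colSums((t(X) - mu_n)^2)), 24)
  expect_lte(mean(lab != oracle), 0.01)
  expect_lte(mean(lab != tt$disk), 0.01)
})

test_that("seeding every pixel reproduces the seeding exactly", {
  tt <- two_tone_disk(16, 5)
  allpix <- which(matrix(TRUE, 16, 16), arr.ind = TRUE)
  seeds <- seed_set(skin = allpix[c(tt$disk), ],
                    nonskin = allpix[!c(tt$disk), ])
  lab <- gsc_segment(tt$image, seeds)
  expect_identical(lab == 1, tt$disk)
})

test_that("output regions are geodesic-star-convex", {
  tt <- two_tone_disk(24, 7)
  seeds <- seed_set(skin = cbind(12, 13), nonskin = cbind(c(2, 22), c(2, 3)))
  lab <- gsc_segment(tt$image, seeds)
  gray <- (tt$image[, , 1] + tt$image[, , 2] + tt$image[, , 3]) / (3 * 255)
  geo <- vitalcam:::cpp_geodesic_parents(vitalcam:::grad_magnitude(gray),
                                         as.integer(12 + 12 * 24), 20)
  # walking from any skin pixel towards the star center stays in skin
  for (p in which(lab == 1)) {
    q <- p
    while (geo$parent[q] > 0) {
      q <- geo$parent[q]
      expect_equal(lab[q], 1L)
    }
  }
})

test_that("without smoothness or shape terms the cut is pixelwise", {
  # 4x4 two-color image: the zero-smoothness cut must equal per-pixel
  # likelihood classification
  img <- array(0, c(4, 4, 3))
  cls <- matrix(c(1, 1, 0, 0), 4, 4)
  for (c in 1:3)
    img[, , c] <- ifelse(cls > 0, c(200, 140, 110)[c], c(30, 60, 140)[c])
  seeds <- seed_set(skin = cbind(1, 1), nonskin = cbind(3, 1))
  lab <- gsc_segment(img, seeds,
                     gsc_params(lambda = 0, star = FALSE, k_components = 1))
  expect_equal(lab, cls + 0L)
})

test_that("empty seed classes and disjointness are enforced", {
  expect_error(seed_set(cbind(1, 1), matrix(0, 0, 2)), "non-empty")
  expect_error(seed_set(cbind(1, 1), cbind(1, 1)), "disjoint")
})

test_that("color models learn flat colors and score membership", {
  tt <- two_tone_disk(20, 6)
  model <- fit_color_models(tt$image, tt$disk + 0L, k_components = 1)
  expect_equal(model$skin$means[1, ], c(220, 150, 120) / 255,
               tolerance = 0.01)
  expect_equal(model$nonskin$means[1, ], c(40, 60, 150) / 255,
               tolerance = 0.01)
  p <- skin_probability(model, tt$image)
  expect_gt(mean(p[tt$disk]), 0.99)
  expect_lt(mean(p[!tt$disk]), 0.01)
  # more components than labeled pixels is an error
  tiny_label <- matrix(0L, 20, 20)
  tiny_label[10, 10] <- 1L
  expect_error(fit_color_models(tt$image, tiny_label, k_components = 5),
               "components")
})

test_that("propagated seeds reproduce the previous label on a still frame", {
  tt <- two_tone_disk(24, 7)
  model <- fit_color_models(tt$image, tt$disk + 0L, k_components = 2)
  seeds <- propose_seeds(tt$image, model, n_seeds = 12, rng_seed = 3)
  lab <- gsc_segment(tt$image, seeds)
  expect_lte(mean((lab == 1) != tt$disk), 0.02)
  # reproducible by seed
  s2 <- propose_seeds(tt$image, model, n_seeds = 12, rng_seed = 3)
  expect_identical(seeds$skin, s2$skin)
  expect_error(propose_seeds(tt$image * 0, model, rng_seed = 1),
               "confidence floor")
})

test_that("best-candidate sampling spreads seeds wider than uniform", {
  pool <- which(matrix(TRUE, 40, 40), arr.ind = TRUE)
  min_pair_dist <- function(pts)
    min(dist(pts))
  withr::with_seed(5, {
    mit <- replicate(100, min_pair_dist(mitchell_sample(pool, 8, 10)))
    unif <- replicate(100, min_pair_dist(pool[sample.int(1600, 8), ]))
  })
  expect_gt(mean(mit), mean(unif))
})

test_that("consensus follows the pixel and image quorums", {
  A <- matrix(0L, 3, 3); A[1, 1] <- 1L; A[2, 2] <- 1L
  B <- A
  C <- matrix(0L, 3, 3); C[2, 2] <- 1L; C[3, 3] <- 1L
  cc <- combine_annotations(list(A, B, C))
  # brute-force enumeration of the 2-of-3 rule
  votes <- A + B + C
  expect_identical(cc, (votes >= 2) + 0L)
  expect_identical(combine_annotations(list(A, A, A)), A)
  # permutation invariance
  expect_identical(combine_annotations(list(C, A, B)), cc)
  # two skips make the image negative
  expect_null(combine_annotations(list(A, NULL, NULL)))
  expect_error(combine_annotations(list(A, matrix(0L, 2, 2), C)), "grids")
})

test_that("agreement is the 2-vote/1-vote set ratio", {
  A <- matrix(0L, 3, 3); A[1, 1] <- 1L; A[2, 2] <- 1L   # {p1, p2}
  B <- A
  C <- matrix(0L, 3, 3); C[2, 2] <- 1L; C[3, 3] <- 1L   # {p2, p3}
  expect_equal(agreement_score(list(A, B, C)), 2 / 3)
  expect_equal(agreement_score(list(A, A, A)), 1)
  D1 <- matrix(0L, 3, 3); D1[1, 1] <- 1L
  D2 <- matrix(0L, 3, 3); D2[2, 2] <- 1L
  D3 <- matrix(0L, 3, 3); D3[3, 3] <- 1L
  expect_equal(agreement_score(list(D1, D2, D3)), 0)
  # empty union is defined as 1
  Z <- matrix(0L, 3, 3)
  expect_equal(agreement_score(list(Z, Z, Z)), 1)
  # making labels more similar never lowers agreement
  s0 <- agreement_score(list(A, B, C))
  C2 <- C; C2[1, 1] <- 1L   # C moves towards A/B
  expect_gte(agreement_score(list(A, B, C2)), s0)
})
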