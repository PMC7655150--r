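# Independent scalar oracles for the two losses, written as plain loops.
oracle_det_loss <- function(p_true) -log(max(p_true, 1e-12))
oracle_seg_loss <- function(map, truth) {
  n_skin <- 0; n_total <- 0
  for (v in c(truth)) {
    n_total <- n_total + 1
    if (v > 0) n_skin <- n_skin + 1
  }
  acc <- 0
  for (i in seq_len(nrow(map)))
    for (j in seq_len(ncol(map))) {
      p <- if (truth[i, j] > 0) map[i, j] else 1 - map[i, j]
      w <- if (n_skin == 0 || n_skin == n_total) 1 / n_total
      else if (truth[i, j] > 0) 1 / (2 * n_skin)
      else 1 / (2 * (n_total - n_skin))
      acc <- acc + w * -log(max(p, 1e-12))
    }
  acc
}

test_that("network geometry follows the subsampling-by-32 arithmetic", {
  cfg <- skinnet_config("tiny", 64)
  net <- build_skinnet(cfg)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  core <- vitalcam:::skin_core_fw(net, x)
  expect_equal(dim(core$taps$pool5)[1:2], c(2, 2))   # 64 / 32
  seg <- vitalcam:::seg_head_fw(net, core$out, core$taps)
  expect_equal(dim(seg$probs)[1:2], c(64, 64))       # back to input size
  # the full-resolution topology: 512 input -> 16x16 coarsest grid
  plan <- vitalcam:::skinnet_plan(skinnet_config("vgg16", 512))
  expect_equal(plan$n_convs, c(2, 2, 3, 3, 3))
  expect_equal(512 / 2^length(plan$n_convs), 16)
  expect_error(skinnet_config("tiny", 100), "divisible by 32")
})

test_that("forward produces normalized scores and conditional segmentation", {
  withr::with_seed(8, {
    net <- build_skinnet(skinnet_config("tiny", 64))
    frame <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  })
  fw <- skinnet_forward(net, frame)
  expect_equal(sum(fw$score), 1, tolerance = 1e-9)
  # per-pixel softmax normalizes
  x <- vitalcam:::center_input(net, list(frame))
  core <- vitalcam:::skin_core_fw(net, x)
  seg <- vitalcam:::seg_head_fw(net, core$out, core$taps)
  expect_equal(max(abs(seg$probs[, , 1, 1] + seg$probs[, , 2, 1] - 1)), 0,
               tolerance = 1e-9)
  # conditional execution: the counter advances exactly when a map is made
  n0 <- net$n_seg_evals
  thr <- fw$score[["present"]]
  net$cfg$detection_threshold <- (thr + 1) / 2   # strictly above p_present
  fw_absent <- skinnet_forward(net, frame)
  expect_null(fw_absent$map)
  expect_equal(net$n_seg_evals, n0)
  net$cfg$detection_threshold <- thr / 2         # strictly below p_present
  fw_present <- skinnet_forward(net, frame)
  expect_false(is.null(fw_present$map))
  expect_equal(net$n_seg_evals, n0 + 1L)
  expect_equal(dim(fw_present$map), c(64, 64))
})

test_that("threshold_map applies the elementwise rule", {
  expect_equal(threshold_map(matrix(0.6, 3, 3), 0.5), matrix(1L, 3, 3))
  expect_equal(threshold_map(matrix(0.4, 3, 3), 0.5), matrix(0L, 3, 3))
  checker <- matrix(c(0.3, 0.7), 4, 4)
  expect_equal(threshold_map(checker, 0.5), (checker >= 0.5) + 0L)
  expect_error(threshold_map(matrix(0.5, 2, 2), 1.5), "theta")
})

test_that("detection loss matches its closed form", {
  expect_equal(detection_loss(c(0, 1), "present"), 0)
  expect_equal(detection_loss(c(0.5, 0.5), "present"), log(2))
  expect_equal(detection_loss(c(0.9, 0.1), "present"), -log(0.1))
  expect_lt(detection_loss(c(1, 0), "present"), -log(1e-13)) # clamped
  expect_error(detection_loss(c(0.2, 0.2), "present"), "probability")
})

test_that("balanced segmentation loss matches the scalar oracle", {
  # hand-computed: 4 pixels (3 non-skin, 1 skin), 0.8 on the true class
  truth <- matrix(c(0, 0, 0, 1), 2)
  map <- matrix(c(0.2, 0.2, 0.2, 0.8), 2)
  expect_equal(segmentation_loss(map, truth), -log(0.8))
  # uniform predictor scores log 2 on any two-class truth
  withr::with_seed(11, {
    for (rep in 1:5) {
      tr <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4)
      if (sum(tr) %in% c(0, 16)) tr[1, 1] <- 1 - tr[1, 1]
      expect_equal(segmentation_loss(matrix(0.5, 4, 4), tr), log(2))
      mp <- matrix(runif(16, 0.05, 0.95), 4)
      expect_equal(segmentation_loss(mp, tr), oracle_seg_loss(mp, tr),
                   tolerance = 1e-12)
    }
  })
  # perfect confident prediction sits at the clamp floor
  expect_lt(segmentation_loss(matrix(c(0, 0, 1, 1), 2),
                              matrix(c(0, 0, 1, 1), 2)), 1e-6)
  expect_error(segmentation_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)),
               "mismatch")
})

test_that("balanced loss is invariant to duplicating one class", {
  # a class-constant predictor keeps its loss when non-skin pixels are
  # duplicated (class weights renormalize)
  truth <- matrix(c(rep(0, 6), rep(1, 2)), 2)
  map <- matrix(0.7, 2, 4)
  big_truth <- cbind(truth, matrix(0, 2, 4))   # duplicate non-skin block
  big_map <- cbind(map, matrix(0.7, 2, 4))
  expect_equal(segmentation_loss(map, truth),
               segmentation_loss(big_map, big_truth))
})

test_that("joint loss is the weighted sum", {
  expect_equal(joint_loss(0.3, 0.7), 1.0)
  expect_equal(joint_loss(5, 123, c(1, 0)), 5)
  expect_equal(joint_loss(log(2), log(2), c(0.5, 0.5)), log(2))
  expect_error(joint_loss(1, 1, c(-1, 1)), "non-negative")
})

test_that("stage schedules reproduce the printed learning-rate plans", {
  s1 <- training_schedule(1, epochs = 4)
  expect_equal(lr_at(0:3, s1$lr_start, s1$decay_every),
               c(1e-2, 1e-2, 1e-3, 1e-3))
  s2 <- training_schedule(2, epochs = 2)
  expect_equal(s2$lr_start, 1e-4)
  expect_equal(s1$batch_size, 20L)
  expect_equal(s1$momentum, 0.90)
})

test_that("a few SGD steps on one image drive the seg loss down", {
  withr::with_seed(13, {
    data <- synth_skin_dataset(8, 64, p_absent = 0, rng_seed = 13)
  })
  net <- build_skinnet(skinnet_config("tiny", 64))
  train_skinnet(net, data, training_schedule(1, epochs = 3, batch_size = 8,
                                             decay_every = 12))
  h <- net$history
  expect_lt(tail(h$seg_loss, 1), h$seg_loss[1])
})
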