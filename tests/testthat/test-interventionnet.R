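test_that("window bookkeeping matches the sliding-window arithmetic", {
  frames <- replicate(60, array(0, c(8, 8, 3)), simplify = FALSE)
  seq <- frame_sequence(frames, fps = 1)
  w <- make_windows(seq, window_config(T = 5, tau = 1))
  expect_length(w, 56)                                  # floor((60-5)/1)+1
  expect_true(all(vapply(w, function(x) length(x$frame_idx), 0L) == 6))
  # boundary: a recording exactly one window long
  seq5 <- frame_sequence(frames[1:5], fps = 1)
  expect_length(make_windows(seq5, window_config()), 1)
  expect_error(make_windows(frame_sequence(frames[1:3], fps = 1),
                            window_config()), "shorter")
  # coverage: every non-edge second is covered by T/tau windows
  cover <- integer(60)
  for (win in w) {
    sec <- win$start_time + 1:5
    cover[sec] <- cover[sec] + 1L
  }
  expect_equal(sum(cover), length(w) * 5)
  expect_true(all(cover[5:55] == 5))
})

test_that("window labels follow the strict majority rule", {
  expect_equal(label_window(c("intervention", "intervention",
                              "intervention", "valid", "valid")),
               "intervention")                          # 3 > 2.5
  expect_equal(label_window(c("intervention", "intervention",
                              "valid", "valid", "valid")),
               "non-intervention")                      # 2 < 2.5
  expect_equal(label_window(rep("valid", 5)), "non-intervention")
  expect_true(is.na(label_window(c("absent", rep("valid", 4)))))
})

test_that("first-conv adaptation replicates the channel average", {
  withr::with_seed(1, w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)))
  w6 <- adapt_first_conv(w, 6L)
  expect_equal(dim(w6), c(3, 3, 6, 4))
  # 6 copies of the mean of 3 channels: input-channel sums double
  expect_equal(apply(w6, c(1, 2, 4), sum), 2 * apply(w, c(1, 2, 4), sum))
  # all new channels identical
  expect_equal(w6[, , 1, ], w6[, , 5, ])
})

test_that("streams accept their channel counts and emit features", {
  cfg <- interventionnet_config("tiny", 64)
  ctx <- build_context_stream(cfg)
  flw <- build_flow_stream(cfg)
  expect_equal(ctx$in_channels, 6L)
  expect_equal(flw$in_channels, 10L)
  withr::with_seed(2, x6 <- array(rnorm(64 * 64 * 6), c(64, 64, 6, 1)))
  f <- vitalcam:::stream_fw(ctx, x6)$features
  expect_equal(dim(f), c(8, 8, ctx$out_channels, 1))     # 64 / 2^3
  expect_error(vitalcam:::stream_fw(ctx,
                                    array(0, c(64, 64, 9, 1))),
               "channel mismatch")
  # all-zero motion input stays finite
  z <- vitalcam:::stream_fw(flw, array(0, c(64, 64, 10, 1)))$features
  expect_true(all(is.finite(z)))
  expect_error(build_context_stream(interventionnet_config("resnet50")),
               "pretrained")
})

test_that("fusion concatenates, reduces to 512 channels and normalizes", {
  cfg <- interventionnet_config("tiny", 64)
  net <- build_interventionnet(cfg)
  expect_equal(dim(net$fuse$fuse_w)[3:4],
               c(net$ctx$out_channels + net$flow$out_channels, 512L))
  withr::with_seed(3, {
    fc <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
    ff <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  })
  out <- fuse_and_classify(net, fc, ff)
  expect_equal(colSums(out$probs), c(1, 1), tolerance = 1e-9)
  expect_error(fuse_and_classify(net, fc, ff[1:4, 1:4, , , drop = FALSE]),
               "spatial")
})

test_that("pooling commutes with fusion on spatially constant features", {
  net <- build_interventionnet(interventionnet_config("tiny", 16))
  withr::with_seed(4, {
    vc <- rnorm(net$ctx$out_channels)
    vf <- rnorm(net$flow$out_channels)
  })
  mk <- function(v, hw) {
    a <- array(0, c(hw, hw, length(v), 1))
    for (c in seq_along(v)) a[, , c, 1] <- v[c]
    a
  }
  p_big <- fuse_and_classify(net, mk(vc, 8), mk(vf, 8))$probs
  p_one <- fuse_and_classify(net, mk(vc, 1), mk(vf, 1))$probs
  expect_equal(p_big, p_one, tolerance = 1e-9)
})

test_that("stage-2 training touches only the post-fusion layers", {
  nets <- quick_nets()
  w <- nets$windows
  net <- build_interventionnet(interventionnet_config("tiny", 64))
  expect_error(train_interventionnet(net, w, intervention_schedule(2, 5)),
               "before stream training")
  train_interventionnet(net, w, intervention_schedule(1, n_iters = 5))
  ctx_before <- net$ctx$params
  flow_before <- net$flow$params
  fuse_before <- net$fuse
  train_interventionnet(net, w, intervention_schedule(2, n_iters = 5,
                                                      lr_start = 1e-2))
  expect_identical(net$ctx$params, ctx_before)   # frozen pre-fusion weights
  expect_identical(net$flow$params, flow_before)
  expect_false(identical(net$fuse, fuse_before))
  s <- intervention_schedule(1)
  expect_equal(s$lr_start, 1e-3)
  expect_equal(s$batch_size, 24L)
  expect_equal(intervention_schedule(2)$batch_size, 12L)
})

test_that("predicted timelines partition the recording with precedence", {
  nets <- quick_nets()
  rec <- generate_recording(scene_config(
    duration = 40, fps = 2, rng_seed = 9,
    events = list(list(type = "occluder", start = 15, end = 27),
                  list(type = "absence", start = 32, end = 38))))
  tl <- predict_timeline(rec$seq, nets$skin, nets$intervention)
  expect_length(tl$states, 40)
  expect_true(all(tl$states %in% c("absent", "intervention", "valid")))
  truth <- rec$truth$timeline$states
  # absence is never reported as intervention
  expect_false(any(tl$states[truth == "absent"] == "intervention"))
  # the true intervention block is found, boundaries within +/- T seconds
  int_pred <- which(tl$states == "intervention")
  expect_gt(length(intersect(int_pred, 16:27)) / 12, 0.6)
  expect_true(all(int_pred >= 16 - 5 & int_pred <= 27 + 5))
  # a quiet recording is all valid
  quiet <- generate_recording(scene_config(duration = 10, fps = 2,
                                           rng_seed = 10))
  tlq <- predict_timeline(quiet$seq, nets$skin, nets$intervention)
  expect_true(all(tlq$states == "valid"))
})

test_that("timeline CSV round-trips", {
  tl <- activity_timeline(c("valid", "absent", "intervention", "valid"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_timeline(tl, p)
  back <- read_timeline(p)
  expect_equal(back$states, tl$states)
})
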