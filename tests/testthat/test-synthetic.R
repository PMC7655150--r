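test_that("the simulator is bit-reproducible and validates its config", {
  cfg <- scene_config(duration = 2, rng_seed = 42)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth$masks, b$truth$masks)
  expect_error(scene_config(ppg_amplitude = 0.5), "ppg_amplitude")
  expect_error(scene_config(events = list(list(type = "occluder",
                                               start = 5, end = 40))),
               "outside")
  expect_error(scene_config(duration = 30, events = list(
    list(type = "absence", start = 1, end = 10),
    list(type = "absence", start = 5, end = 12))), "overlapping")
})

test_that("absence events empty the mask for exactly their frames", {
  rec <- generate_recording(scene_config(
    duration = 30, fps = 2, rng_seed = 1,
    events = list(list(type = "absence", start = 10, end = 20))))
  t <- (seq_len(n_frames(rec$seq)) - 1) / 2
  expect_identical(rec$truth$presence, !(t >= 10 & t < 20))
  areas <- vapply(rec$truth$masks, sum, 0)
  expect_true(all(areas[t >= 10 & t < 20] == 0))
  expect_true(all(areas[t < 10 | t >= 20] > 0))
})

test_that("green-channel modulation carries the cardiac frequency", {
  rec <- generate_recording(scene_config(duration = 30, hr = 150,
                                         noise_sd = 0.5, rng_seed = 2))
  g <- extract_ppgi(rec$seq, rec$truth$masks)
  # 150/60 Hz over 30 s -> 75 cycles
  expect_length(detect_peaks(g, rate_band(90, 240)), 75)
})

test_that("ground-truth states partition the recording", {
  rec <- generate_recording(scene_config(
    duration = 40, fps = 2, rng_seed = 3,
    events = list(list(type = "occluder", start = 5, end = 12),
                  list(type = "absence", start = 20, end = 26))))
  st <- rec$truth$timeline$states
  expect_length(st, 40)
  expect_true(all(st %in% c("absent", "intervention", "valid")))
  expect_equal(sum(st == "intervention"), 7)
  expect_equal(sum(st == "absent"), 6)
})

test_that("clean recordings recover the configured vital signs", {
  rec <- generate_recording(scene_config(duration = 30, hr = 150, rr = 40,
                                         rng_seed = 4))
  hr <- estimate_rate(extract_ppgi(rec$seq, rec$truth$masks),
                      rate_band(90, 240))$rate
  rr <- estimate_rate(extract_resp(rec$truth$masks, 20)$area,
                      rate_band(20, 120))$rate
  expect_equal(hr, 150, tolerance = 2)
  expect_equal(rr, 40, tolerance = 2)
})

test_that("simulated annotators degrade gracefully with boundary noise", {
  rec <- generate_recording(scene_config(duration = 1, fps = 2,
                                         rng_seed = 5))
  truth <- rec$truth$masks[1]
  # zero disagreement: exact copies, perfect agreement
  ann0 <- simulate_annotators(truth, 3, disagreement = 0)
  expect_identical(ann0[[1]], truth)
  expect_equal(agreement_score(list(ann0[[1]][[1]], ann0[[2]][[1]],
                                    ann0[[3]][[1]])), 1)
  # 2 px of boundary noise keeps agreement high but below 1
  scores <- vapply(1:25, function(s) {
    ann <- simulate_annotators(truth, 3, disagreement = 2, rng_seed = s)
    agreement_score(list(ann[[1]][[1]], ann[[2]][[1]], ann[[3]][[1]]))
  }, 0)
  expect_true(all(scores > 0.8 & scores <= 1))
  # consensus denoises: its IOU beats the mean single-annotator IOU
  ious <- vapply(1:25, function(s) {
    ann <- simulate_annotators(truth, 3, disagreement = 2, rng_seed = s)
    labs <- list(ann[[1]][[1]], ann[[2]][[1]], ann[[3]][[1]])
    cons <- combine_annotations(labs)
    c(mask_iou(cons, truth[[1]]),
      mean(vapply(labs, mask_iou, 0, b = truth[[1]])))
  }, c(0, 0))
  expect_gte(mean(ious[1, ]), mean(ious[2, ]))
})

test_that("recordings round-trip through the on-disk layout", {
  rec <- generate_recording(scene_config(duration = 6, fps = 1,
                                         rng_seed = 6))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  expect_true(file.exists(file.path(dir, "scene.yaml")))
  seq <- load_frames(file.path(dir, "frames"), fps = 1)
  expect_equal(n_frames(seq), 6)
  expect_equal(seq$frames[[1]], rec$seq$frames[[1]], tolerance = 0.5)
  tl <- read.csv(file.path(dir, "truth", "timeline.csv"))
  expect_equal(nrow(tl), 6)
  m <- read_mask(file.path(dir, "truth", "masks", "mask_00001.png"))
  expect_identical(m, rec$truth$masks[[1]])
})
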