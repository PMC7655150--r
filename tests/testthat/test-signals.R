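test_that("PPGi extraction is the masked spatial mean of the channel", {
  fr1 <- array(0, c(2, 2, 3)); fr1[, , 2] <- matrix(c(10, 30, 50, 70), 2)
  fr2 <- array(100, c(2, 2, 3))
  mask <- matrix(c(1, 1, 0, 0), 2)
  seq <- frame_sequence(list(fr1, fr2), fps = 2)
  ts <- extract_ppgi(seq, list(mask, mask))
  expect_equal(ts$samples, c(mean(c(10, 30)), 100))
  expect_true(all(ts$valid))
  # empty mask -> invalid sample
  ts2 <- extract_ppgi(seq, list(mask, matrix(0, 2, 2)))
  expect_false(ts2$valid[2])
  expect_error(extract_ppgi(seq, list(mask, matrix(0, 3, 3))), "mismatch")
})

test_that("PPGi never depends on non-skin pixels", {
  withr::with_seed(1, {
    fr <- array(runif(8 * 8 * 3) * 255, c(8, 8, 3))
    mask <- matrix(rbinom(64, 1, 0.4), 8)
    perturbed <- fr
    bg <- which(mask == 0)
    for (c in 1:3) {
      p <- perturbed[, , c]
      p[bg] <- runif(length(bg)) * 255
      perturbed[, , c] <- p
    }
  })
  s1 <- extract_ppgi(frame_sequence(list(fr), 1), list(mask))
  s2 <- extract_ppgi(frame_sequence(list(perturbed), 1), list(mask))
  expect_identical(s1$samples, s2$samples)
})

test_that("respiratory geometry: area, centroid and perimeter", {
  m <- matrix(0L, 10, 10); m[3:7, 4:8] <- 1L
  r <- extract_resp(list(m, m), fps = 2)
  expect_equal(r$area$samples, c(25, 25))
  expect_equal(r$centroid_y$samples[1], 5)   # symmetric block center
  expect_equal(r$centroid_x$samples[1], 6)
  expect_equal(r$perimeter$samples[1], 16)   # 5x5 block boundary
  big <- matrix(1L, 40, 25)
  expect_equal(extract_resp(list(big), 1)$area$samples, 1000)
})

test_that("area oscillation carries the respiratory fundamental", {
  rec <- generate_recording(scene_config(duration = 30, rr = 60,
                                         noise_sd = 0.5, rng_seed = 6))
  est <- estimate_rate(extract_resp(rec$truth$masks, 20)$area,
                       rate_band(20, 120))
  expect_equal(est$rate, 60, tolerance = 2)
})

test_that("peak detection counts sinusoid cycles", {
  expect_length(detect_peaks(sine_series(2.6, 30), rate_band(90, 240)), 78)
  expect_length(detect_peaks(sine_series(7 / 6, 30), rate_band(20, 120)), 35)
  # 10% white noise changes the count by at most one
  withr::with_seed(7, {
    t <- (0:599) / 20
    noisy <- vital_timeseries(sin(2 * pi * 2.6 * t) + rnorm(600, 0, 0.1), 20)
  })
  expect_lte(abs(length(detect_peaks(noisy, rate_band(90, 240))) - 78), 1)
  # all-invalid series has no peaks
  dead <- vital_timeseries(sin(2 * pi * t), 20, valid = rep(FALSE, 600))
  expect_length(detect_peaks(dead, rate_band(90, 240)), 0)
  expect_error(rate_band(120, 90), "empty")
})

test_that("rate conversion is linear in peaks over duration", {
  expect_equal(rate_from_peaks(78, 30)$rate, 156)
  expect_equal(rate_from_peaks(35, 30)$rate, 70)
  expect_equal(rate_from_peaks(0, 30)$rate, 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      k <- sample.int(200, 1); d <- runif(1, 5, 120)
      expect_equal(rate_from_peaks(k, d)$rate, k * 60 / d)
      expect_equal(rate_from_peaks(2 * k, d)$rate,
                   2 * rate_from_peaks(k, d)$rate)
      expect_equal(rate_from_peaks(k, 2 * d)$rate,
                   rate_from_peaks(k, d)$rate / 2)
    }
  })
  expect_error(rate_from_peaks(10, 0), "positive")
})

test_that("timeline masking invalidates exactly the flagged seconds", {
  x <- vital_timeseries(rnorm(60 * 20), 20)
  states <- rep("valid", 60)
  states[21:30] <- "intervention"
  tl <- activity_timeline(states)
  m <- mask_invalid(x, tl)
  expect_equal(sum(!m$valid), 10 * 20)
  expect_equal(which(!m$valid), 401:600)
  expect_identical(m$samples, x$samples)      # values preserved
  # all-valid timeline is a no-op; all-absent kills everything
  expect_true(all(mask_invalid(x, activity_timeline(rep("valid", 60)))$valid))
  expect_false(any(mask_invalid(x,
                                activity_timeline(rep("absent", 60)))$valid))
  expect_error(mask_invalid(x, activity_timeline(rep("valid", 30))),
               "cover")
})

test_that("series CSV export round-trips values and validity", {
  s <- vital_timeseries(c(1.5, 2.5, 3.5), 1, valid = c(TRUE, FALSE, TRUE))
  p <- withr::local_tempfile(fileext = ".csv")
  write_series(s, p)
  d <- read.csv(p)
  expect_equal(d$value, s$samples)
  expect_equal(as.logical(d$valid), s$valid)
})
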