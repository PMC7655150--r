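# Shared fixtures, all generated in code.

# Pure sinusoid as a vital time series.
sine_series <- function(freq_hz, duration_s, fs = 20) {
  t <- (0:(duration_s * fs - 1)) / fs
  vital_timeseries(sin(2 * pi * freq_hz * t), fs)
}

# Two-tone image: flat disk on a contrasting flat background (plus a
# little noise so GMM fits are non-degenerate).
two_tone_disk <- function(sz = 24, r = 7, noise = 2, seed = 1) {
  withr::with_seed(seed, {
    rows <- row(matrix(0, sz, sz))
    cols <- col(matrix(0, sz, sz))
    disk <- (rows - sz / 2)^2 + (cols - sz / 2 - 1)^2 <= r^2
    img <- array(0, c(sz, sz, 3))
    fg <- c(220, 150, 120)
    bg <- c(40, 60, 150)
    for (c in 1:3) {
      p <- matrix(bg[c], sz, sz)
      p[disk] <- fg[c]
      img[, , c] <- p
    }
    img <- img + array(rnorm(sz * sz * 3, 0, noise), dim(img))
    list(image = pmin(pmax(img, 0), 255), disk = disk)
  })
}

flow_field <- function(u, v = u * 0) {
  structure(list(u = u, v = v), class = "flow_field")
}

# Quick-trained networks for wiring-level tests (cached for the session;
# the acceptance suite trains its own models under the full protocol).
.net_cache <- new.env()
quick_nets <- function() {
  if (!is.null(.net_cache$nets)) return(.net_cache$nets)
  set.seed(5)
  sd <- synth_skin_dataset(120, 64, p_absent = 0.3, rng_seed = 5)
  snet <- build_skinnet(skinnet_config("tiny", 64))
  train_skinnet(snet, sd, training_schedule(1, epochs = 6, decay_every = 12))
  train_skinnet(snet, sd, training_schedule(2, epochs = 4, decay_every = 12,
                                            lr_start = 1e-3))
  wd <- synth_window_dataset(160, 64, rng_seed = 6)
  inet <- build_interventionnet(interventionnet_config("tiny", 64))
  train_interventionnet(inet, wd, intervention_schedule(1, n_iters = 80))
  train_interventionnet(inet, wd, intervention_schedule(2, n_iters = 80,
                                                        lr_start = 1e-2))
  .net_cache$nets <- list(skin = snet, intervention = inet, windows = wd)
  .net_cache$nets
}
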