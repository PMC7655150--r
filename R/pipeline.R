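#' Default configuration tree
#'
#' One nested list with per-module sections; [load_config()] deep-merges a
#' YAML file over these defaults, and command-line flags override both.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    videoio = list(fps = 20, input_size = 64L,
                   channel_means = c(0, 0, 0)),
    augment = list(
      skin_net = list(translate_range = 0.10, scale_range = c(0.90, 1.10),
                      rotate_range = c(0, 0), mirror = FALSE),
      intervention_net = list(translate_range = 0.10,
                              scale_range = c(1.00, 1.25),
                              rotate_range = c(-45, 45), mirror = TRUE)),
    skinnet = list(backbone = "tiny", detection_threshold = 0.5,
                   mask_threshold = 0.5),
    flow = list(clip_limit = 40, alpha = 0.05, jpeg_quality = 90),
    window = list(T = 5, tau = 1),
    signals = list(hr_band = c(90, 240), rr_band = c(20, 120),
                   segment_s = 30),
    seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname default_config
#' @param path YAML file; missing/NULL returns the defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path) && nzchar(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Rates over sliding analysis segments
#'
#' Splits a waveform into consecutive segments (default 30 s) and counts
#' peaks in each, mirroring how monitor-style rate readouts are formed.
#'
#' @param series a [vital_timeseries].
#' @param band a [rate_band()].
#' @param segment_s segment length, seconds.
#' @param min_valid minimum fraction of valid samples for a segment to be
#'   scored (others get `NA`).
#' @return data.frame with `t_start,t_end,rate,peaks`.
#' @export
rates_over_segments <- function(series, band, segment_s = 30,
                                min_valid = 0.8) {
  n <- length(series$samples)
  dur <- n / series$fs
  starts <- seq(0, dur - segment_s, by = segment_s)
  if (length(starts) == 0) starts <- 0
  out <- lapply(starts, function(s) {
    i0 <- round(s * series$fs) + 1L
    i1 <- min(round((s + segment_s) * series$fs), n)
    sub <- vital_timeseries(series$samples[i0:i1], series$fs, series$kind,
                            series$valid[i0:i1])
    if (mean(sub$valid) < min_valid)
      return(data.frame(t_start = s, t_end = s + segment_s, rate = NA,
                        peaks = NA))
    est <- estimate_rate(sub, band)
    data.frame(t_start = s, t_end = s + segment_s, rate = est$rate,
               peaks = est$peak_count)
  })
  do.call(rbind, out)
}

#' Run the full monitoring pipeline on a recording
#'
#' Detection + segmentation on every frame, the two-stream intervention
#' timeline at one-second resolution, and PPGi/respiratory extraction
#' restricted to valid periods. Outputs: `masks/*.png`, `conf/*.png`
#' (8-bit confidence maps), `timeline.csv`, `ppgi.csv`, `resp_area.csv`,
#' `rates.csv` and `summary.yaml` in `out_dir`. Partial outputs are
#' removed on failure.
#'
#' @param input recording directory (image sequence).
#' @param skin_checkpoint,intervention_checkpoint checkpoint paths from
#'   [save_skinnet()] / [save_interventionnet()].
#' @param out_dir output directory.
#' @param config configuration list ([load_config()]) or YAML path.
#' @param seed integer seed controlling any stochastic step.
#' @return invisibly, a list with the timeline and rate tables.
#' @export
run_pipeline <- function(input, skin_checkpoint, intervention_checkpoint,
                         out_dir, config = default_config(), seed = 1L) {
  if (is.character(config)) config <- load_config(config)
  for (p in c(skin_checkpoint, intervention_checkpoint))
    if (!file.exists(p)) stop("missing checkpoint: ", p)
  created <- !dir.exists(out_dir)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "conf"), showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)
  withr::with_seed(as.integer(seed), {
    snet <- load_skinnet(skin_checkpoint)
    inet <- load_interventionnet(intervention_checkpoint)
    seq <- load_frames(input, fps = config$videoio$fps)
    sz <- snet$cfg$input_size
    d <- dim(seq$frames[[1]])
    if (d[1] != sz || d[2] != sz)
      seq$frames <- lapply(seq$frames, function(f)
        letterbox_resize(f, sz)$image)
    masks <- vector("list", n_frames(seq))
    any_present <- FALSE
    for (i in seq_len(n_frames(seq))) {
      fw <- skinnet_forward(snet, seq$frames[[i]])
      if (is.null(fw$map)) {
        masks[[i]] <- matrix(0L, sz, sz)
      } else {
        any_present <- TRUE
        masks[[i]] <- threshold_map(fw$map, config$skinnet$mask_threshold)
        png::writePNG(round(fw$map * 255) / 255, # 8-bit confidence map
                      file.path(out_dir, "conf",
                                sprintf("conf_%05d.png", i)))
        write_mask(masks[[i]],
                   file.path(out_dir, "masks",
                             sprintf("mask_%05d.png", i)))
      }
    }
    timeline <- predict_timeline(seq, snet, inet,
                                 window_config(config$window$T,
                                               config$window$tau))
    write_timeline(timeline, file.path(out_dir, "timeline.csv"))
    ppgi <- mask_invalid(extract_ppgi(seq, masks), timeline)
    resp <- mask_invalid(extract_resp(masks, seq$fps)$area, timeline)
    write_series(ppgi, file.path(out_dir, "ppgi.csv"))
    write_series(resp, file.path(out_dir, "resp_area.csv"))
    hr_band <- rate_band(config$signals$hr_band[1],
                         config$signals$hr_band[2])
    rr_band <- rate_band(config$signals$rr_band[1],
                         config$signals$rr_band[2])
    rates <- rbind(
      cbind(kind = "ppgi",
            rates_over_segments(ppgi, hr_band, config$signals$segment_s)),
      cbind(kind = "resp_area",
            rates_over_segments(resp, rr_band, config$signals$segment_s)))
    write_rates(rates, file.path(out_dir, "rates.csv"))
    yaml::write_yaml(
      list(n_frames = n_frames(seq), fps = seq$fps,
           any_present = any_present,
           states = as.list(table(timeline$states)),
           seed = as.integer(seed)),
      file.path(out_dir, "summary.yaml"))
    ok <- TRUE
    invisible(list(timeline = timeline, rates = rates))
  })
}
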