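#' Scene configuration for the incubator simulator
#'
#' Describes a simple neonatal-incubator-like scene: one skin-colored
#' elliptical region whose green channel is modulated by a cardiac
#' pulsation, whose area breathes at a respiratory frequency, a slow
#' global illumination drift, additive Gaussian pixel noise, and timed
#' events (moving occluders standing in for clinical interventions, and
#' patient-absence intervals).
#'
#' @param image_size square frame side, pixels.
#' @param fps frames per second.
#' @param duration recording length, seconds.
#' @param skin_chroma RGB of the skin region (0--255).
#' @param hr heart rate, beats/min; green intensity is modulated by
#'   `ppg_amplitude * sin(2 pi hr/60 t)`.
#' @param ppg_amplitude fractional green-channel modulation (0--0.2).
#' @param rr respiratory rate, breaths/min; the ellipse area is modulated
#'   by `resp_area_amplitude` at this frequency.
#' @param resp_area_amplitude fractional area modulation.
#' @param lighting_drift list with `amplitude` (intensity units) and
#'   `period` (s) of a global sinusoidal lightness drift.
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param events list of `list(type = "occluder"|"absence", start, end)`
#'   (seconds); events of one type must not overlap.
#' @param occluder_speed horizontal occluder speed, px/s (> 40 so that
#'   one-second flow exceeds the codec clip limit).
#' @param center,axes ellipse center and semi-axes as fractions of
#'   `image_size` (row, col).
#' @param rng_seed integer seed making frames bit-reproducible.
#' @return a `scene_config`.
#' @export
scene_config <- function(image_size = 64L, fps = 20, duration = 30,
                         skin_chroma = c(224, 160, 130), hr = 150,
                         ppg_amplitude = 0.01, rr = 40,
                         resp_area_amplitude = 0.05,
                         lighting_drift = list(amplitude = 4, period = 20),
                         noise_sd = 1, events = list(),
                         occluder_speed = 48,
                         center = c(0.5, 0.5), axes = c(0.30, 0.38),
                         rng_seed = 1L) {
  if (ppg_amplitude <= 0 || ppg_amplitude >= 0.2)
    stop("ppg_amplitude must be in (0, 0.2)")
  for (ev in events) {
    if (!ev$type %in% c("occluder", "absence")) stop("unknown event type")
    if (ev$start < 0 || ev$end > duration || ev$end <= ev$start)
      stop("event outside recording")
  }
  for (type in c("occluder", "absence")) {
    evs <- Filter(function(e) e$type == type, events)
    if (length(evs) > 1) {
      o <- order(vapply(evs, `[[`, 0, "start"))
      evs <- evs[o]
      for (i in seq_len(length(evs) - 1))
        if (evs[[i]]$end > evs[[i + 1]]$start)
          stop("overlapping ", type, " events")
    }
  }
  structure(list(image_size = as.integer(image_size), fps = fps,
                 duration = duration, skin_chroma = skin_chroma, hr = hr,
                 ppg_amplitude = ppg_amplitude, rr = rr,
                 resp_area_amplitude = resp_area_amplitude,
                 lighting_drift = lighting_drift, noise_sd = noise_sd,
                 events = events, occluder_speed = occluder_speed,
                 center = center, axes = axes,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Per-second activity timeline
#'
#' One of three mutually exclusive states per second: `absent`,
#' `intervention` or `valid`.
#'
#' @param states character vector of per-second states.
#' @param start_time start of the first second, seconds.
#' @return an `activity_timeline`.
#' @export
activity_timeline <- function(states, start_time = 0) {
  if (!all(states %in% c("absent", "intervention", "valid")))
    stop("states must be absent/intervention/valid")
  structure(list(states = states, start_time = start_time,
                 duration = length(states)),
            class = "activity_timeline")
}

#' @export
print.activity_timeline <- function(x, ...) {
  tb <- table(factor(x$states, c("absent", "intervention", "valid")))
  cat(sprintf("<activity_timeline> %d s (absent %d, intervention %d, valid %d)\n",
              x$duration, tb[1], tb[2], tb[3]))
  invisible(x)
}

in_event <- function(t, events, type) {
  for (ev in events)
    if (ev$type == type && t >= ev$start && t < ev$end) return(ev)
  NULL
}

#' Generate a labelled synthetic recording
#'
#' @param cfg a [scene_config()].
#' @return list with `seq` (a [frame_sequence]), and `truth`: per-frame
#'   skin `masks`, per-frame `presence` flags, the per-second `timeline`
#'   (an [activity_timeline]), and the true `hr` and `rr`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  sz <- cfg$image_size
  nfr <- round(cfg$duration * cfg$fps)
  bg <- c(70, 80, 95)
  occ_col <- c(40, 110, 205) # occluder chroma kept distinct from skin
  rows <- matrix(seq_len(sz), sz, sz)
  cols <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
  cy <- cfg$center[1] * sz; cx <- cfg$center[2] * sz
  ay <- cfg$axes[1] * sz; ax <- cfg$axes[2] * sz
  frames <- vector("list", nfr)
  masks <- vector("list", nfr)
  presence <- logical(nfr)
  withr::with_seed(cfg$rng_seed, {
    for (i in seq_len(nfr)) {
      t <- (i - 1) / cfg$fps
      drift <- cfg$lighting_drift$amplitude *
        sin(2 * pi * t / cfg$lighting_drift$period)
      fr <- array(0, c(sz, sz, 3L))
      for (c in 1:3) fr[, , c] <- bg[c]
      absent <- !is.null(in_event(t, cfg$events, "absence"))
      skin <- matrix(FALSE, sz, sz)
      if (!absent) {
        m <- sqrt(1 + cfg$resp_area_amplitude *
                    sin(2 * pi * cfg$rr / 60 * t))
        skin <- ((rows - cy) / (ay * m))^2 + ((cols - cx) / (ax * m))^2 <= 1
        ppg <- 1 + cfg$ppg_amplitude * sin(2 * pi * cfg$hr / 60 * t)
        ch <- cfg$skin_chroma * c(1, ppg, 1)
        for (c in 1:3) {
          plane <- fr[, , c]
          plane[skin] <- ch[c]
          fr[, , c] <- plane
        }
      }
      occ <- in_event(t, cfg$events, "occluder")
      if (!is.null(occ)) {
        ow <- round(sz * 0.35); oh <- round(sz * 0.45)
        x0 <- 1 + ((occ$x0 %||% 0) + (t - occ$start) * cfg$occluder_speed) %%
          (sz - 1)
        occm <- cols >= x0 & cols < x0 + ow &
          rows >= (sz - oh) / 2 & rows < (sz + oh) / 2
        for (c in 1:3) {
          plane <- fr[, , c]
          plane[occm] <- occ_col[c]
          fr[, , c] <- plane
        }
        skin <- skin & !occm
      }
      fr <- fr + drift
      if (cfg$noise_sd > 0)
        fr <- fr + array(stats::rnorm(length(fr), 0, cfg$noise_sd), dim(fr))
      frames[[i]] <- pmin(pmax(fr, 0), 255)
      masks[[i]] <- skin + 0L
      presence[i] <- !absent
    }
  })
  states <- vapply(seq_len(floor(cfg$duration)) - 1L, function(s) {
    tm <- s + 0.5
    if (!is.null(in_event(tm, cfg$events, "absence"))) "absent"
    else if (!is.null(in_event(tm, cfg$events, "occluder"))) "intervention"
    else "valid"
  }, "")
  list(seq = frame_sequence(frames, cfg$fps),
       truth = list(masks = masks, presence = presence,
                    timeline = activity_timeline(states),
                    hr = cfg$hr, rr = cfg$rr, cfg = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate independent annotators from ground-truth masks
#'
#' Each annotator's label is the truth perturbed by an independent smooth
#' boundary-noise field: a Gaussian random field is added to the signed
#' distance transform of the mask and the result re-thresholded, moving
#' the boundary by roughly `disagreement` pixels.
#'
#' @param truth_masks list of binary matrices.
#' @param n_annotators number of annotators.
#' @param disagreement boundary noise scale, pixels (0 = exact copies).
#' @param rng_seed integer seed.
#' @return list of length `n_annotators`, each a list of binary masks.
#' @export
simulate_annotators <- function(truth_masks, n_annotators = 3L,
                                disagreement = 2, rng_seed = 1L) {
  stopifnot(disagreement >= 0)
  if (disagreement == 0)
    return(replicate(n_annotators, truth_masks, simplify = FALSE))
  withr::with_seed(rng_seed, {
    lapply(seq_len(n_annotators), function(a) {
      lapply(truth_masks, function(m) {
        if (sum(m) == 0) return(m * 0L)
        d_in <- EBImage::imageData(EBImage::distmap(m))
        d_out <- EBImage::imageData(EBImage::distmap(1 - m))
        sgn <- d_in - d_out
        fld <- matrix(stats::rnorm(length(m)), nrow(m))
        fld <- EBImage::imageData(EBImage::gblur(fld, sigma = 3))
        fld <- fld / stats::sd(fld) * disagreement
        (sgn + fld > 0) + 0L
      })
    })
  })
}

#' Write a recording directory to disk
#'
#' Layout: `frames/*.png`, `truth/masks/*.png`, `truth/timeline.csv`
#' (`second,state`) and `scene.yaml`.
#'
#' @param rec result of [generate_recording()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(file.path(dir, "truth", "masks"), recursive = TRUE,
             showWarnings = FALSE)
  write_frames(rec$seq, file.path(dir, "frames"))
  for (i in seq_along(rec$truth$masks))
    write_mask(rec$truth$masks[[i]],
               file.path(dir, "truth", "masks", sprintf("mask_%05d.png", i)))
  tl <- rec$truth$timeline
  utils::write.csv(data.frame(second = seq_along(tl$states) - 1L,
                              state = tl$states),
                   file.path(dir, "truth", "timeline.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- rec$truth$cfg
  cfg$events <- lapply(cfg$events, function(e) e[c("type", "start", "end")])
  yaml::write_yaml(unclass(cfg), file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Synthetic frame dataset for training the skin network
#'
#' Draws independent scene variants (ellipse position, size, chroma and
#' lighting jittered per frame) and returns frames with masks and
#' presence flags; a fraction of frames are patient-absent.
#'
#' @param n_frames number of frames.
#' @param image_size square frame side.
#' @param p_absent fraction of absent (negative) frames.
#' @param rng_seed integer seed.
#' @return list with `images`, `masks` (`NULL` for negatives) and
#'   `present`, as expected by [train_skinnet()].
#' @export
synth_skin_dataset <- function(n_frames, image_size = 64L, p_absent = 0.25,
                               rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    images <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    present <- stats::runif(n_frames) >= p_absent
    for (i in seq_len(n_frames)) {
      cfg <- scene_config(
        image_size = image_size, fps = 1, duration = 1,
        skin_chroma = c(224, 160, 130) + stats::rnorm(3, 0, 12),
        hr = 150, rr = 40,
        lighting_drift = list(amplitude = 0, period = 20),
        noise_sd = 2,
        center = c(stats::runif(1, 0.3, 0.7), stats::runif(1, 0.3, 0.7)),
        axes = c(stats::runif(1, 0.15, 0.35), stats::runif(1, 0.15, 0.4)),
        events = if (present[i]) list() else
          list(list(type = "absence", start = 0, end = 1)),
        rng_seed = sample.int(2^30, 1))
      rec <- generate_recording(cfg)
      off <- stats::rnorm(1, 0, 15) # global illumination offset per frame
      images[[i]] <- pmin(pmax(rec$seq$frames[[1]] + off, 0), 255)
      masks[i] <- list(if (present[i]) rec$truth$masks[[1]] else NULL)
    }
    list(images = images, masks = masks, present = present)
  })
}

#' Synthetic labelled window dataset for the intervention network
#'
#' Generates several incubator scenes with timed moving-occluder events,
#' samples frames at 1 Hz, derives per-second skin-confidence maps from
#' the ground-truth masks (softened with a small Gaussian blur) and
#' encoded-decoded optical flow between consecutive sampled frames, and
#' slices everything into labelled 5 s windows (strict-majority rule).
#'
#' @param n_windows windows to return.
#' @param image_size square frame side.
#' @param rng_seed integer seed.
#' @param fps simulator frame rate (frames are consumed at 1 Hz).
#' @return list with `context`, `motion` and `label`, as expected by
#'   [train_interventionnet()].
#' @export
synth_window_dataset <- function(n_windows, image_size = 64L,
                                 rng_seed = 1L, fps = 2) {
  withr::with_seed(rng_seed, {
    context <- list(); motion <- list(); label <- character()
    while (length(label) < n_windows) {
      dur <- 72
      ev_starts <- c(8, 32, 56) + sample(-3:3, 3, replace = TRUE)
      events <- lapply(ev_starts, function(s)
        list(type = "occluder", start = s, end = s + 12))
      cfg <- scene_config(
        image_size = image_size, fps = fps, duration = dur,
        events = events, noise_sd = 2,
        center = c(stats::runif(1, 0.35, 0.65),
                   stats::runif(1, 0.35, 0.65)),
        rng_seed = sample.int(2^30, 1))
      rec <- generate_recording(cfg)
      idx <- pmin(round((0:dur) * fps) + 1L, n_frames(rec$seq))
      maps <- lapply(idx, function(i)
        EBImage::imageData(EBImage::gblur(rec$truth$masks[[i]] * 0.9 + 0.05,
                                          sigma = 1)))
      flows <- lapply(seq_len(dur), function(k)
        decode_flow(encode_flow(
          compute_flow(rec$seq$frames[[idx[k]]],
                       rec$seq$frames[[idx[k + 1]]]))))
      states <- rec$truth$timeline$states
      for (s in 0:(dur - 5L)) {
        ctx <- array(0, c(image_size, image_size, 6L))
        for (k in 0:5) ctx[, , k + 1] <- maps[[s + k + 1]]
        mot <- array(0, c(image_size, image_size, 10L))
        for (k in 1:5) {
          mot[, , 2 * k - 1] <- flows[[s + k]]$u
          mot[, , 2 * k] <- flows[[s + k]]$v
        }
        context[[length(context) + 1L]] <- ctx
        motion[[length(motion) + 1L]] <- mot
        label <- c(label, label_window(states[(s + 1):(s + 5)]))
      }
    }
    keep <- seq_len(n_windows)
    list(context = context[keep], motion = motion[keep],
         label = label[keep])
  })
}
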