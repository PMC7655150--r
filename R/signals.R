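#' Vital-sign time series
#'
#' A sampled waveform with a per-sample validity mask. Kinds: `ppgi`
#' (green-channel skin intensity), `resp_area`, `resp_centroid_x/y`,
#' `resp_perimeter`.
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz.
#' @param kind waveform kind string.
#' @param valid logical vector, same length as `samples`.
#' @return a `vital_timeseries`.
#' @export
vital_timeseries <- function(samples, fs,
                             kind = "ppgi",
                             valid = rep(TRUE, length(samples))) {
  stopifnot(fs > 0, length(valid) == length(samples))
  structure(list(samples = samples, fs = fs, kind = kind, valid = valid),
            class = "vital_timeseries")
}

#' @export
print.vital_timeseries <- function(x, ...) {
  cat(sprintf("<vital_timeseries:%s> %d samples @ %g Hz (%.0f%% valid)\n",
              x$kind, length(x$samples), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Extract the PPGi waveform from segmented skin
#'
#' Per frame, the spatial mean of the chosen channel (green by default,
#' where cardiac pulsation is strongest) over the skin pixels. Frames with
#' an empty mask (patient absent) yield invalid samples.
#'
#' @param seq a [frame_sequence].
#' @param masks list of binary skin masks, one per frame.
#' @param channel 1 = red, 2 = green, 3 = blue.
#' @return a `vital_timeseries` of kind `"ppgi"`.
#' @export
extract_ppgi <- function(seq, masks, channel = 2L) {
  n <- n_frames(seq)
  if (length(masks) != n) stop("one mask per frame required")
  samples <- numeric(n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    m <- masks[[i]] > 0
    if (!identical(dim(m), dim(seq$frames[[i]])[1:2]))
      stop("mask/frame size mismatch")
    if (any(m)) {
      samples[i] <- mean(seq$frames[[i]][, , channel][m])
      valid[i] <- TRUE
    }
  }
  vital_timeseries(samples, seq$fps, "ppgi", valid)
}

#' Extract respiratory signals from skin-mask geometry
#'
#' Per-frame area (pixel count; the default respiratory signal), centroid
#' coordinates and boundary perimeter of the segmented skin region.
#'
#' @param masks ordered list of binary masks.
#' @param fps frames per second.
#' @return list of `vital_timeseries`: `area`, `centroid_x`, `centroid_y`,
#'   `perimeter`.
#' @export
extract_resp <- function(masks, fps) {
  n <- length(masks)
  area <- cx <- cy <- per <- numeric(n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    m <- masks[[i]] > 0
    a <- sum(m)
    area[i] <- a
    valid[i] <- a > 0
    if (a > 0) {
      idx <- which(m, arr.ind = TRUE)
      cy[i] <- mean(idx[, 1])
      cx[i] <- mean(idx[, 2])
      # boundary length: mask pixels with at least one off-mask 4-neighbor
      H <- nrow(m); W <- ncol(m)
      pad <- matrix(FALSE, H + 2, W + 2)
      pad[2:(H + 1), 2:(W + 1)] <- m
      interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
      per[i] <- sum(m & !interior)
    }
  }
  list(area = vital_timeseries(area, fps, "resp_area", valid),
       centroid_x = vital_timeseries(cx, fps, "resp_centroid_x", valid),
       centroid_y = vital_timeseries(cy, fps, "resp_centroid_y", valid),
       perimeter = vital_timeseries(per, fps, "resp_perimeter", valid))
}

#' Physiologic rate band
#' @param min_rate,max_rate limits in events per minute. Defaults cover
#'   neonatal heart rates; use `rate_band(20, 120)` for respiration.
#' @export
rate_band <- function(min_rate = 90, max_rate = 240) {
  if (!(max_rate > min_rate && min_rate > 0)) stop("empty physiologic band")
  structure(list(min_rate = min_rate, max_rate = max_rate),
            class = "rate_band")
}

# Moving-average detrend; window = 2x the slowest expected period.
detrend_series <- function(x, fs, band) {
  w <- max(3L, round(2 * 60 / band$min_rate * fs))
  if (w %% 2 == 0) w <- w + 1L
  if (w >= length(x)) return(x - mean(x))
  base <- stats::filter(x, rep(1 / w, w), sides = 2)
  h <- (w - 1L) / 2L
  nx <- length(x)
  base[seq_len(h)] <- base[h + 1L]
  base[(nx - h + 1L):nx] <- base[nx - h]
  as.numeric(x - base)
}

#' Detect peaks in a vital-sign waveform
#'
#' The series is detrended with a moving-average baseline (window twice
#' the slowest period of the band), lightly smoothed, and local maxima
#' are kept subject to a minimum separation of `60 / max_rate` seconds
#' and a minimum prominence (a fraction of the detrended amplitude). Only
#' valid samples are considered.
#'
#' @param series a [vital_timeseries].
#' @param band a [rate_band()].
#' @param min_prominence peak height floor as a fraction of the maximum
#'   absolute detrended amplitude.
#' @return integer vector of peak sample indices.
#' @export
detect_peaks <- function(series, band = rate_band(),
                         min_prominence = 0.25) {
  stopifnot(inherits(band, "rate_band"))
  x <- series$samples
  v <- series$valid
  if (!any(v)) return(integer(0))
  x[!v] <- NA
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  min_dist <- max(1L, round(60 / band$max_rate * series$fs))
  for (r in which(runs$values)) {
    seg <- x[starts[r]:ends[r]]
    if (length(seg) < 3L) next
    seg <- detrend_series(seg, series$fs, band)
    sm <- seg
    if (length(seg) >= 5L) {
      f <- as.numeric(stats::filter(seg, rep(1 / 3, 3), sides = 2))
      f[c(1L, length(f))] <- seg[c(1L, length(f))]
      sm <- f
    }
    sm[is.na(sm)] <- 0
    amp <- max(abs(sm))
    if (amp == 0) next
    pk <- pracma::findpeaks(sm, minpeakdistance = min_dist,
                            minpeakheight = min_prominence * amp,
                            zero = "+") # count plateau maxima once
    if (!is.null(pk))
      peaks <- c(peaks, starts[r] - 1L + sort(pk[, 2]))
  }
  sort(peaks)
}

#' Convert a peak count to a rate
#'
#' @param peak_count number of detected peaks.
#' @param window_duration duration of the analysis segment, seconds.
#' @return a `rate_estimate` with `rate = peak_count * 60 /
#'   window_duration` (events per minute).
#' @export
rate_from_peaks <- function(peak_count, window_duration) {
  if (window_duration <= 0) stop("window_duration must be positive")
  structure(list(rate = peak_count * 60 / window_duration,
                 peak_count = peak_count,
                 window_duration = window_duration),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%g peaks / %g s = %.1f min^-1\n", x$peak_count,
              x$window_duration, x$rate))
  invisible(x)
}

#' Estimate a rate over one analysis segment of a waveform
#'
#' Counts peaks over the whole (valid part of the) series and converts to
#' events per minute; segment length defaults to the full series.
#'
#' @param series a [vital_timeseries].
#' @param band a [rate_band()].
#' @param ... passed to [detect_peaks()].
#' @return a `rate_estimate`.
#' @export
estimate_rate <- function(series, band = rate_band(), ...) {
  pk <- detect_peaks(series, band, ...)
  rate_from_peaks(length(pk), length(series$samples) / series$fs)
}

#' Mask samples that fall in absent or intervention seconds
#'
#' Values are preserved; only the validity flags change. Vital signs are
#' estimated only when the patient is present and no intervention is
#' under way.
#'
#' @param series a [vital_timeseries].
#' @param timeline an [activity_timeline] covering the series' span.
#' @return the masked `vital_timeseries`.
#' @export
mask_invalid <- function(series, timeline) {
  n <- length(series$samples)
  sec <- floor((seq_len(n) - 1) / series$fs) - timeline$start_time
  if (any(sec >= timeline$duration | sec < 0))
    stop("timeline does not cover the series")
  bad <- timeline$states[sec + 1] != "valid"
  series$valid <- series$valid & !bad
  series
}

#' Write a waveform (or rates) as CSV
#'
#' Waveform rows are `time,value,valid`; rate rows are
#' `t_start,t_end,rate,peaks`.
#'
#' @param series a [vital_timeseries].
#' @param path CSV path.
#' @export
write_series <- function(series, path) {
  utils::write.csv(data.frame(time = (seq_along(series$samples) - 1) /
                                series$fs,
                              value = series$samples,
                              valid = as.integer(series$valid)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param rates data.frame with columns `t_start,t_end,rate,peaks`.
#' @export
write_rates <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
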