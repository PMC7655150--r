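#' Frame sequences
#'
#' A `frame_sequence` holds an ordered set of RGB frames (numeric arrays
#' `H x W x 3` with intensities on the 0--255 scale), the sampling rate in
#' frames per second and a time offset of the first frame in seconds.
#'
#' @param frames list of `H x W x 3` numeric arrays, all the same size.
#' @param fps frames per second (> 0).
#' @param origin_time time of the first frame, seconds.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, origin_time = 0) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of H x W x 3 arrays")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("'fps' must be a positive scalar")
  d <- dim(frames[[1]])
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("frames must be H x W x 3 arrays")
  for (f in frames)
    if (!identical(dim(f), d)) stop("all frames must share one size")
  structure(list(frames = frames, fps = fps, origin_time = origin_time),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.3g fps, %.1f s\n",
              length(x$frames), d[1], d[2], x$fps, seq_duration(x)))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Duration of a sequence in seconds
#' @param seq a `frame_sequence`.
#' @export
seq_duration <- function(seq) length(seq$frames) / seq$fps

#' Load frames from a directory of ordered image files
#'
#' Reads an image-sequence directory (PNG/JPEG, ordered by file name) into a
#' [frame_sequence]. Image containers carry no rate metadata, so the nominal
#' rate is supplied by the caller (20 fps by default, the usual incubator
#' camera setting). Taking every `sampling`-th frame divides the recorded
#' rate accordingly.
#'
#' @param source path to a directory of image files.
#' @param sampling keep every `sampling`-th frame (default 1 = all).
#' @param fps nominal sampling rate of the stored frames.
#' @return a [frame_sequence].
#' @export
load_frames <- function(source, sampling = 1L, fps = 20) {
  if (!dir.exists(source)) {
    if (file.exists(source))
      stop("video containers are not supported; supply a directory of frames")
    stop("unreadable source: ", source)
  }
  files <- sort(list.files(source, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no image files found in ", source)
  sampling <- as.integer(sampling)
  if (sampling < 1L) stop("'sampling' must be >= 1")
  files <- files[seq(1L, length(files), by = sampling)]
  frames <- lapply(files, read_frame)
  d <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d)) stop("mixed frame sizes in ", source)
  frame_sequence(frames, fps = fps / sampling)
}

read_frame <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  # EBImage reads x-major (W x H); transpose to H x W
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  aperm(a, c(2L, 1L, 3L)) * 255
}

#' Write frames of a sequence as numbered PNG files
#' @param seq a [frame_sequence].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
write_frames <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_frames(seq))
  for (i in seq_len(n_frames(seq))) {
    paths[i] <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(clamp01(seq$frames[[i]] / 255), paths[i])
  }
  invisible(paths)
}

#' Read and write binary skin masks (single-channel PNG, 0 = non-skin,
#' 255 = skin)
#' @param path PNG file path.
#' @return `read_mask`: an integer `H x W` matrix of 0/1.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (a >= 0.5) + 0L
}

#' @rdname read_mask
#' @param mask binary matrix (0/1 or logical).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask)), path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Letterbox a frame to a square target
#'
#' Aspect-preserving bilinear resize onto a square black canvas. Landscape
#' sources are padded top/bottom, portrait sources left/right; an odd padding
#' remainder puts the extra row/column at the bottom/right. The pixel grid is
#' 0-based with a half-open content box.
#'
#' @param frame `H x W x C` array (or `H x W` matrix).
#' @param target square canvas side in pixels.
#' @param mask logical; if `TRUE` use nearest-neighbour resampling so binary
#'   labels stay binary.
#' @return list with `image` (the `target x target` result) and `transform`,
#'   a `letterbox_transform` with fields `target_size`, `content_box`
#'   (`x0, y0, w, h` in column/row order), and `scale`.
#' @export
letterbox_resize <- function(frame, target, mask = FALSE) {
  d <- dim(frame)
  if (is.null(d)) stop("frame must be a matrix or array")
  H <- d[1]; W <- d[2]
  if (target <= 0 || H == 0 || W == 0) stop("degenerate frame or target")
  scale <- target / max(H, W)
  if (W >= H) { # landscape: pad rows (top/bottom)
    w2 <- target; h2 <- round(target * H / W)
  } else {      # portrait: pad columns (left/right)
    h2 <- target; w2 <- round(target * W / H)
  }
  filt <- if (mask) "none" else "bilinear"
  content <- EBImage::imageData(EBImage::resize(frame, w = h2, h = w2,
                                                filter = filt))
  pad_top <- (target - h2) %/% 2L
  pad_left <- (target - w2) %/% 2L
  out <- if (length(d) == 3L) array(0, c(target, target, d[3]))
         else matrix(0, target, target)
  ri <- pad_top + seq_len(h2); ci <- pad_left + seq_len(w2)
  if (length(d) == 3L) out[ri, ci, ] <- content else out[ri, ci] <- content
  tf <- structure(list(target_size = target,
                       content_box = c(x0 = pad_left, y0 = pad_top,
                                       w = w2, h = h2),
                       scale = scale,
                       source_size = c(h = H, w = W)),
                  class = "letterbox_transform")
  list(image = out, transform = tf)
}

#' Map letterboxed coordinates back to source coordinates (or forward)
#'
#' @param transform a `letterbox_transform` from [letterbox_resize()].
#' @param xy two-column matrix of 0-based (col, row) coordinates.
#' @param inverse if `TRUE` (default) map target -> source, else
#'   source -> target.
#' @return two-column matrix of mapped coordinates.
#' @export
letterbox_map <- function(transform, xy, inverse = TRUE) {
  xy <- rbind(xy)
  box <- transform$content_box
  src <- transform$source_size
  sx <- box["w"] / src["w"]; sy <- box["h"] / src["h"]
  if (inverse)
    cbind((xy[, 1] - box["x0"]) / sx, (xy[, 2] - box["y0"]) / sy)
  else
    cbind(xy[, 1] * sx + box["x0"], xy[, 2] * sy + box["y0"])
}

#' Per-channel intensity means of a training corpus
#'
#' @param frames list of `H x W x 3` arrays or a [frame_sequence].
#' @return numeric length-3 vector (R, G, B) on the pixel scale.
#' @export
channel_means <- function(frames) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  acc <- c(0, 0, 0); n <- 0
  for (f in frames) {
    acc <- acc + c(sum(f[, , 1]), sum(f[, , 2]), sum(f[, , 3]))
    n <- n + length(f[, , 1])
  }
  stats::setNames(acc / n, c("r", "g", "b"))
}

#' Subtract fixed per-channel means from every frame
#'
#' Centering uses means computed once over the training corpus (see
#' [channel_means()]); they are configuration, not recomputed at inference.
#'
#' @param seq a [frame_sequence] or a single frame array.
#' @param means length-3 numeric vector on the pixel scale.
#' @return same type as `seq`, with centered (possibly negative) intensities.
#' @export
mean_subtract <- function(seq, means) {
  if (any(means < 0) || any(means > 255))
    stop("channel means outside pixel range")
  center <- function(f) {
    for (c in 1:3) f[, , c] <- f[, , c] - means[c]
    f
  }
  if (inherits(seq, "frame_sequence")) {
    seq$frames <- lapply(seq$frames, center)
    seq
  } else center(seq)
}
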