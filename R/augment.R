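#' Fit the lighting-variation model from a training corpus
#'
#' The average HSL lightness of every corpus image is histogrammed, the
#' lightness range is split into four uniform intervals, and the mean of the
#' values falling in each interval is recorded (an empty interval falls back
#' to its midpoint). Lighting augmentation later rescales an image's
#' lightness towards the means of intervals 2--4.
#'
#' @param corpus list of `H x W x 3` arrays (0--255) or a [frame_sequence].
#' @return a `lighting_model` with fields `interval_means` (length 4,
#'   strictly increasing) and `edges` (length 5).
#' @export
fit_lighting_model <- function(corpus) {
  if (inherits(corpus, "frame_sequence")) corpus <- corpus$frames
  if (length(corpus) == 0L) stop("empty corpus")
  avg <- vapply(corpus, function(f) mean(rgb_to_hsl(f / 255)[, , 3]), 0)
  rng <- range(avg)
  if (diff(rng) < 1e-8)
    stop("degenerate lightness histogram: corpus has no lightness variance")
  edges <- seq(rng[1], rng[2], length.out = 5L)
  bin <- pmin(pmax(findInterval(avg, edges, rightmost.closed = TRUE), 1L), 4L)
  means <- vapply(1:4, function(k) {
    v <- avg[bin == k]
    if (length(v)) mean(v) else (edges[k] + edges[k + 1]) / 2
  }, 0)
  structure(list(interval_means = means, edges = edges),
            class = "lighting_model")
}

#' Generate the three lighting variants of an image
#'
#' Variant `k` multiplies the HSL lightness channel so that the image's
#' average lightness matches interval mean `k + 1` of the fitted
#' [fit_lighting_model()] (intervals 2, 3 and 4); hue and saturation are
#' untouched and lightness is clipped to the valid range.
#'
#' @param image `H x W x 3` array, 0--255.
#' @param model a `lighting_model`.
#' @return list of exactly 3 images (0--255 arrays).
#' @export
lighting_variants <- function(image, model) {
  stopifnot(inherits(model, "lighting_model"))
  hsl <- rgb_to_hsl(image / 255)
  lbar <- mean(hsl[, , 3])
  if (lbar <= 0) stop("zero-lightness image: lightness scale undefined")
  lapply(model$interval_means[2:4], function(target) {
    v <- hsl
    v[, , 3] <- clamp01(hsl[, , 3] * (target / lbar))
    hsl_to_rgb(v) * 255
  })
}

#' Deterministic geometric variants: 7 rotations and 2 mirrors
#'
#' Rotations at 45-degree increments through 360 degrees (45, 90, ...,
#' 315) on the fixed square canvas, exposing black corners; mirrors about
#' the horizontal and vertical center axes. A paired mask undergoes the
#' identical transforms with nearest-neighbour interpolation so labels stay
#' binary.
#'
#' @param image square `H x H x C` array (post-letterbox) or `H x H` matrix.
#' @param mask optional binary matrix of the same spatial size.
#' @return list with `images` (named list of 9 arrays: `rot45` ... `rot315`,
#'   `mirror_x`, `mirror_y`) and `masks` (same names, or `NULL`).
#' @export
geometric_variants <- function(image, mask = NULL) {
  d <- dim(image)
  if (d[1] != d[2])
    stop("rotation without resizing requires a square image; letterbox first")
  rot <- function(x, a, filt) {
    EBImage::imageData(EBImage::rotate(x, a, filter = filt,
                                       output.dim = c(d[1], d[2]),
                                       bg.col = 0))
  }
  mirror_rows <- function(x) { # about the horizontal center axis
    if (length(dim(x)) == 3L) x[rev(seq_len(d[1])), , , drop = FALSE]
    else x[rev(seq_len(d[1])), , drop = FALSE]
  }
  mirror_cols <- function(x) {
    if (length(dim(x)) == 3L) x[, rev(seq_len(d[2])), , drop = FALSE]
    else x[, rev(seq_len(d[2])), drop = FALSE]
  }
  angles <- seq(45, 315, by = 45)
  images <- c(lapply(angles, function(a) rot(image, a, "bilinear")),
              list(mirror_rows(image), mirror_cols(image)))
  names(images) <- c(paste0("rot", angles), "mirror_x", "mirror_y")
  masks <- NULL
  if (!is.null(mask)) {
    masks <- c(lapply(angles, function(a) (rot(mask, a, "none") > 0.5) + 0L),
               list((mirror_rows(mask) > 0.5) + 0L,
                    (mirror_cols(mask) > 0.5) + 0L))
    names(masks) <- names(images)
  }
  list(images = images, masks = masks)
}

#' Random-jitter configuration
#'
#' @param translate_range maximum translation as a fraction of the image
#'   size (displacement drawn uniformly in +/- this fraction per axis).
#' @param scale_range two scaling-factor bounds, e.g. `c(0.90, 1.10)`.
#' @param rotate_range two rotation bounds in degrees.
#' @param mirror logical; when `TRUE` each axis is mirrored with
#'   probability 1/2.
#' @return a `jitter_config`.
#' @export
jitter_config <- function(translate_range = 0.1,
                          scale_range = c(0.90, 1.10),
                          rotate_range = c(0, 0),
                          mirror = FALSE) {
  stopifnot(translate_range >= 0,
            length(scale_range) == 2L, scale_range[1] <= scale_range[2],
            scale_range[1] > 0,
            length(rotate_range) == 2L, rotate_range[1] <= rotate_range[2])
  structure(list(translate_range = translate_range,
                 scale_range = scale_range,
                 rotate_range = rotate_range,
                 mirror = isTRUE(mirror)),
            class = "jitter_config")
}

#' Named jitter presets
#'
#' `"skin_net"`: +/-10% translation and 0.90--1.10 scaling.
#' `"intervention_net"`: +/-10% translation, 1.00--1.25 scaling,
#' +/-45 degree rotation and random mirroring.
#'
#' @param name preset name.
#' @return a [jitter_config].
#' @export
augment_preset <- function(name = c("skin_net", "intervention_net")) {
  switch(match.arg(name),
         skin_net = jitter_config(0.10, c(0.90, 1.10), c(0, 0), FALSE),
         intervention_net = jitter_config(0.10, c(1.00, 1.25),
                                          c(-45, 45), TRUE))
}

#' Draw one randomly jittered sample
#'
#' Applies a random translation, scaling, rotation and (optionally) mirror
#' about the image center in a single resampling step. A paired mask is
#' transformed with the identical parameters using nearest-neighbour
#' interpolation. Supplying `rng_seed` makes the draw reproducible.
#'
#' @param image `H x W x C` array or matrix.
#' @param cfg a [jitter_config].
#' @param rng_seed optional integer seed.
#' @param mask optional binary matrix.
#' @return list with `image`, `mask` (or `NULL`) and `params`, the drawn
#'   transform parameters.
#' @export
random_jitter <- function(image, cfg, rng_seed = NULL, mask = NULL) {
  stopifnot(inherits(cfg, "jitter_config"))
  draw <- function() {
    list(tx = stats::runif(1, -cfg$translate_range, cfg$translate_range),
         ty = stats::runif(1, -cfg$translate_range, cfg$translate_range),
         s = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
         theta = stats::runif(1, cfg$rotate_range[1], cfg$rotate_range[2]),
         mx = cfg$mirror && stats::runif(1) < 0.5,
         my = cfg$mirror && stats::runif(1) < 0.5)
  }
  p <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  out <- apply_jitter_params(image, p)
  mk <- NULL
  if (!is.null(mask))
    mk <- (apply_jitter_params(mask, p, nearest = TRUE) > 0.5) + 0L
  list(image = out, mask = mk, params = p)
}

# Apply a drawn jitter-parameter set to an image (or multi-channel stack);
# shared by both networks so paired inputs stay pixel-aligned.
apply_jitter_params <- function(image, p, nearest = FALSE) {
  d <- dim(image)
  if (p$s == 1 && p$theta == 0 && p$tx == 0 && p$ty == 0 && !p$mx && !p$my)
    return(image)
  th <- p$theta * pi / 180
  M <- p$s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
    diag(c(if (p$mx) -1 else 1, if (p$my) -1 else 1))
  ctr <- (c(d[1], d[2]) + 1) / 2
  tvec <- ctr - as.vector(ctr %*% M) + c(p$tx * d[1], p$ty * d[2])
  m <- rbind(M, tvec)
  EBImage::imageData(EBImage::affine(image, m,
                                     filter = if (nearest) "none"
                                              else "bilinear",
                                     output.dim = c(d[1], d[2]),
                                     bg.col = 0))
}
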