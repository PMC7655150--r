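#' Dense optical flow between two frames
#'
#' Coarse-to-fine variational flow (Horn--Schunck smoothness with
#' incremental warping on an image pyramid), computed on the grayscale
#' means of the inputs. Displacements are in pixels: `u` is horizontal
#' (columns), `v` vertical (rows).
#'
#' @param frameA,frameB `H x W x 3` arrays (0--255) or grayscale matrices
#'   of the same size.
#' @param alpha smoothness weight of the variational solver (on the
#'   unit-intensity scale).
#' @param n_levels maximum pyramid depth.
#' @param n_warps warping iterations per level.
#' @param n_iters relaxation iterations per warp.
#' @param mask optional logical matrix; flow outside it (e.g. letterbox
#'   padding) is zeroed.
#' @return a `flow_field`: list with matrices `u` and `v`.
#' @export
compute_flow <- function(frameA, frameB, alpha = 0.05, n_levels = 5L,
                         n_warps = 3L, n_iters = 60L, mask = NULL) {
  to_gray <- function(f) {
    if (length(dim(f)) == 3L) (f[, , 1] + f[, , 2] + f[, , 3]) / (3 * 255)
    else f / max(1, max(f))
  }
  a <- to_gray(frameA); b <- to_gray(frameB)
  if (!identical(dim(a), dim(b))) stop("frame size mismatch")
  fl <- cpp_hs_flow(a, b, alpha, as.integer(n_levels), as.integer(n_warps),
                    as.integer(n_iters))
  if (!is.null(mask)) {
    fl$u[!mask] <- 0
    fl$v[!mask] <- 0
  }
  structure(list(u = fl$u, v = fl$v), class = "flow_field")
}

round_half_up <- function(x) floor(x + 0.5)

#' Encode a flow field into two 8-bit images
#'
#' Each displacement component is clipped to +/- `clip_limit` pixels
#' (displacements larger than 40 px over one second rarely occur, and are
#' clipped to 40) and mapped linearly onto 0..255: `-clip -> 0`,
#' `0 -> 128` (round half up of 127.5), `+clip -> 255`.
#'
#' @param field a `flow_field` from [compute_flow()].
#' @param clip_limit clipping magnitude in pixels (default 40).
#' @return an `encoded_flow`: list with integer matrices `u`, `v` in 0..255
#'   and the `clip_limit`.
#' @export
encode_flow <- function(field, clip_limit = 40) {
  enc <- function(m) {
    m <- pmin(pmax(m, -clip_limit), clip_limit)
    matrix(as.integer(round_half_up((m + clip_limit) * 255 /
                                      (2 * clip_limit))), nrow(m))
  }
  structure(list(u = enc(field$u), v = enc(field$v),
                 clip_limit = clip_limit),
            class = "encoded_flow")
}

#' Decode an 8-bit encoded flow back to displacements
#'
#' Linear inverse of [encode_flow()]; code 255 maps back exactly to the
#' clip limit. Quantization error is at most `clip/255` px per component
#' (0.157 px at the default clip of 40) for a lossless container.
#'
#' @param enc an `encoded_flow` (or list with `u`, `v`, `clip_limit`).
#' @return a `flow_field`.
#' @export
decode_flow <- function(enc) {
  cl <- enc$clip_limit
  dec <- function(m) m * (2 * cl) / 255 - cl
  structure(list(u = dec(enc$u), v = dec(enc$v)), class = "flow_field")
}

#' Write / read an encoded flow pair on disk
#'
#' Components are stored as `<stem>_u.<ext>` and `<stem>_v.<ext>` with a
#' YAML sidecar `<stem>.yaml` carrying the clip limit and mapping
#' endpoints (needed for bit-exact decoding). JPEG (quality 90) matches
#' the storage-saving practice for long recordings; PNG is lossless.
#'
#' @param enc an `encoded_flow`.
#' @param stem file-path stem (no extension).
#' @param format `"jpeg"` or `"png"`.
#' @param quality JPEG quality.
#' @return `read_encoded_flow`: an `encoded_flow`.
#' @export
write_encoded_flow <- function(enc, stem, format = c("jpeg", "png"),
                               quality = 90) {
  format <- match.arg(format)
  ext <- if (format == "jpeg") "jpg" else "png"
  wr <- function(m, path) {
    img <- t(m) / 255 # EBImage writes x-major
    EBImage::writeImage(EBImage::Image(img), path, quality = quality)
  }
  wr(enc$u, paste0(stem, "_u.", ext))
  wr(enc$v, paste0(stem, "_v.", ext))
  yaml::write_yaml(list(clip_limit = enc$clip_limit, code_min = 0L,
                        code_max = 255L, format = format),
                   paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_encoded_flow
#' @export
read_encoded_flow <- function(stem) {
  side <- yaml::read_yaml(paste0(stem, ".yaml"))
  ext <- if (side$format == "jpeg") "jpg" else "png"
  rd <- function(path) {
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    matrix(as.integer(round_half_up(t(a) * 255)), ncol(a))
  }
  structure(list(u = rd(paste0(stem, "_u.", ext)),
                 v = rd(paste0(stem, "_v.", ext)),
                 clip_limit = side$clip_limit),
            class = "encoded_flow")
}

#' Build the 10-channel flow stack of one 5-second window
#'
#' From exactly six frames sampled 1 s apart, computes the five flows of
#' consecutive pairs and stacks their components in temporal order
#' `(u1, v1, u2, v2, ..., u5, v5)` after 8-bit encoding and decoding (the
#' lossy codec the classifier is trained on).
#'
#' @param frames list of exactly 6 frames (`H x W x 3` arrays).
#' @param encode apply the 8-bit codec round trip (default `TRUE`); set
#'   `FALSE` for raw flow.
#' @param ... passed to [compute_flow()].
#' @return `H x W x 10` array.
#' @export
window_flow_stack <- function(frames, encode = TRUE, ...) {
  if (length(frames) != 6L) stop("a 5 s window needs exactly 6 frames")
  d <- dim(frames[[1]])
  out <- array(0, c(d[1], d[2], 10L))
  for (k in 1:5) {
    fl <- compute_flow(frames[[k]], frames[[k + 1]], ...)
    if (encode) fl <- decode_flow(encode_flow(fl))
    out[, , 2 * k - 1] <- fl$u
    out[, , 2 * k] <- fl$v
  }
  out
}
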