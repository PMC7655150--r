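#' Configuration for the patient-detection + skin-segmentation network
#'
#' The network has a shared convolutional core (3x3 conv stacks, batch
#' normalization between every convolution and its ReLU, 2x2 max pooling
#' after each stage, overall subsampling factor 32), a detection head (1x1
#' convolution with two outputs on the last pooling stage, global average
#' pooling, softmax) and an FCN-style segmentation head (1x1 score
#' convolutions on pooling stages 3, 4 and 5 fused by x2, x2, x8 learned
#' upsampling with skip additions, per-pixel softmax).
#'
#' @param backbone `"tiny"` (five single-conv stages, 8--32 filters, for
#'   desk-scale work) or `"vgg16"` (the full 13-conv topology with the
#'   fully-connected layers converted to convolutions).
#' @param input_size square input side in pixels; must be divisible by 32.
#' @param detection_threshold presence probability at or above which the
#'   segmentation head is evaluated.
#' @param fc_dim channel width of the converted fully-connected layers
#'   (vgg16 backbone only).
#' @return a `skinnet_config`.
#' @export
skinnet_config <- function(backbone = c("tiny", "vgg16"), input_size = 64,
                           detection_threshold = 0.5, fc_dim = 4096) {
  backbone <- match.arg(backbone)
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  if (detection_threshold <= 0 || detection_threshold >= 1)
    stop("detection_threshold must be in (0,1)")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 n_classes = 2L, skip_stages = c(3L, 4L, 5L),
                 detection_threshold = detection_threshold,
                 fc_dim = as.integer(fc_dim)),
            class = "skinnet_config")
}

# Layer plan: stage conv counts/filters plus converted-fc widths.
skinnet_plan <- function(cfg) {
  if (cfg$backbone == "tiny")
    list(n_convs = rep(1L, 5), filters = c(8L, 16L, 16L, 32L, 32L),
         fc = integer(0))
  else
    list(n_convs = c(2L, 2L, 3L, 3L, 3L),
         filters = c(64L, 128L, 256L, 512L, 512L),
         fc = c(cfg$fc_dim, cfg$fc_dim))
}

#' Build the patient-detection + skin-segmentation network
#'
#' Allocates all parameters: Xavier-initialized convolutions with zero
#' biases, unit-gain batch normalization, and transpose-convolution
#' upsamplers initialized as bilinear interpolation filters with no bias.
#'
#' @param cfg a [skinnet_config()].
#' @return a `skinnet` object (environment) holding parameters, batch-norm
#'   state, the channel means used for input centering, and a counter of
#'   segmentation-head evaluations.
#' @export
build_skinnet <- function(cfg) {
  stopifnot(inherits(cfg, "skinnet_config"))
  plan <- skinnet_plan(cfg)
  params <- list()
  bn <- list()
  cin <- 3L
  for (s in seq_along(plan$n_convs)) {
    for (j in seq_len(plan$n_convs[s])) {
      nm <- sprintf("s%dc%d", s, j)
      f <- plan$filters[s]
      params[[paste0(nm, "_w")]] <- xavier_init(3L, 3L, cin, f)
      params[[paste0(nm, "_b")]] <- numeric(f)
      params[[paste0(nm, "_bn_gamma")]] <- rep(1, f)
      params[[paste0(nm, "_bn_beta")]] <- numeric(f)
      bn[[nm]] <- list(mean = numeric(f), var = rep(1, f))
      cin <- f
    }
  }
  if (length(plan$fc)) {
    ks <- c(7L, 1L)
    for (j in seq_along(plan$fc)) {
      nm <- sprintf("fc%d", 5L + j)
      params[[paste0(nm, "_w")]] <- xavier_init(ks[j], ks[j], cin, plan$fc[j])
      params[[paste0(nm, "_b")]] <- numeric(plan$fc[j])
      params[[paste0(nm, "_bn_gamma")]] <- rep(1, plan$fc[j])
      params[[paste0(nm, "_bn_beta")]] <- numeric(plan$fc[j])
      bn[[nm]] <- list(mean = numeric(plan$fc[j]), var = rep(1, plan$fc[j]))
      cin <- plan$fc[j]
    }
  }
  f3 <- plan$filters[3]; f4 <- plan$filters[4]
  params$det_w <- xavier_init(1L, 1L, plan$filters[5], 2L)
  params$det_b <- numeric(2)
  params$score32_w <- xavier_init(1L, 1L, cin, 2L)
  params$score32_b <- numeric(2)
  params$score16_w <- xavier_init(1L, 1L, f4, 2L)
  params$score16_b <- numeric(2)
  params$score8_w <- xavier_init(1L, 1L, f3, 2L)
  params$score8_b <- numeric(2)
  params$up2a_w <- bilinear_kernel(2L, 2L)
  params$up2b_w <- bilinear_kernel(2L, 2L)
  params$up8_w <- bilinear_kernel(8L, 2L)
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$plan <- plan
  net$params <- params
  net$bn <- bn
  net$means <- c(0, 0, 0)
  net$n_seg_evals <- 0L
  class(net) <- "skinnet"
  net
}

#' @export
print.skinnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<skinnet> backbone=%s input=%d params=%s\n",
              x$cfg$backbone, x$cfg$input_size, format(np, big.mark = ",")))
  invisible(x)
}

# Shared core forward.  x: H x W x 3 x N (already centered).  Returns the
# core output, the three tapped pooling stages and (if training) caches.
skin_core_fw <- function(net, x, training = FALSE) {
  plan <- net$plan
  caches <- list()
  taps <- list()
  cur <- x
  for (s in seq_along(plan$n_convs)) {
    for (j in seq_len(plan$n_convs[s])) {
      nm <- sprintf("s%dc%d", s, j)
      xin <- cur
      z <- conv_f(xin, net$params[[paste0(nm, "_w")]],
                  net$params[[paste0(nm, "_b")]])
      bnr <- bn_f(z, net$params[[paste0(nm, "_bn_gamma")]],
                  net$params[[paste0(nm, "_bn_beta")]],
                  net$bn[[nm]], training)
      net$bn[[nm]] <- bnr$state
      y <- relu_f(bnr$y)
      if (training)
        caches[[nm]] <- list(x = xin, bn = bnr[c("xhat", "inv")], y = y)
      cur <- y
    }
    pl <- pool_f(cur, 2L)
    if (training)
      caches[[sprintf("pool%d", s)]] <- list(idx = pl$idx, xdim = dim(cur))
    cur <- pl$y
    if (s %in% c(3L, 4L, 5L)) taps[[sprintf("pool%d", s)]] <- cur
  }
  for (j in seq_along(plan$fc)) {
    nm <- sprintf("fc%d", 5L + j)
    xin <- cur
    z <- conv_f(xin, net$params[[paste0(nm, "_w")]],
                net$params[[paste0(nm, "_b")]])
    bnr <- bn_f(z, net$params[[paste0(nm, "_bn_gamma")]],
                net$params[[paste0(nm, "_bn_beta")]],
                net$bn[[nm]], training)
    net$bn[[nm]] <- bnr$state
    y <- relu_f(bnr$y)
    if (training)
      caches[[nm]] <- list(x = xin, bn = bnr[c("xhat", "inv")], y = y)
    cur <- y
  }
  list(out = cur, taps = taps, caches = caches)
}

# Backward through the shared core given gradients at the core output and
# at the tapped pooling stages (NULL where unused).
skin_core_bw <- function(net, caches, d_out, d_taps) {
  plan <- net$plan
  grads <- list()
  cur <- d_out
  conv_bn_bw <- function(nm, dy) {
    cc <- caches[[nm]]
    dy <- relu_b(cc$y, dy)
    bnb <- bn_b(cc$bn, net$params[[paste0(nm, "_bn_gamma")]], dy)
    grads[[paste0(nm, "_bn_gamma")]] <<- bnb$dgamma
    grads[[paste0(nm, "_bn_beta")]] <<- bnb$dbeta
    cb <- conv_b(cc$x, net$params[[paste0(nm, "_w")]], bnb$dx)
    grads[[paste0(nm, "_w")]] <<- cb$dw
    grads[[paste0(nm, "_b")]] <<- cb$db
    cb$dx
  }
  for (j in rev(seq_along(plan$fc)))
    cur <- conv_bn_bw(sprintf("fc%d", 5L + j), cur)
  for (s in rev(seq_along(plan$n_convs))) {
    tap <- d_taps[[sprintf("pool%d", s)]]
    if (!is.null(tap)) cur <- cur + tap
    pc <- caches[[sprintf("pool%d", s)]]
    cur <- pool_b(pc$idx, cur, pc$xdim)
    for (j in rev(seq_len(plan$n_convs[s])))
      cur <- conv_bn_bw(sprintf("s%dc%d", s, j), cur)
  }
  list(grads = grads, dx = cur)
}

# Detection head forward: 1x1 conv on pool5 -> GAP -> softmax.
det_head_fw <- function(net, pool5) {
  z <- conv_f(pool5, net$params$det_w, net$params$det_b)
  logits <- gap_f(z)                       # 2 x N
  list(probs = softmax_cols(logits), z = z, pool5 = pool5)
}

# Segmentation head forward: score convs + skip-fused upsampling.
seg_head_fw <- function(net, core_out, taps) {
  p <- net$params
  s32 <- conv_f(core_out, p$score32_w, p$score32_b)
  u1 <- tconv_f(s32, p$up2a_w, 2L)
  s16 <- conv_f(taps$pool4, p$score16_w, p$score16_b)
  f16 <- u1 + s16
  u2 <- tconv_f(f16, p$up2b_w, 2L)
  s8 <- conv_f(taps$pool3, p$score8_w, p$score8_b)
  f8 <- u2 + s8
  logits <- tconv_f(f8, p$up8_w, 8L)
  list(probs = softmax_pixels(logits), logits = logits,
       s32 = s32, f16 = f16, f8 = f8, core_out = core_out, taps = taps)
}

seg_head_bw <- function(net, cache, dlogits) {
  p <- net$params
  grads <- list()
  tb <- tconv_b(cache$f8, p$up8_w, dlogits, 8L)
  grads$up8_w <- tb$dw
  df8 <- tb$dx
  cb <- conv_b(cache$taps$pool3, p$score8_w, df8)
  grads$score8_w <- cb$dw; grads$score8_b <- cb$db
  d_pool3 <- cb$dx
  tb <- tconv_b(cache$f16, p$up2b_w, df8, 2L)
  grads$up2b_w <- tb$dw
  df16 <- tb$dx
  cb <- conv_b(cache$taps$pool4, p$score16_w, df16)
  grads$score16_w <- cb$dw; grads$score16_b <- cb$db
  d_pool4 <- cb$dx
  tb <- tconv_b(cache$s32, p$up2a_w, df16, 2L)
  grads$up2a_w <- tb$dw
  cb <- conv_b(cache$core_out, p$score32_w, tb$dx)
  grads$score32_w <- cb$dw; grads$score32_b <- cb$db
  list(grads = grads, d_core = cb$dx, d_pool4 = d_pool4, d_pool3 = d_pool3)
}

center_input <- function(net, frames) {
  # frames: list of H x W x 3 arrays -> centered H x W x 3 x N batch
  H <- dim(frames[[1]])[1]
  x <- array(0, c(H, H, 3L, length(frames)))
  for (i in seq_along(frames))
    x[, , , i] <- frames[[i]]
  for (c in 1:3) x[, , c, ] <- x[, , c, ] - net$means[c]
  x
}

#' Run the network on one frame with conditional execution
#'
#' The detection head always runs; the segmentation head is evaluated only
#' if the presence probability reaches the detection threshold, and the
#' evaluation counter `net$n_seg_evals` is incremented accordingly.
#'
#' @param net a trained [build_skinnet()] network.
#' @param frame `H x W x 3` array (0--255) with `H = W = cfg$input_size`.
#' @return list with `score` (named probabilities `absent`, `present`) and
#'   `map` (the skin-confidence matrix, or `NULL` when the patient is
#'   absent).
#' @export
skinnet_forward <- function(net, frame) {
  d <- dim(frame)
  if (d[1] != net$cfg$input_size || d[2] != net$cfg$input_size)
    stop("frame size does not match cfg$input_size; letterbox first")
  x <- center_input(net, list(frame))
  core <- skin_core_fw(net, x, training = FALSE)
  det <- det_head_fw(net, core$taps$pool5)
  score <- stats::setNames(det$probs[, 1], c("absent", "present"))
  map <- NULL
  if (score["present"] >= net$cfg$detection_threshold) {
    net$n_seg_evals <- net$n_seg_evals + 1L
    seg <- seg_head_fw(net, core$out, core$taps)
    map <- seg$probs[, , 2, 1]
  }
  list(score = score, map = map)
}

#' Threshold a skin-confidence map into a binary skin label
#' @param map matrix of per-pixel skin probabilities in `[0,1]`.
#' @param theta threshold in (0,1); a pixel is skin iff `p >= theta`.
#' @return integer 0/1 matrix.
#' @export
threshold_map <- function(map, theta = 0.5) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0,1)")
  (map >= theta) + 0L
}

#' Detection loss: multinomial logistic loss on a probability pair
#' @param score numeric pair `(p_absent, p_present)`.
#' @param truth `"absent"` or `"present"`.
#' @return negative log probability of the true class (probability clamped
#'   at 1e-12).
#' @export
detection_loss <- function(score, truth = c("absent", "present")) {
  truth <- match.arg(truth)
  if (any(score < 0) || abs(sum(score) - 1) > 1e-6)
    stop("score must be a probability pair")
  p <- if (truth == "absent") score[[1]] else score[[2]]
  -log(max(p, 1e-12))
}

#' Class-balanced segmentation loss
#'
#' Per-pixel negative log-likelihood summed over the image, with each pixel
#' weighted by `1 / (2 * frequency of its true class)` so that skin and
#' non-skin contribute equally regardless of class imbalance (a uniform
#' predictor scores `log 2` on any two-class truth). Single-class truths
#' fall back to the plain per-pixel mean.
#'
#' @param map matrix of per-pixel skin probabilities.
#' @param truth binary matrix (1 = skin) of the same size.
#' @return scalar loss.
#' @export
segmentation_loss <- function(map, truth) {
  if (!identical(dim(map), dim(truth))) stop("map/truth size mismatch")
  truth <- truth > 0
  p_true <- ifelse(truth, map, 1 - map)
  p_true <- pmax(p_true, 1e-12)
  n_skin <- sum(truth)
  n <- length(truth)
  if (n_skin == 0 || n_skin == n) return(mean(-log(p_true)))
  w <- ifelse(truth, 1 / (2 * n_skin), 1 / (2 * (n - n_skin)))
  sum(w * -log(p_true))
}

#' Joint multi-task loss
#' @param l_det detection loss.
#' @param l_seg segmentation loss.
#' @param weights non-negative weight pair, default equal.
#' @return `weights[1] * l_det + weights[2] * l_seg`.
#' @export
joint_loss <- function(l_det, l_seg, weights = c(1, 1)) {
  if (any(weights < 0)) stop("weights must be non-negative")
  weights[1] * l_det + weights[2] * l_seg
}

#' Training schedule for the skin network
#'
#' Stage 1 trains the shared core and segmentation head on positive images
#' only (learning rate 1e-2); stage 2 trains all layers jointly on positive
#' and negative images (learning rate 1e-4). Both decay the rate by a
#' factor of 10 every `decay_every` epochs with momentum 0.90 and batch
#' size 20.
#'
#' @param stage 1 or 2.
#' @param epochs number of epochs to run.
#' @param lr_start initial learning rate (stage default if `NULL`).
#' @param decay_every epochs between 10x learning-rate drops.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param loss_weights detection/segmentation loss weights (stage 2).
#' @return a `training_schedule`.
#' @export
training_schedule <- function(stage, epochs = 10L, lr_start = NULL,
                              decay_every = 2L, batch_size = 20L,
                              momentum = 0.90, loss_weights = c(1, 1)) {
  stopifnot(stage %in% c(1L, 2L))
  if (is.null(lr_start)) lr_start <- if (stage == 1) 1e-2 else 1e-4
  stopifnot(lr_start > 0, momentum >= 0, momentum < 1)
  structure(list(stage = as.integer(stage), epochs = as.integer(epochs),
                 lr_start = lr_start, decay_every = decay_every,
                 decay_factor = 10, batch_size = as.integer(batch_size),
                 momentum = momentum, loss_weights = loss_weights),
            class = "training_schedule")
}

# Balanced per-pixel CE loss and logit gradient for one image.
seg_loss_grad <- function(probs, truth) {
  # probs: H x W x 2, channel 2 = skin
  truth <- truth > 0
  n_skin <- sum(truth)
  n <- length(truth)
  w <- if (n_skin == 0 || n_skin == n) matrix(1 / n, nrow(truth), ncol(truth))
       else ifelse(truth, 1 / (2 * n_skin), 1 / (2 * (n - n_skin)))
  p_true <- ifelse(truth, probs[, , 2], probs[, , 1])
  loss <- sum(w * -log(pmax(p_true, 1e-12)))
  dz <- probs
  dz[, , 1] <- w * (probs[, , 1] - !truth)
  dz[, , 2] <- w * (probs[, , 2] - truth)
  list(loss = loss, dz = dz)
}

#' Train the skin network (two-stage procedure)
#'
#' @param net a [build_skinnet()] network.
#' @param data list with `images` (list of `H x W x 3` arrays, 0--255),
#'   `masks` (list of binary matrices, `NULL` entries for negatives) and
#'   `present` (logical vector).
#' @param schedule a [training_schedule()].
#' @param verbose print per-epoch losses.
#' @return the network, invisibly; per-epoch losses are appended to
#'   `net$history`.
#' @export
train_skinnet <- function(net, data, schedule, verbose = FALSE) {
  stopifnot(inherits(schedule, "training_schedule"))
  if (schedule$stage == 2 && is.null(net$history) &&
      net$cfg$backbone == "vgg16")
    warning("stage-2 training without stage-1 weights on a from-scratch ",
            "vgg16 backbone")
  if (all(net$means == 0))
    net$means <- channel_means(data$images)
  use <- if (schedule$stage == 1) which(data$present) else
    seq_along(data$images)
  if (length(use) == 0L) stop("no training images for this stage")
  vel <- list()
  hist <- net$history
  for (ep in seq_len(schedule$epochs)) {
    lr <- lr_at(ep - 1L, schedule$lr_start, schedule$decay_every,
                schedule$decay_factor)
    ord <- sample(use)
    ep_det <- ep_seg <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = schedule$batch_size)) {
      idx <- ord[b0:min(b0 + schedule$batch_size - 1L, length(ord))]
      x <- center_input(net, data$images[idx])
      core <- skin_core_fw(net, x, training = TRUE)
      seg <- seg_head_fw(net, core$out, core$taps)
      N <- length(idx)
      dlogits <- seg$logits * 0
      l_seg <- 0
      for (k in seq_len(N)) {
        truth <- data$masks[[idx[k]]]
        if (is.null(truth))
          truth <- matrix(0L, dim(x)[1], dim(x)[2])
        sg <- seg_loss_grad(seg$probs[, , , k], truth)
        l_seg <- l_seg + sg$loss / N
        dlogits[, , , k] <- sg$dz / N
      }
      l_det <- 0
      d_det_pool5 <- NULL
      grads_det <- list()
      if (schedule$stage == 2) {
        det <- det_head_fw(net, core$taps$pool5)
        y <- rbind(as.numeric(!data$present[idx]),
                   as.numeric(data$present[idx]))
        l_det <- mean(-log(pmax(colSums(det$probs * y), 1e-12)))
        dgap <- (det$probs - y) / N * schedule$loss_weights[1]
        dz <- gap_b(dgap, dim(det$z))
        cb <- conv_b(core$taps$pool5, net$params$det_w, dz)
        grads_det <- list(det_w = cb$dw, det_b = cb$db)
        d_det_pool5 <- cb$dx
      }
      sb <- seg_head_bw(net, seg, dlogits * schedule$loss_weights[2])
      d_taps <- list(pool3 = sb$d_pool3, pool4 = sb$d_pool4)
      d_core <- sb$d_core
      if (!is.null(d_det_pool5)) {
        if (length(net$plan$fc) == 0L) d_core <- d_core + d_det_pool5
        else d_taps$pool5 <- d_det_pool5
      }
      cbw <- skin_core_bw(net, core$caches, d_core, d_taps)
      grads <- c(cbw$grads, sb$grads, grads_det)
      st <- sgd_step(net$params, grads, vel, lr, schedule$momentum)
      net$params <- st$params
      vel <- st$vel
      ep_det <- ep_det + l_det; ep_seg <- ep_seg + l_seg; nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(stage = schedule$stage, epoch = ep,
                                   lr = lr, det_loss = ep_det / nb,
                                   seg_loss = ep_seg / nb))
    if (verbose)
      message(sprintf("stage %d epoch %d lr %.1e det %.4f seg %.4f",
                      schedule$stage, ep, lr, ep_det / nb, ep_seg / nb))
  }
  net$history <- hist
  invisible(net)
}

#' Intersection-over-union of two binary masks
#' @param a,b binary matrices. An empty union is scored 1.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Save / load a skin network
#'
#' The checkpoint is R's native serialized form; a YAML sidecar
#' (`<path>.yaml`) records the configuration and channel means.
#' @param net a `skinnet`.
#' @param path checkpoint file path.
#' @export
save_skinnet <- function(net, path) {
  saveRDS(list(cfg = net$cfg, params = net$params, bn = net$bn,
               means = net$means, history = net$history), path)
  yaml::write_yaml(list(backbone = net$cfg$backbone,
                        input_size = net$cfg$input_size,
                        detection_threshold = net$cfg$detection_threshold,
                        channel_means = as.list(net$means)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_skinnet
#' @export
load_skinnet <- function(path) {
  s <- readRDS(path)
  net <- new.env(parent = emptyenv())
  net$cfg <- s$cfg; net$plan <- skinnet_plan(s$cfg)
  net$params <- s$params; net$bn <- s$bn; net$means <- s$means
  net$history <- s$history; net$n_seg_evals <- 0L
  class(net) <- "skinnet"
  net
}
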