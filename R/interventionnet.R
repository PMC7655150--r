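#' Sliding-window configuration
#'
#' A window of `T` seconds advancing in `tau`-second steps; each window
#' samples `T + 1` frames one second apart (6 frames for the default 5 s
#' window, giving 5 flow pairs).
#'
#' @param T window length, seconds.
#' @param tau step size, seconds.
#' @return a `window_config`.
#' @export
window_config <- function(T = 5, tau = 1) {
  if (!(T >= tau && tau > 0)) stop("need T >= tau > 0")
  structure(list(T = T, tau = tau, frames_per_window = as.integer(T + 1L)),
            class = "window_config")
}

#' Slice a recording into sliding windows
#'
#' Window starts are `0, tau, 2 tau, ...`; the count is
#' `floor((duration - T)/tau) + 1`. Each window records the indices of its
#' `T + 1` frames sampled one second apart (the final sample of the last
#' window clamps to the last recorded frame).
#'
#' @param seq a [frame_sequence].
#' @param cfg a [window_config()].
#' @return list of windows, each `list(start_time, frame_idx)`.
#' @export
make_windows <- function(seq, cfg = window_config()) {
  dur <- seq_duration(seq)
  if (dur < cfg$T) stop("recording shorter than the window length")
  starts <- seq(0, dur - cfg$T, by = cfg$tau)
  lapply(starts, function(s) {
    idx <- pmin(round((s + 0:cfg$T) * seq$fps) + 1L, n_frames(seq))
    list(start_time = s, frame_idx = as.integer(idx))
  })
}

#' Label a window from its per-second activity states
#'
#' A window is `intervention` iff strictly more than half of its labelled
#' time is intervention. Windows overlapping patient absence are excluded
#' from training and get `NA`.
#'
#' @param states character vector of per-second states covering the window.
#' @return `"intervention"`, `"non-intervention"`, or `NA` (absence).
#' @export
label_window <- function(states) {
  if (any(states == "absent")) return(NA_character_)
  if (sum(states == "intervention") > length(states) / 2) "intervention"
  else "non-intervention"
}

#' Two-stream intervention-network configuration
#'
#' @param backbone `"tiny"` (three strided-convolution stages for
#'   desk-scale work) or `"resnet50"` (requires externally supplied
#'   pretrained weights, treated as a non-bundled asset).
#' @param input_size square spatial input side.
#' @param fusion_channels outputs of the 1x1 fusion convolution.
#' @param filters per-stage filter counts of the tiny backbone.
#' @return an `interventionnet_config`.
#' @export
interventionnet_config <- function(backbone = c("tiny", "resnet50"),
                                   input_size = 64L,
                                   fusion_channels = 512L,
                                   filters = c(8L, 16L, 32L)) {
  backbone <- match.arg(backbone)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 fusion_channels = as.integer(fusion_channels),
                 filters = as.integer(filters)),
            class = "interventionnet_config")
}

#' Adapt a first-layer convolution kernel to a new channel count
#'
#' Cross-modality initialization: the original kernels are averaged over
#' their input-channel dimension and the average is replicated across the
#' new channels (so the sum over input channels grows by
#' `new_channels / old_channels`).
#'
#' @param w kernel array `kh x kw x Cin x Cout`.
#' @param new_channels target input channel count.
#' @return `kh x kw x new_channels x Cout` array.
#' @export
adapt_first_conv <- function(w, new_channels) {
  d <- dim(w)
  avg <- apply(w, c(1, 2, 4), mean) # kh x kw x Cout
  out <- array(0, c(d[1], d[2], new_channels, d[4]))
  for (k in seq_len(new_channels)) out[, , k, ] <- avg
  out
}

# One stream: strided conv-BN-ReLU stages; classification head (GAP + FC)
# used when the stream is trained individually, removed under fusion.
build_stream <- function(cfg, in_channels) {
  if (cfg$backbone == "resnet50")
    stop("the resnet50 backbone needs externally supplied pretrained ",
         "weights; use backbone = 'tiny' or load a checkpoint")
  params <- list()
  bn <- list()
  cin <- in_channels
  for (s in seq_along(cfg$filters)) {
    f <- cfg$filters[s]
    nm <- sprintf("c%d", s)
    w <- xavier_init(3L, 3L, if (s == 1) 3L else cin, f)
    if (s == 1) w <- adapt_first_conv(w, in_channels) # cross-modality init
    params[[paste0(nm, "_w")]] <- w
    params[[paste0(nm, "_b")]] <- numeric(f)
    params[[paste0(nm, "_bn_gamma")]] <- rep(1, f)
    params[[paste0(nm, "_bn_beta")]] <- numeric(f)
    bn[[nm]] <- list(mean = numeric(f), var = rep(1, f))
    cin <- f
  }
  params$head_w <- matrix(stats::rnorm(2 * cin, 0, sqrt(1 / cin)), 2, cin)
  params$head_b <- numeric(2)
  list(params = params, bn = bn, in_channels = in_channels,
       out_channels = cin)
}

#' Build the context stream (6-channel skin-confidence input)
#'
#' The first convolution accepts the 6 stacked confidence maps, its
#' kernels initialized by averaging 3-channel kernels across the input
#' dimension and replicating ([adapt_first_conv()]); under fusion the
#' stream outputs feature maps (its pooling/classifier head is removed).
#'
#' @param cfg an [interventionnet_config()].
#' @return a stream (parameter list).
#' @export
build_context_stream <- function(cfg) build_stream(cfg, 6L)

#' Build the optical-flow stream (10-channel encoded-flow input)
#' @param cfg an [interventionnet_config()].
#' @return a stream (parameter list).
#' @export
build_flow_stream <- function(cfg) build_stream(cfg, 10L)

stream_fw <- function(stream, x, training = FALSE) {
  caches <- list()
  cur <- x
  for (s in seq_along(stream$bn)) {
    nm <- sprintf("c%d", s)
    xin <- cur
    z <- conv_f(xin, stream$params[[paste0(nm, "_w")]],
                stream$params[[paste0(nm, "_b")]], stride = 2L, pad = 1L)
    bnr <- bn_f(z, stream$params[[paste0(nm, "_bn_gamma")]],
                stream$params[[paste0(nm, "_bn_beta")]],
                stream$bn[[nm]], training)
    stream$bn[[nm]] <- bnr$state
    cur <- relu_f(bnr$y)
    if (training)
      caches[[nm]] <- list(x = xin, bn = bnr[c("xhat", "inv")], y = cur)
  }
  list(features = cur, caches = caches, stream = stream)
}

stream_bw <- function(stream, caches, dfeat) {
  grads <- list()
  cur <- dfeat
  for (s in rev(seq_along(stream$bn))) {
    nm <- sprintf("c%d", s)
    cc <- caches[[nm]]
    cur <- relu_b(cc$y, cur)
    bnb <- bn_b(cc$bn, stream$params[[paste0(nm, "_bn_gamma")]], cur)
    grads[[paste0(nm, "_bn_gamma")]] <- bnb$dgamma
    grads[[paste0(nm, "_bn_beta")]] <- bnb$dbeta
    cb <- conv_b(cc$x, stream$params[[paste0(nm, "_w")]], bnb$dx,
                 stride = 2L, pad = 1L)
    grads[[paste0(nm, "_w")]] <- cb$dw
    grads[[paste0(nm, "_b")]] <- cb$db
    cur <- cb$dx
  }
  grads
}

#' Assemble the fused two-stream intervention network
#'
#' @param cfg an [interventionnet_config()].
#' @param ctx,flow optionally pre-trained streams (from
#'   [build_context_stream()] / [build_flow_stream()], possibly after
#'   stage-1 training); new streams are built when omitted.
#' @return an `interventionnet` environment.
#' @export
build_interventionnet <- function(cfg = interventionnet_config(),
                                  ctx = NULL, flow = NULL) {
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$ctx <- ctx %||% build_context_stream(cfg)
  net$flow <- flow %||% build_flow_stream(cfg)
  cc <- net$ctx$out_channels + net$flow$out_channels
  fc <- cfg$fusion_channels
  net$fuse <- list(fuse_w = xavier_init(1L, 1L, cc, fc),
                   fuse_b = numeric(fc),
                   fc_w = matrix(stats::rnorm(2 * fc, 0, sqrt(1 / fc)), 2, fc),
                   fc_b = numeric(2))
  net$means <- c(context = 0, motion = 0)
  class(net) <- "interventionnet"
  net
}

#' Fuse stream features and classify the window
#'
#' Channel concatenation, 1x1 fusion convolution (`fusion_channels`
#' outputs, ReLU), global average pooling, a two-output fully-connected
#' layer and softmax.
#'
#' @param net an `interventionnet`.
#' @param ctx_features,flow_features feature maps `H x W x C x N` on the
#'   same spatial grid.
#' @param training keep caches for backpropagation.
#' @return list with `probs` (2 x N matrix, rows `intervention`,
#'   `non_intervention`) and caches when training.
#' @export
fuse_and_classify <- function(net, ctx_features, flow_features,
                              training = FALSE) {
  dc <- dim(ctx_features); df <- dim(flow_features)
  if (!all(dc[c(1, 2, 4)] == df[c(1, 2, 4)]))
    stop("stream feature maps must share a spatial grid")
  x <- array(0, c(dc[1], dc[2], dc[3] + df[3], dc[4]))
  x[, , seq_len(dc[3]), ] <- ctx_features
  x[, , dc[3] + seq_len(df[3]), ] <- flow_features
  z <- conv_f(x, net$fuse$fuse_w, net$fuse$fuse_b)
  a <- relu_f(z)
  v <- gap_f(a)
  logits <- fc_f(v, net$fuse$fc_w, net$fuse$fc_b)
  probs <- softmax_cols(logits)
  rownames(probs) <- c("intervention", "non_intervention")
  out <- list(probs = probs)
  if (training) out <- c(out, list(x = x, a = a, v = v, nc = dc[3]))
  out
}

fuse_bw <- function(net, cache, dlogits) {
  fb <- fc_b(cache$v, net$fuse$fc_w, dlogits)
  da <- gap_b(fb$dx, dim(cache$a))
  dz <- relu_b(cache$a, da)
  cb <- conv_b(cache$x, net$fuse$fuse_w, dz)
  list(grads = list(fuse_w = cb$dw, fuse_b = cb$db,
                    fc_w = fb$dw, fc_b = fb$db),
       d_ctx = cb$dx[, , seq_len(cache$nc), , drop = FALSE],
       d_flow = cb$dx[, , -seq_len(cache$nc), , drop = FALSE])
}

#' Training schedule for the intervention network
#'
#' Stage 1 trains each stream individually with its own pooling +
#' fully-connected head (learning rate 1e-3, divided by 10 every 12000
#' iterations, batch 24). Stage 2 trains only the layers added after
#' fusion (1e-5, divided by 10 every 6000 iterations, batch 12). Momentum
#' 0.90 throughout; every iteration samples windows uniformly across the
#' two classes.
#'
#' @param stage 1 or 2.
#' @param n_iters iterations to run.
#' @param lr_start,decay_every,batch_size overrides of the stage defaults.
#' @param momentum SGD momentum.
#' @param augment apply the intervention-net jitter preset to each sampled
#'   window (both stacks, identical parameters).
#' @return an `intervention_schedule`.
#' @export
intervention_schedule <- function(stage, n_iters = 200L, lr_start = NULL,
                                  decay_every = NULL, batch_size = NULL,
                                  momentum = 0.90, augment = TRUE) {
  stopifnot(stage %in% c(1L, 2L))
  structure(list(stage = as.integer(stage), n_iters = as.integer(n_iters),
                 lr_start = lr_start %||% c(1e-3, 1e-5)[stage],
                 decay_every = decay_every %||% c(12000L, 6000L)[stage],
                 batch_size = batch_size %||% c(24L, 12L)[stage],
                 momentum = momentum, augment = isTRUE(augment)),
            class = "intervention_schedule")
}

sample_balanced <- function(labels, n) {
  # uniform over classes, with replacement
  cls <- split(seq_along(labels), labels)
  unlist(lapply(cls, function(ix) sample(ix, ceiling(n / length(cls)),
                                         replace = TRUE)))[seq_len(n)]
}

stack_batch <- function(stacks, idx, jitter_params = NULL) {
  d <- dim(stacks[[idx[1]]])
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (k in seq_along(idx)) {
    s <- stacks[[idx[k]]]
    if (!is.null(jitter_params)) s <- apply_jitter_params(s, jitter_params[[k]])
    x[, , , k] <- s
  }
  x
}

draw_jitter <- function(n, preset = augment_preset("intervention_net")) {
  lapply(seq_len(n), function(i) random_jitter(matrix(0, 2, 2), preset)$params)
}

label_onehot <- function(labels, idx) {
  y <- rbind(as.numeric(labels[idx] == "intervention"),
             as.numeric(labels[idx] != "intervention"))
  y
}

#' Train the two-stream intervention network
#'
#' @param net a [build_interventionnet()] model.
#' @param data list with `context` (list of `H x W x 6` stacks), `motion`
#'   (list of `H x W x 10` stacks) and `label` (character,
#'   `"intervention"` / `"non-intervention"`; `NA` windows are dropped).
#' @param schedule an [intervention_schedule()].
#' @param verbose print running losses.
#' @return the model, invisibly; losses in `net$history`.
#' @export
train_interventionnet <- function(net, data, schedule, verbose = FALSE) {
  keep <- which(!is.na(data$label))
  labels <- data$label[keep]
  context <- data$context[keep]
  motion <- data$motion[keep]
  if (length(unique(labels)) < 2)
    stop("training needs both intervention and non-intervention windows")
  if (all(net$means == 0)) {
    net$means <- c(context = mean(vapply(context, mean, 0)),
                   motion = mean(vapply(motion, mean, 0)))
  }
  if (schedule$stage == 2 && is.null(net$history))
    stop("fusion training requested before stream training")
  vel_ctx <- vel_flow <- vel_fuse <- list()
  hist <- net$history
  for (it in seq_len(schedule$n_iters)) {
    lr <- lr_at(it - 1L, schedule$lr_start, schedule$decay_every)
    idx <- sample_balanced(labels, schedule$batch_size)
    jp <- if (schedule$augment) draw_jitter(length(idx)) else NULL
    xc <- stack_batch(context, idx, jp) - net$means["context"]
    xf <- stack_batch(motion, idx, jp) - net$means["motion"]
    y <- label_onehot(labels, idx)
    N <- length(idx)
    if (schedule$stage == 1) {
      loss <- 0
      for (sname in c("ctx", "flow")) {
        stream <- net[[sname]]
        x <- if (sname == "ctx") xc else xf
        fw <- stream_fw(stream, x, training = TRUE)
        net[[sname]] <- fw$stream # running BN stats
        v <- gap_f(fw$features)
        probs <- softmax_cols(fc_f(v, stream$params$head_w,
                                   stream$params$head_b))
        loss <- loss + mean(-log(pmax(colSums(probs * y), 1e-12)))
        dlog <- (probs - y) / N
        fb <- fc_b(v, stream$params$head_w, dlog)
        dfeat <- gap_b(fb$dx, dim(fw$features))
        grads <- stream_bw(net[[sname]], fw$caches, dfeat)
        grads$head_w <- fb$dw
        grads$head_b <- fb$db
        vel <- if (sname == "ctx") vel_ctx else vel_flow
        st <- sgd_step(net[[sname]]$params, grads, vel, lr,
                       schedule$momentum)
        net[[sname]]$params <- st$params
        if (sname == "ctx") vel_ctx <- st$vel else vel_flow <- st$vel
      }
      loss <- loss / 2
    } else {
      fc_ <- stream_fw(net$ctx, xc, training = FALSE)
      ff_ <- stream_fw(net$flow, xf, training = FALSE)
      out <- fuse_and_classify(net, fc_$features, ff_$features,
                               training = TRUE)
      loss <- mean(-log(pmax(colSums(out$probs * y), 1e-12)))
      dlog <- (out$probs - y) / N
      fb <- fuse_bw(net, out, dlog)
      st <- sgd_step(net$fuse, fb$grads, vel_fuse, lr, schedule$momentum)
      net$fuse <- st$params
      vel_fuse <- st$vel
    }
    hist <- rbind(hist, data.frame(stage = schedule$stage, iter = it,
                                   lr = lr, loss = loss))
    if (verbose && it %% 20 == 0)
      message(sprintf("stage %d iter %d loss %.4f", schedule$stage, it, loss))
  }
  net$history <- hist
  invisible(net)
}

#' Score one window with the fused network
#'
#' @param net a trained `interventionnet`.
#' @param context `H x W x 6` confidence stack.
#' @param motion `H x W x 10` decoded-flow stack.
#' @return named probability pair (`intervention`, `non_intervention`).
#' @export
predict_window <- function(net, context, motion) {
  d <- dim(context)
  xc <- array(context - net$means["context"], c(d[1], d[2], 6L, 1L))
  xf <- array(motion - net$means["motion"], c(d[1], d[2], 10L, 1L))
  fc_ <- stream_fw(net$ctx, xc, training = FALSE)
  ff_ <- stream_fw(net$flow, xf, training = FALSE)
  out <- fuse_and_classify(net, fc_$features, ff_$features)
  stats::setNames(out$probs[, 1], c("intervention", "non_intervention"))
}

#' Predict the per-second activity timeline of a recording
#'
#' Frames are sampled at 1 Hz and passed through the skin network; seconds
#' whose frame is classified patient-absent are `absent` (absence takes
#' precedence over everything). Windows are scored with the fused
#' two-stream model, each second averages `p_intervention` over all
#' windows covering it, and seconds at or above 0.5 become
#' `intervention`; the rest are `valid`.
#'
#' @param seq a [frame_sequence] of square frames matching the skin
#'   network input size.
#' @param skinnet a trained skin network.
#' @param net a trained `interventionnet`.
#' @param wcfg a [window_config()].
#' @return an [activity_timeline].
#' @export
predict_timeline <- function(seq, skinnet, net, wcfg = window_config()) {
  dur <- floor(seq_duration(seq))
  if (dur < wcfg$T) stop("recording shorter than the window length")
  sec <- 0:dur
  idx <- pmin(round(sec * seq$fps) + 1L, n_frames(seq))
  sz <- skinnet$cfg$input_size
  maps <- vector("list", length(sec))
  present <- logical(length(sec))
  for (k in seq_along(sec)) {
    fw <- skinnet_forward(skinnet, seq$frames[[idx[k]]])
    present[k] <- !is.null(fw$map)
    maps[[k]] <- fw$map %||% matrix(0, sz, sz)
  }
  flows <- vector("list", length(sec) - 1L)
  for (k in seq_len(length(sec) - 1L)) {
    fl <- compute_flow(seq$frames[[idx[k]]], seq$frames[[idx[k + 1]]])
    flows[[k]] <- decode_flow(encode_flow(fl))
  }
  starts <- seq(0, dur - wcfg$T, by = wcfg$tau)
  p_sum <- numeric(dur)
  p_n <- numeric(dur)
  for (s in starts) {
    # windows overlapping patient absence are never scored, mirroring
    # their exclusion from training; their seconds fall back to the
    # absence/valid states
    if (any(!present[s + 1:6])) next
    ctx <- array(0, c(sz, sz, 6L))
    mot <- array(0, c(sz, sz, 10L))
    for (k in 0:5) ctx[, , k + 1] <- maps[[s + k + 1]]
    for (k in 1:5) {
      mot[, , 2 * k - 1] <- flows[[s + k]]$u
      mot[, , 2 * k] <- flows[[s + k]]$v
    }
    p <- predict_window(net, ctx, mot)[["intervention"]]
    cover <- (s + 1):min(s + wcfg$T, dur)
    p_sum[cover] <- p_sum[cover] + p
    p_n[cover] <- p_n[cover] + 1
  }
  states <- ifelse(!present[seq_len(dur)], "absent",
                   ifelse(p_sum / pmax(p_n, 1) >= 0.5, "intervention",
                          "valid"))
  activity_timeline(states)
}

#' Write / read a per-second timeline CSV (`second,state`)
#' @param timeline an [activity_timeline].
#' @param path CSV path.
#' @export
write_timeline <- function(timeline, path) {
  utils::write.csv(data.frame(second = seq_along(timeline$states) - 1L +
                                timeline$start_time,
                              state = timeline$states),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_timeline(d$state, start_time = d$second[1])
}

#' Save / load an intervention network
#' @param net an `interventionnet`.
#' @param path checkpoint path.
#' @export
save_interventionnet <- function(net, path) {
  saveRDS(list(cfg = net$cfg, ctx = net$ctx, flow = net$flow,
               fuse = net$fuse, means = net$means, history = net$history),
          path)
  yaml::write_yaml(list(backbone = net$cfg$backbone,
                        input_size = net$cfg$input_size,
                        fusion_channels = net$cfg$fusion_channels),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_interventionnet
#' @export
load_interventionnet <- function(path) {
  s <- readRDS(path)
  net <- new.env(parent = emptyenv())
  net$cfg <- s$cfg; net$ctx <- s$ctx; net$flow <- s$flow
  net$fuse <- s$fuse; net$means <- s$means; net$history <- s$history
  class(net) <- "interventionnet"
  net
}
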