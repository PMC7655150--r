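#' Seed set for interactive segmentation
#'
#' Brush-stroke pixels marking known skin and non-skin areas; star centers
#' (a subset of the skin seeds, by default all of them) anchor the
#' geodesic star-convexity shape prior.
#'
#' @param skin,nonskin two-column matrices of 1-based (row, col) pixel
#'   coordinates; the sets must be disjoint.
#' @param star_centers two-column matrix, defaults to `skin`.
#' @return a `seed_set`.
#' @export
seed_set <- function(skin, nonskin, star_centers = skin) {
  skin <- rbind(skin); nonskin <- rbind(nonskin)
  star_centers <- rbind(star_centers)
  if (nrow(skin) == 0 || nrow(nonskin) == 0)
    stop("both seed classes must be non-empty")
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(skin), key(nonskin))))
    stop("seed sets must be disjoint")
  structure(list(skin = skin, nonskin = nonskin,
                 star_centers = star_centers),
            class = "seed_set")
}

#' Read / write seeds as CSV (`x,y,class`; x = column, y = row, 0-based)
#' @param seeds a [seed_set].
#' @param path CSV path.
#' @export
write_seeds <- function(seeds, path) {
  df <- rbind(data.frame(x = seeds$skin[, 2] - 1L, y = seeds$skin[, 1] - 1L,
                         class = "skin"),
              data.frame(x = seeds$nonskin[, 2] - 1L,
                         y = seeds$nonskin[, 1] - 1L, class = "nonskin"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seed_set(skin = cbind(df$y[df$class == "skin"] + 1L,
                        df$x[df$class == "skin"] + 1L),
           nonskin = cbind(df$y[df$class == "nonskin"] + 1L,
                           df$x[df$class == "nonskin"] + 1L))
}

# ----------------------------------------------------------------- color GMMs

# Gaussian mixture with diagonal covariances in a standard parameter list;
# fitted with mclust when the data support it, with a k-means + moment
# fallback for (near-)degenerate inputs.  Color values on the [0, 1] scale.
fit_gmm <- function(X, k) {
  X <- rbind(X)
  n <- nrow(X); d <- ncol(X)
  if (k > n) stop("more mixture components than pixels")
  floor_var <- 1e-4
  k_eff <- min(k, nrow(unique(X)))
  fit <- NULL
  if (k_eff > 1 && n > 3 * k_eff && all(apply(X, 2, stats::sd) > 1e-6)) {
    fit <- tryCatch(
      suppressWarnings({
        bic <- mclust::mclustBIC(X, G = k_eff, modelNames = "VVI",
                                 verbose = FALSE)
        mclust::Mclust(X, x = bic, verbose = FALSE)
      }),
      error = function(e) NULL)
  }
  if (!is.null(fit) && !is.null(fit$parameters)) {
    pr <- fit$parameters
    vars <- t(apply(pr$variance$sigma, 3, diag))
    list(weights = pr$pro, means = t(pr$mean),
         vars = pmax(matrix(vars, ncol = d), floor_var))
  } else if (k_eff >= n) {
    list(weights = rep(1 / n, n), means = X,
         vars = matrix(floor_var, n, d))
  } else {
    cl <- if (k_eff > 1)
      tryCatch(stats::kmeans(X, k_eff, nstart = 3)$cluster,
               error = function(e) rep(1L, n))
    else rep(1L, n)
    means <- vars <- matrix(0, k_eff, d)
    w <- numeric(k_eff)
    for (j in seq_len(k_eff)) {
      Xi <- X[cl == j, , drop = FALSE]
      means[j, ] <- colMeans(Xi)
      vars[j, ] <- pmax(apply(Xi, 2, stats::var), floor_var)
      vars[j, is.na(vars[j, ])] <- floor_var
      w[j] <- nrow(Xi) / n
    }
    list(weights = w, means = means, vars = vars)
  }
}

gmm_density <- function(gmm, X) {
  X <- rbind(X)
  out <- numeric(nrow(X))
  for (j in seq_along(gmm$weights)) {
    mu <- gmm$means[j, ]; v <- gmm$vars[j, ]
    q <- rep(0, nrow(X))
    for (c in seq_along(mu)) q <- q + (X[, c] - mu[c])^2 / v[c]
    out <- out + gmm$weights[j] *
      exp(-0.5 * q) / sqrt((2 * pi)^length(mu) * prod(v))
  }
  out
}

#' Fit per-class color models from an annotated image
#'
#' Learns one Gaussian mixture per class (skin, non-skin) from the labeled
#' pixels, recording the class proportions as priors; used to propagate a
#' skin label to the following frame.
#'
#' @param image `H x W x 3` array (0--255).
#' @param label binary matrix (1 = skin) with both classes present.
#' @param k_components mixture components per class.
#' @return a `color_model`.
#' @export
fit_color_models <- function(image, label, k_components = 5L) {
  label <- label > 0
  if (!any(label) || all(label)) stop("label must contain both classes")
  X <- pixel_colors(image)
  skin <- fit_gmm(X[c(label), , drop = FALSE], k_components)
  nonskin <- fit_gmm(X[!c(label), , drop = FALSE], k_components)
  structure(list(skin = skin, nonskin = nonskin,
                 prior_skin = mean(label)),
            class = "color_model")
}

pixel_colors <- function(image) {
  cbind(c(image[, , 1]), c(image[, , 2]), c(image[, , 3])) / 255
}

#' Per-pixel skin probability under a color model
#' @param model a [fit_color_models()] result.
#' @param image `H x W x 3` array.
#' @return matrix of posterior skin probabilities.
#' @export
skin_probability <- function(model, image) {
  X <- pixel_colors(image)
  fs <- gmm_density(model$skin, X) * model$prior_skin
  fn <- gmm_density(model$nonskin, X) * (1 - model$prior_skin)
  matrix(fs / pmax(fs + fn, 1e-300), dim(image)[1])
}

# ------------------------------------------------------- graph-cut with GSC

#' Parameters of the graph-cut energy
#'
#' Unary terms are negative log GMM likelihoods fitted from the seed
#' strokes; the pairwise term is the contrast-sensitive boundary cost
#' `lambda * exp(-beta ||ci - cj||^2) / dist(i,j)` with `beta` set to the
#' reciprocal of twice the mean squared neighbor color difference. Star
#' convexity adds infinite-capacity edges from each pixel to its
#' predecessor on the geodesic path (on a gradient-magnitude-weighted
#' 8-connected grid, weight `1 + geo_gamma * gradient`) towards the
#' nearest star center.
#'
#' @param lambda pairwise weight (0 disables smoothness).
#' @param k_components GMM components per seed class.
#' @param geo_gamma gradient weight of the geodesic metric.
#' @param star enforce the star-convexity constraint.
#' @return a `gsc_params` list.
#' @export
gsc_params <- function(lambda = 2, k_components = 5L, geo_gamma = 20,
                       star = TRUE) {
  list(lambda = lambda, k_components = k_components,
       geo_gamma = geo_gamma, star = isTRUE(star))
}

grad_magnitude <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  gx <- cbind(gray[, 2:W], gray[, W]) - cbind(gray[, 1], gray[, 1:(W - 1)])
  gy <- rbind(gray[2:H, ], gray[H, ]) - rbind(gray[1, ], gray[1:(H - 1), ])
  sqrt(gx^2 + gy^2) / 2
}

# 8-neighborhood directed edge list of an H x W grid (1-based node ids,
# column-major), one direction per pair; returned as from/to/dist columns.
grid_edges <- function(H, W) {
  id <- matrix(seq_len(H * W), H, W)
  e <- list(
    list(id[-H, ], id[-1, ], 1),                 # down
    list(id[, -W], id[, -1], 1),                 # right
    list(id[-H, -W], id[-1, -1], sqrt(2)),       # down-right
    list(id[-1, -W], id[-H, -1], sqrt(2)))       # up-right
  cbind(from = unlist(lapply(e, function(x) c(x[[1]]))),
        to = unlist(lapply(e, function(x) c(x[[2]]))),
        dist = unlist(lapply(e, function(x) rep(x[[3]], length(x[[1]])))))
}

#' Graph-cut skin segmentation with geodesic star convexity
#'
#' Minimizes a color + contrast-boundary energy subject to hard seed
#' constraints and (optionally) geodesic star convexity with respect to
#' the star centers: along the geodesic path from any pixel to its star
#' center, skin membership is monotone.
#'
#' @param image `H x W x 3` array (0--255).
#' @param seeds a [seed_set()].
#' @param params a [gsc_params()] list.
#' @return binary skin label (integer matrix).
#' @export
gsc_segment <- function(image, seeds, params = gsc_params()) {
  stopifnot(inherits(seeds, "seed_set"))
  H <- dim(image)[1]; W <- dim(image)[2]
  n <- H * W
  X <- pixel_colors(image)
  pix_id <- function(m) (m[, 2] - 1L) * H + m[, 1]
  skin_idx <- pix_id(seeds$skin)
  non_idx <- pix_id(seeds$nonskin)
  if (any(c(skin_idx, non_idx) < 1) || any(c(skin_idx, non_idx) > n))
    stop("seeds outside the image")
  kc <- params$k_components
  gmm_s <- fit_gmm(X[skin_idx, , drop = FALSE], min(kc, length(skin_idx)))
  gmm_n <- fit_gmm(X[non_idx, , drop = FALSE], min(kc, length(non_idx)))
  U_skin <- -log(pmax(gmm_density(gmm_s, X), 1e-20))
  U_non <- -log(pmax(gmm_density(gmm_n, X), 1e-20))
  INF <- 1e9
  s_node <- n + 1L; t_node <- n + 2L
  # terminal links: cap(s->p) paid when p is labeled non-skin, and
  # conversely; seeds get infinite links on their own side
  cap_s <- U_non
  cap_t <- U_skin
  cap_s[skin_idx] <- INF
  cap_t[non_idx] <- INF
  ed <- grid_edges(H, W)
  cd <- (X[ed[, "from"], ] - X[ed[, "to"], ])^2
  cd <- rowSums(cd)
  pair_cap <- if (params$lambda > 0) {
    beta <- 1 / max(2 * mean(cd), 1e-12)
    params$lambda * exp(-beta * cd) / ed[, "dist"]
  } else rep(0, nrow(ed))
  from <- c(rep(s_node, n), seq_len(n), ed[, "from"], ed[, "to"])
  to <- c(seq_len(n), rep(t_node, n), ed[, "to"], ed[, "from"])
  cap <- c(cap_s, cap_t, pair_cap, pair_cap)
  if (params$star) {
    gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / (3 * 255)
    geo <- cpp_geodesic_parents(grad_magnitude(gray),
                                as.integer(pix_id(seeds$star_centers)),
                                params$geo_gamma)
    has_par <- which(geo$parent > 0)
    from <- c(from, has_par)
    to <- c(to, geo$parent[has_par])
    cap <- c(cap, rep(INF, length(has_par)))
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n + 2L,
                          directed = TRUE)
  cut <- igraph::min_cut(g, source = s_node, target = t_node,
                         capacity = pmin(cap, INF), value.only = FALSE)
  lab <- matrix(0L, H, W)
  src_side <- setdiff(as.integer(cut$partition1), c(s_node, t_node))
  if (!(s_node %in% as.integer(cut$partition1)))
    src_side <- setdiff(as.integer(cut$partition2), c(s_node, t_node))
  lab[src_side] <- 1L
  lab
}

#' Propose segmentation seeds for the next frame
#'
#' Seeds are placed inside high-confidence regions of the propagated color
#' model (posterior skin probability at or above `conf_floor` for skin
#' seeds, at or below `1 - conf_floor` for non-skin) and spread out with
#' Mitchell's best-candidate (farthest-point) sampling.
#'
#' @param next_image `H x W x 3` array.
#' @param model a [fit_color_models()] result from the previous frame.
#' @param n_seeds seeds per class.
#' @param rng_seed integer seed for reproducible placement.
#' @param conf_floor posterior confidence floor.
#' @param n_candidates candidates examined per accepted seed.
#' @return a [seed_set()] whose star centers are the skin seeds.
#' @export
propose_seeds <- function(next_image, model, n_seeds = 20L, rng_seed = 1L,
                          conf_floor = 0.9, n_candidates = 10L) {
  p <- skin_probability(model, next_image)
  skin_pool <- which(p >= conf_floor, arr.ind = TRUE)
  non_pool <- which(p <= 1 - conf_floor, arr.ind = TRUE)
  if (nrow(skin_pool) == 0 || nrow(non_pool) == 0)
    stop("no pixels exceed the confidence floor for one class")
  withr::with_seed(rng_seed, {
    sk <- mitchell_sample(skin_pool, min(n_seeds, nrow(skin_pool)),
                          n_candidates)
    nk <- mitchell_sample(non_pool, min(n_seeds, nrow(non_pool)),
                          n_candidates)
    seed_set(skin = sk, nonskin = nk)
  })
}

#' Mitchell's best-candidate point sampling
#'
#' Greedy farthest-point heuristic: each new point is the best of
#' `n_candidates` uniform draws, maximizing the minimum distance to the
#' points already chosen.
#'
#' @param pool two-column coordinate matrix to sample from.
#' @param n points to place.
#' @param n_candidates candidates per placement.
#' @return two-column coordinate matrix (`n` rows).
#' @export
mitchell_sample <- function(pool, n, n_candidates = 10L) {
  pool <- rbind(pool)
  chosen <- pool[sample.int(nrow(pool), 1L), , drop = FALSE]
  while (nrow(chosen) < n) {
    cand <- pool[sample.int(nrow(pool), n_candidates, replace = TRUE), ,
                 drop = FALSE]
    dmin <- apply(cand, 1, function(q)
      min((chosen[, 1] - q[1])^2 + (chosen[, 2] - q[2])^2))
    chosen <- rbind(chosen, cand[which.max(dmin), ])
  }
  unname(chosen)
}

#' Consensus rule for multi-annotator labels
#' @param n_annotators annotators asked.
#' @param pixel_quorum votes for a pixel to count as skin.
#' @param image_quorum annotators that must supply a label for the image
#'   to be positive.
#' @export
consensus_rule <- function(n_annotators = 3L, pixel_quorum = 2L,
                           image_quorum = 2L) {
  stopifnot(pixel_quorum <= n_annotators, image_quorum <= n_annotators)
  structure(list(n_annotators = n_annotators, pixel_quorum = pixel_quorum,
                 image_quorum = image_quorum), class = "consensus_rule")
}

#' Combine annotator labels into a consensus skin label
#'
#' The image is positive iff at least `image_quorum` annotators supplied a
#' label (did not skip); a pixel of a positive image is skin iff at least
#' `pixel_quorum` of the suppliers marked it skin.
#'
#' @param labels list of binary matrices; `NULL` entries are skips.
#' @param rule a [consensus_rule()].
#' @return consensus binary matrix, or `NULL` when the image is negative.
#' @export
combine_annotations <- function(labels, rule = consensus_rule()) {
  supplied <- Filter(Negate(is.null), labels)
  if (length(supplied) < rule$image_quorum) return(NULL)
  d <- dim(supplied[[1]])
  for (l in supplied)
    if (!identical(dim(l), d)) stop("annotator masks on different grids")
  votes <- Reduce(`+`, lapply(supplied, function(m) (m > 0) + 0L))
  (votes >= rule$pixel_quorum) + 0L
}

#' Inter-annotator agreement ratio
#'
#' Ratio of the intersection of skin labels provided by at least two
#' annotators to the union provided by the three; an empty union scores 1.
#'
#' @param labels list of three binary matrices on one grid.
#' @return agreement in `[0, 1]`.
#' @export
agreement_score <- function(labels) {
  stopifnot(length(labels) == 3L)
  votes <- Reduce(`+`, lapply(labels, function(m) (m > 0) + 0L))
  union <- sum(votes >= 1)
  if (union == 0) return(1)
  sum(votes >= 2) / union
}
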