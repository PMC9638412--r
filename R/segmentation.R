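# A compact multi-resolution encoder-decoder for semantic segmentation,
# with training (Adam, MSE) and tiled inference. Tensors are R arrays in
# [H, W, C, N] layout; convolutions run through im2col GEMM kernels in C++.
#
# Topology: a stem of A blocks (conv + batch-norm + ReLU) and bottleneck
# blocks at full resolution; parallel branches at 1, 1/2, 1/4, ...
# resolution, each opened by a stride-2 A block and carrying basic residual
# blocks; all branch outputs are bilinearly upsampled to full resolution,
# concatenated, and fed to a 1x1 convolution with a sigmoid head, so the
# output is a [0, 1] probability map of the input's spatial size.

# ---- tree utilities over nested parameter lists ---------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) if (is.null(e)) NULL else tree_map(f, e))
  else f(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))  # NULL members stay NULL
    names(out) <- names(a)
    for (i in seq_along(a)) {
      if (!is.null(a[[i]])) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    }
    out
  } else f(a, b)
}

tree_sum <- function(f, x) {
  if (is.list(x)) sum(vapply(x, function(e) if (is.null(e)) 0 else tree_sum(f, e),
                             numeric(1)))
  else f(x)
}

# ---- primitive layers -----------------------------------------------------

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

channel_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

from_channel_matrix <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(x, gamma, beta, st, training) {
  d <- dim(x)
  xp <- channel_matrix(x)
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
    st$mean <- BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * mu
    st$var <- BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- st$mean
    v <- st$var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(xp, 2, mu, "-"), 2, invstd, "*")
  yp <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = from_channel_matrix(yp, d), st = st,
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

bn_bwd <- function(gy, gamma, cache) {
  gyp <- channel_matrix(gy)
  m <- nrow(gyp)
  gbeta <- colSums(gyp)
  ggamma <- colSums(gyp * cache$xhat)
  gxhat <- sweep(gyp, 2, gamma, "*")
  s1 <- colSums(gxhat)
  s2 <- colSums(gxhat * cache$xhat)
  gxp <- sweep(gxhat - sweep(cache$xhat, 2, s2 / m, "*"), 2, s1 / m, "-")
  gxp <- sweep(gxp, 2, cache$invstd, "*")
  list(gx = from_channel_matrix(gxp, cache$d), ggamma = ggamma, gbeta = gbeta)
}

# conv -> batch norm -> (optional ReLU)
cb_fwd <- function(x, prm, st, stride, training, relu = TRUE) {
  z <- cpp_conv_fwd(x, prm$w, as.integer(stride))
  bn <- bn_fwd(z, prm$gamma, prm$beta, st, training)
  y <- bn$y
  mask <- NULL
  if (relu) {
    mask <- y > 0
    y <- y * mask
  }
  list(y = y, st = bn$st, cache = list(x = x, bn = bn$cache, mask = mask))
}

cb_bwd <- function(gy, prm, cache, stride) {
  if (!is.null(cache$mask)) gy <- gy * cache$mask
  b <- bn_bwd(gy, prm$gamma, cache$bn)
  cv <- cpp_conv_bwd(cache$x, prm$w, b$gx, as.integer(stride))
  list(gx = cv$gx, grads = list(w = cv$gw, gamma = b$ggamma, beta = b$gbeta))
}

new_cb <- function(k, cin, cout) {
  list(w = he_init(k, cin, cout), gamma = rep(1, cout), beta = rep(0, cout))
}

new_bn_stats <- function(cout) list(mean = rep(0, cout), var = rep(1, cout))

# basic residual block: [conv3 bn relu, conv3 bn] + skip, relu
basic_fwd <- function(x, prm, st, training) {
  a <- cb_fwd(x, prm$c1, st$c1, 1, training, relu = TRUE)
  b <- cb_fwd(a$y, prm$c2, st$c2, 1, training, relu = FALSE)
  s <- b$y + x
  mask <- s > 0
  list(y = s * mask, st = list(c1 = a$st, c2 = b$st),
       cache = list(a = a$cache, b = b$cache, mask = mask))
}

basic_bwd <- function(gy, prm, cache) {
  g <- gy * cache$mask
  b <- cb_bwd(g, prm$c2, cache$b, 1)
  a <- cb_bwd(b$gx, prm$c1, cache$a, 1)
  list(gx = a$gx + g, grads = list(c1 = a$grads, c2 = b$grads))
}

# bottleneck block: [conv1 bn relu (C/2), conv3 bn relu (C/2), conv1 bn (C)]
# + skip, relu; keeps spatial resolution while enlarging the receptive field
bottleneck_fwd <- function(x, prm, st, training) {
  a <- cb_fwd(x, prm$c1, st$c1, 1, training, relu = TRUE)
  b <- cb_fwd(a$y, prm$c2, st$c2, 1, training, relu = TRUE)
  cc <- cb_fwd(b$y, prm$c3, st$c3, 1, training, relu = FALSE)
  s <- cc$y + x
  mask <- s > 0
  list(y = s * mask, st = list(c1 = a$st, c2 = b$st, c3 = cc$st),
       cache = list(a = a$cache, b = b$cache, cc = cc$cache, mask = mask))
}

bottleneck_bwd <- function(gy, prm, cache) {
  g <- gy * cache$mask
  cc <- cb_bwd(g, prm$c3, cache$cc, 1)
  b <- cb_bwd(cc$gx, prm$c2, cache$b, 1)
  a <- cb_bwd(b$gx, prm$c1, cache$a, 1)
  list(gx = a$gx + g, grads = list(c1 = a$grads, c2 = b$grads, c3 = cc$grads))
}

# ---- model ---------------------------------------------------------------

#' Build a segmentation model
#'
#' Initializes all parameters (He-normal convolution weights, unit-gain
#' batch norm) for the architecture described by `config`. The parameter
#' count is a deterministic function of the configuration.
#'
#' @param config a [SegModelConfig-class].
#' @param seed RNG seed for weight initialization.
#' @return A [SegModel-class].
#' @examples
#' m <- buildSegModel(SegModelConfig(inputSize = c(64, 64),
#'                                   baseChannels = 4, nBranches = 2))
#' nParameters(m)
#' @export
buildSegModel <- function(config = SegModelConfig(), seed = 1) {
  validObject(config)
  C <- config@baseChannels
  Cm <- max(1, floor(C / 2))
  nb <- config@nBranches
  with_seed(seed, {
    params <- list()
    stats <- list()
    cin <- 3
    params$stem <- list(); stats$stem <- list()
    for (i in seq_len(config@stemABlocks)) {
      params$stem[[i]] <- new_cb(3, cin, C)
      stats$stem[[i]] <- new_bn_stats(C)
      cin <- C
    }
    params$bott <- list(); stats$bott <- list()
    for (i in seq_len(config@stemBottlenecks)) {
      params$bott[[i]] <- list(c1 = new_cb(1, C, Cm), c2 = new_cb(3, Cm, Cm),
                               c3 = new_cb(1, Cm, C))
      stats$bott[[i]] <- list(c1 = new_bn_stats(Cm), c2 = new_bn_stats(Cm),
                              c3 = new_bn_stats(C))
    }
    params$branches <- list(); stats$branches <- list()
    for (k in seq_len(nb)) {
      ck <- C * 2^(k - 1)
      br <- list(down = NULL, blocks = list())
      sbr <- list(down = NULL, blocks = list())
      if (k > 1) {
        br$down <- new_cb(3, C * 2^(k - 2), ck)
        sbr$down <- new_bn_stats(ck)
      }
      for (j in seq_len(config@branchBlocks)) {
        br$blocks[[j]] <- list(c1 = new_cb(3, ck, ck), c2 = new_cb(3, ck, ck))
        sbr$blocks[[j]] <- list(c1 = new_bn_stats(ck), c2 = new_bn_stats(ck))
      }
      params$branches[[k]] <- br
      stats$branches[[k]] <- sbr
    }
    ctot <- C * (2^nb - 1)
    params$head <- list(w = he_init(1, ctot, 1), b = 0)
    env <- new.env(parent = emptyenv())
    env$params <- params
    env$stats <- stats
    env$step <- 0L
    env$adam <- NULL
    new("SegModel", config = config, env = env)
  })
}

#' Number of trainable parameters
#' @param model a [SegModel-class].
#' @return integer count.
#' @export
nParameters <- function(model) {
  tree_sum(length, model@env$params)
}

concat_channels <- function(pieces) {
  d1 <- dim(pieces[[1]])
  ctot <- sum(vapply(pieces, function(p) dim(p)[3], numeric(1)))
  out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
  at <- 0
  for (p in pieces) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

model_fwd <- function(model, x, training) {
  prm <- model@env$params
  st <- model@env$stats
  cache <- list(
    stem = vector("list", length(prm$stem)),
    bott = vector("list", length(prm$bott)),
    branches = lapply(prm$branches, function(br)
      list(down = NULL, blocks = vector("list", length(br$blocks)))))
  h <- x
  for (i in seq_along(prm$stem)) {
    r <- cb_fwd(h, prm$stem[[i]], st$stem[[i]], 1, training)
    h <- r$y; st$stem[[i]] <- r$st; cache$stem[[i]] <- r$cache
  }
  for (i in seq_along(prm$bott)) {
    r <- bottleneck_fwd(h, prm$bott[[i]], st$bott[[i]], training)
    h <- r$y; st$bott[[i]] <- r$st; cache$bott[[i]] <- r$cache
  }
  branch_out <- list()
  bh <- h
  for (k in seq_along(prm$branches)) {
    br <- prm$branches[[k]]
    if (k > 1) {
      r <- cb_fwd(bh, br$down, st$branches[[k]]$down, 2, training)
      bh <- r$y; st$branches[[k]]$down <- r$st; cache$branches[[k]]$down <- r$cache
    }
    for (j in seq_along(br$blocks)) {
      r <- basic_fwd(bh, br$blocks[[j]], st$branches[[k]]$blocks[[j]], training)
      bh <- r$y
      st$branches[[k]]$blocks[[j]] <- r$st
      cache$branches[[k]]$blocks[[j]] <- r$cache
    }
    branch_out[[k]] <- bh
  }
  ups <- list(branch_out[[1]])
  if (length(branch_out) > 1) {
    for (k in 2:length(branch_out)) {
      ups[[k]] <- cpp_bilinear_up(branch_out[[k]], as.integer(2^(k - 1)))
    }
  }
  cat_in <- concat_channels(ups)
  z <- cpp_conv_fwd(cat_in, prm$head$w, 1L) + prm$head$b
  p <- 1 / (1 + exp(-z))
  cache$cat_in <- cat_in
  cache$branch_dims <- lapply(branch_out, dim)
  cache$p <- p
  if (training) model@env$stats <- st
  list(p = p, cache = cache)
}

model_bwd <- function(model, cache, gp) {
  prm <- model@env$params
  gz <- gp * cache$p * (1 - cache$p)
  cv <- cpp_conv_bwd(cache$cat_in, prm$head$w, gz, 1L)
  grads <- list(head = list(w = cv$gw, b = sum(gz)))
  gcat <- cv$gx
  nb <- length(prm$branches)
  at <- 0
  gstem_accum <- NULL
  gbr_next <- NULL  # gradient flowing into branch k's input from deeper branches
  # split concat gradient per branch, then walk branches deepest-first so the
  # stride-2 entry gradient can be added to the previous branch's output
  gbranch_out <- vector("list", nb)
  for (k in seq_len(nb)) {
    dk <- cache$branch_dims[[k]]
    ck <- dk[3]
    gk <- gcat[, , at + seq_len(ck), , drop = FALSE]
    if (k > 1) gk <- cpp_bilinear_up_bwd(gk, as.integer(2^(k - 1)), dk[1], dk[2])
    gbranch_out[[k]] <- gk
    at <- at + ck
  }
  grads$branches <- vector("list", nb)
  for (k in rev(seq_len(nb))) {
    br <- prm$branches[[k]]
    g <- gbranch_out[[k]]
    gb <- list(down = NULL, blocks = vector("list", length(br$blocks)))
    for (j in rev(seq_along(br$blocks))) {
      r <- basic_bwd(g, br$blocks[[j]], cache$branches[[k]]$blocks[[j]])
      g <- r$gx
      gb$blocks[[j]] <- r$grads
    }
    if (k > 1) {
      r <- cb_bwd(g, br$down, cache$branches[[k]]$down, 2)
      gb$down <- r$grads
      gbranch_out[[k - 1]] <- gbranch_out[[k - 1]] + r$gx
    } else {
      gstem_accum <- g
    }
    grads$branches[[k]] <- gb
  }
  g <- gstem_accum
  grads$bott <- vector("list", length(prm$bott))
  for (i in rev(seq_along(prm$bott))) {
    r <- bottleneck_bwd(g, prm$bott[[i]], cache$bott[[i]])
    g <- r$gx
    grads$bott[[i]] <- r$grads
  }
  grads$stem <- vector("list", length(prm$stem))
  for (i in rev(seq_along(prm$stem))) {
    r <- cb_bwd(g, prm$stem[[i]], cache$stem[[i]], 1)
    g <- r$gx
    grads$stem[[i]] <- r$grads
  }
  grads[c("stem", "bott", "branches", "head")]
}

as_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  d <- dim(images[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

as_mask_batch <- function(masks, d) {
  if (is.list(masks)) {
    out <- array(0, c(d[1], d[2], 1, length(masks)))
    for (i in seq_along(masks)) out[, , 1, i] <- as.numeric(masks[[i]])
    out
  } else if (length(dim(masks)) == 2) {
    array(as.numeric(masks), c(d[1], d[2], 1, 1))
  } else masks
}

normalize_input <- function(x) {
  if (max(x) > 1.001) x / 255 else x
}

#' Forward inference on one or more tiles
#'
#' @param model a [SegModel-class].
#' @param images an H x W x 3 array, a list of them, or an H x W x 3 x N
#'   array; values in \[0, 1\] (a 0-255 range is rescaled).
#' @return a probability matrix for a single tile, else a list of matrices.
#' @export
predictTiles <- function(model, images) {
  single <- is.array(images) && length(dim(images)) == 3
  x <- normalize_input(as_batch(images))
  d <- dim(x)
  assert_that(d[1] == model@config@inputSize[1] &&
              d[2] == model@config@inputSize[2] && d[3] == 3,
              "input tiles must be %d x %d x 3",
              model@config@inputSize[1], model@config@inputSize[2])
  p <- model_fwd(model, x, training = FALSE)$p
  out <- lapply(seq_len(d[4]), function(i) p[, , 1, i])
  if (single) out[[1]] else out
}

#' Train a segmentation model
#'
#' Inputs are scaled to \[0, 1\], the loss is per-pixel mean squared error
#' against the binary mask, and optimization uses Adam. Training stops at
#' `maxSteps` or as soon as the loss reaches `convergenceLoss`. The loss
#' history is reproducible for a fixed `trainCfg@seed`.
#'
#' @param model a [SegModel-class]; updated in place.
#' @param images list of H x W x 3 arrays (or one 4-D array).
#' @param masks list of binary H x W matrices matching `images`.
#' @param trainCfg a [TrainConfig-class].
#' @return data.frame `history` with columns `step` and `loss`.
#' @export
trainSegModel <- function(model, images, masks, trainCfg = TrainConfig()) {
  validObject(trainCfg)
  x_all <- normalize_input(as_batch(images))
  d <- dim(x_all)
  assert_that(d[4] >= 1, "dataset must be non-empty")
  y_all <- as_mask_batch(masks, d)
  assert_that(all(y_all %in% c(0, 1)), "masks must be binary")
  assert_that(identical(dim(y_all)[c(1, 2, 4)], d[c(1, 2, 4)]),
              "masks must match images")
  env <- model@env
  lr <- trainCfg@initialLr
  history <- data.frame(step = integer(0), loss = numeric(0))
  with_seed(trainCfg@seed, {
    for (s in seq_len(trainCfg@maxSteps)) {
      if (d[4] <= trainCfg@batchSize) {
        x <- x_all; y <- y_all
      } else {
        pick <- sample.int(d[4], trainCfg@batchSize, replace = TRUE)
        x <- x_all[, , , pick, drop = FALSE]
        y <- y_all[, , , pick, drop = FALSE]
      }
      fw <- model_fwd(model, x, training = TRUE)
      loss <- mean((fw$p - y)^2)
      if (!is.finite(loss)) {
        stopf("training diverged (non-finite loss) at step %d", env$step + 1L)
      }
      gp <- 2 * (fw$p - y) / length(y)
      grads <- model_bwd(model, fw$cache, gp)
      if (is.null(env$adam)) {
        env$adam <- list(m = tree_map(function(p) p * 0, env$params),
                         v = tree_map(function(p) p * 0, env$params),
                         t = 0L)
      }
      env$adam$t <- env$adam$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      env$adam$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g,
                              env$adam$m, grads)
      env$adam$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2,
                              env$adam$v, grads)
      t <- env$adam$t
      mh <- tree_map(function(m) m / (1 - b1^t), env$adam$m)
      vh <- tree_map(function(v) v / (1 - b2^t), env$adam$v)
      upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
      env$params <- tree_map2(`-`, env$params, upd)
      env$step <- env$step + 1L
      history <- rbind(history, data.frame(step = env$step, loss = loss))
      if (loss <= trainCfg@convergenceLoss) break
    }
  })
  history
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single versioned file embedding the configuration,
#' all parameters and the batch-norm running statistics; a loaded model
#' reproduces the saved model's predictions exactly.
#'
#' @param model a [SegModel-class].
#' @param path checkpoint file path.
#' @return `saveModel`: `path` invisibly; `loadModel`: a
#'   [SegModel-class].
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  saveRDS(list(
    format = "nervePNI-segmodel", version = 1L,
    config = list(inputSize = cfg@inputSize, baseChannels = cfg@baseChannels,
                  nBranches = cfg@nBranches, stemABlocks = cfg@stemABlocks,
                  stemBottlenecks = cfg@stemBottlenecks,
                  branchBlocks = cfg@branchBlocks),
    params = model@env$params, stats = model@env$stats,
    step = model@env$step), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  assert_that(identical(ck$format, "nervePNI-segmodel"),
              "'%s' is not a model checkpoint", path)
  config <- do.call(SegModelConfig, ck$config)
  env <- new.env(parent = emptyenv())
  env$params <- ck$params
  env$stats <- ck$stats
  env$step <- ck$step
  env$adam <- NULL
  new("SegModel", config = config, env = env)
}

# ---- augmentation ---------------------------------------------------------

reflect_index <- function(n, total) {
  base <- c(seq_len(n), seq(n, 1))  # periodic symmetric extension
  base[((seq_len(total) - 1) %% (2 * n)) + 1]
}

resize_nearest <- function(m, oh, ow) {
  ri <- pmin(pmax(round((seq_len(oh) - 0.5) * nrow(m) / oh + 0.5), 1), nrow(m))
  ci <- pmin(pmax(round((seq_len(ow) - 0.5) * ncol(m) / ow + 0.5), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Augment an (image, mask) training pair
#'
#' A random crop window (between the target size and the full image) is
#' rescaled to `cropRescaleTo` -- bilinearly for the image, nearest
#' neighbour for the mask, which therefore stays binary -- followed by
#' optional horizontal/vertical flips (applied identically to both) and
#' image-only photometric jitter: additive brightness, saturation scaling
#' about the pixel luminance and contrast scaling about mid-gray, each
#' drawn from the configured ranges. Deterministic for a fixed seed.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param mask binary H x W matrix.
#' @param config an [AugmentationConfig-class].
#' @param seed RNG seed.
#' @return list with `image` and `mask`.
#' @export
augmentPair <- function(image, mask, config = AugmentationConfig(), seed = 1) {
  validObject(config)
  d <- dim(image)
  assert_that(identical(dim(mask), d[1:2]), "image and mask must share spatial dims")
  ch <- config@cropRescaleTo[1]; cw <- config@cropRescaleTo[2]
  assert_that(ch <= d[1] && cw <= d[2],
              "image of %d x %d is smaller than the %d x %d crop",
              d[1], d[2], ch, cw)
  with_seed(seed, {
    smax <- min(d[1] / ch, d[2] / cw)
    s <- stats::runif(1, 1, smax)
    wh <- min(d[1], round(ch * s)); ww <- min(d[2], round(cw * s))
    r0 <- if (d[1] > wh) sample.int(d[1] - wh + 1, 1) else 1L
    c0 <- if (d[2] > ww) sample.int(d[2] - ww + 1, 1) else 1L
    img <- image[r0:(r0 + wh - 1), c0:(c0 + ww - 1), , drop = FALSE]
    msk <- mask[r0:(r0 + wh - 1), c0:(c0 + ww - 1), drop = FALSE]
    if (wh != ch || ww != cw) {
      out <- array(0, c(ch, cw, 3))
      for (k in 1:3) out[, , k] <- cpp_resize_bilinear(img[, , k], ch, cw)
      img <- out
      msk <- resize_nearest(msk, ch, cw)
    }
    if (config@hflip && stats::runif(1) < 0.5) {
      img <- img[, rev(seq_len(cw)), , drop = FALSE]
      msk <- msk[, rev(seq_len(cw)), drop = FALSE]
    }
    if (config@vflip && stats::runif(1) < 0.5) {
      img <- img[rev(seq_len(ch)), , , drop = FALSE]
      msk <- msk[rev(seq_len(ch)), , drop = FALSE]
    }
    if (config@brightnessDelta > 0) {
      img <- img + stats::runif(1, -config@brightnessDelta, config@brightnessDelta)
    }
    sat <- stats::runif(1, config@saturationRange[1], config@saturationRange[2])
    if (sat != 1) {
      gray <- rgb_luminance(img)
      for (k in 1:3) img[, , k] <- gray + sat * (img[, , k] - gray)
    }
    con <- stats::runif(1, config@contrastRange[1], config@contrastRange[2])
    if (con != 1) img <- 0.5 + con * (img - 0.5)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = msk)
  })
}

# ---- tiled whole-image inference ------------------------------------------

#' Predict a probability map for an arbitrarily sized image
#'
#' The image is tiled by [makePatchGrid()] with stride `tile - overlap`;
#' per-tile predictions are blended by averaging in overlap zones. Images
#' smaller than a tile are reflect-padded, predicted, and cropped back.
#'
#' @param model a [SegModel-class], or (for testing) a function mapping an
#'   H x W x 3 tile array to a prediction matrix.
#' @param image H x W x 3 array in \[0, 1\].
#' @param tile tile side in pixels; defaults to the model's input size.
#' @param overlap overlap between neighbouring tiles (`< tile`).
#' @param mpp,channel metadata for the returned map.
#' @return A [ProbabilityMap-class] with the image's spatial dimensions.
#' @export
predictMap <- function(model, image, tile = NULL, overlap = 0,
                       mpp = 0.23, channel = c("nerve", "pni")) {
  channel <- match.arg(channel)
  if (is.null(tile)) {
    tile <- if (is.function(model)) 256 else model@config@inputSize[1]
  }
  assert_that(overlap >= 0 && overlap < tile, "overlap must be < tile")
  d <- dim(image)
  H <- d[1]; W <- d[2]
  padH <- max(0, tile - H); padW <- max(0, tile - W)
  if (padH > 0 || padW > 0) {
    ri <- reflect_index(H, H + padH)
    ci <- reflect_index(W, W + padW)
    image <- image[ri, ci, , drop = FALSE]
  }
  dH <- dim(image)[1]; dW <- dim(image)[2]
  grid <- makePatchGrid(dH, dW, tile, tile - overlap)
  acc <- matrix(0, dH, dW)
  wgt <- matrix(0, dH, dW)
  run_tile <- function(patch) {
    if (is.function(model)) model(patch) else predictTiles(model, patch)
  }
  for (i in seq_len(nrow(grid@origins))) {
    r0 <- grid@origins[i, 1] + 1; c0 <- grid@origins[i, 2] + 1
    rs <- r0:(r0 + tile - 1); cs <- c0:(c0 + tile - 1)
    p <- run_tile(image[rs, cs, , drop = FALSE])
    acc[rs, cs] <- acc[rs, cs] + p
    wgt[rs, cs] <- wgt[rs, cs] + 1
  }
  out <- (acc / wgt)[seq_len(H), seq_len(W), drop = FALSE]
  ProbabilityMap(pmin(pmax(out, 0), 1), mpp = mpp, channel = channel)
}
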