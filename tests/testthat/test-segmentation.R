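tiny_cfg <- function(...) {
  SegModelConfig(inputSize = c(32, 32), baseChannels = 4, nBranches = 2,
                 stemABlocks = 1, stemBottlenecks = 1, branchBlocks = 1, ...)
}

train_tile <- function(seed, size = 64) {
  sc <- generateScene(SceneSpec(
    heightPx = size, widthPx = size, nNerves = 1, pniFraction = 0,
    nerveAxisRangePx = c(10, 16), perineuriumThicknessPx = 2,
    nNoiseBlobs = 0, nSpecks = 0, backgroundTexture = 0.02, seed = seed))
  list(image = sc@image, mask = matrix(as.numeric(sc@nerveTruth), size))
}

test_that("the network maps RGB tiles to [0,1] maps of the same size", {
  m <- buildSegModel(tiny_cfg(), seed = 3)
  p <- predictTiles(m, array(0, c(32, 32, 3)))
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))

  set.seed(1)
  p2 <- predictTiles(m, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_true(all(p2 >= 0 & p2 <= 1))

  # parameter count is a deterministic function of the configuration
  expect_equal(nParameters(buildSegModel(tiny_cfg(), seed = 1)),
               nParameters(buildSegModel(tiny_cfg(), seed = 99)))

  # single-branch, single-A-block degenerate case is a plain conv stack
  m1 <- buildSegModel(SegModelConfig(inputSize = c(20, 20), baseChannels = 4,
                                     nBranches = 1, stemABlocks = 1,
                                     stemBottlenecks = 0, branchBlocks = 0))
  p1 <- predictTiles(m1, array(0.5, c(20, 20, 3)))
  expect_equal(dim(p1), c(20, 20))

  expect_error(predictTiles(m, array(0, c(16, 16, 3))), "32 x 32")
  expect_error(SegModelConfig(inputSize = c(30, 30), nBranches = 4),
               "divisible")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- SegModelConfig(inputSize = c(16, 16), baseChannels = 3, nBranches = 2,
                        stemABlocks = 1, stemBottlenecks = 1, branchBlocks = 1)
  m <- buildSegModel(cfg, seed = 2)
  set.seed(1)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  loss_at <- function() mean((nervePNI:::model_fwd(m, x, TRUE)$p - y)^2)
  fw <- nervePNI:::model_fwd(m, x, TRUE)
  gr <- nervePNI:::model_bwd(m, fw$cache, 2 * (fw$p - y) / length(y))
  eps <- 1e-5
  paths <- list(
    list(g = function(p) p$stem[[1]]$w, s = function(p, v) { p$stem[[1]]$w <- v; p }, i = 5),
    list(g = function(p) p$bott[[1]]$c2$w, s = function(p, v) { p$bott[[1]]$c2$w <- v; p }, i = 3),
    list(g = function(p) p$branches[[2]]$down$w, s = function(p, v) { p$branches[[2]]$down$w <- v; p }, i = 7),
    list(g = function(p) p$branches[[1]]$blocks[[1]]$c1$gamma, s = function(p, v) { p$branches[[1]]$blocks[[1]]$c1$gamma <- v; p }, i = 2),
    list(g = function(p) p$branches[[2]]$blocks[[1]]$c2$beta, s = function(p, v) { p$branches[[2]]$blocks[[1]]$c2$beta <- v; p }, i = 1),
    list(g = function(p) p$head$w, s = function(p, v) { p$head$w <- v; p }, i = 4))
  for (pt in paths) {
    p0 <- pt$g(m@env$params)
    analytic <- pt$g(gr)[pt$i]
    pp <- p0; pp[pt$i] <- pp[pt$i] + eps
    m@env$params <- pt$s(m@env$params, pp); l1 <- loss_at()
    pp[pt$i] <- pp[pt$i] - 2 * eps
    m@env$params <- pt$s(m@env$params, pp); l0 <- loss_at()
    pp[pt$i] <- pp[pt$i] + eps
    m@env$params <- pt$s(m@env$params, pp)
    expect_equal(analytic, (l1 - l0) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("augmentation is seeded, geometric on both, photometric on image", {
  tile <- train_tile(1)
  idcfg <- AugmentationConfig(brightnessDelta = 0, saturationRange = c(1, 1),
                              contrastRange = c(1, 1), hflip = FALSE,
                              vflip = FALSE, cropRescaleTo = c(64, 64))
  out <- augmentPair(tile$image, tile$mask, idcfg, seed = 5)
  expect_equal(out$image, tile$image)
  expect_equal(out$mask, tile$mask)

  cfg <- AugmentationConfig(cropRescaleTo = c(48, 48))
  a1 <- augmentPair(tile$image, tile$mask, cfg, seed = 11)
  a2 <- augmentPair(tile$image, tile$mask, cfg, seed = 11)
  expect_identical(a1, a2)
  expect_equal(dim(a1$image), c(48, 48, 3))
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_true(all(a1$image >= 0 & a1$image <= 1))

  # pure flips preserve the mask's foreground pixel count
  flipcfg <- AugmentationConfig(brightnessDelta = 0, saturationRange = c(1, 1),
                                contrastRange = c(1, 1), hflip = TRUE,
                                vflip = TRUE, cropRescaleTo = c(64, 64))
  for (s in 1:5) {
    out <- augmentPair(tile$image, tile$mask, flipcfg, seed = s)
    expect_equal(sum(out$mask), sum(tile$mask))
  }

  expect_error(augmentPair(tile$image, tile$mask,
                           AugmentationConfig(cropRescaleTo = c(128, 128))),
               "smaller")
})

test_that("training overfits a single tile and is reproducible", {
  tile <- train_tile(3)
  cfg <- SegModelConfig(inputSize = c(64, 64), baseChannels = 8, nBranches = 2,
                        stemABlocks = 1, stemBottlenecks = 1, branchBlocks = 1)
  tc <- TrainConfig(maxSteps = 150, convergenceLoss = 0.01, seed = 2,
                    initialLr = 0.003)
  m <- buildSegModel(cfg, seed = 4)
  h <- trainSegModel(m, list(tile$image), list(tile$mask), tc)
  expect_lte(tail(h$loss, 1), 0.01)
  expect_true(all(diff(h$step) == 1))

  m2 <- buildSegModel(cfg, seed = 4)
  h2 <- trainSegModel(m2, list(tile$image), list(tile$mask),
                      TrainConfig(maxSteps = 5, convergenceLoss = 1e-9, seed = 2))
  m3 <- buildSegModel(cfg, seed = 4)
  h3 <- trainSegModel(m3, list(tile$image), list(tile$mask),
                      TrainConfig(maxSteps = 5, convergenceLoss = 1e-9, seed = 2))
  expect_identical(h2, h3)

  expect_error(trainSegModel(m, list(), list(), tc), "subscript|non-empty")
  expect_error(trainSegModel(m, list(tile$image), list(tile$mask * 0.5), tc),
               "binary")
})

test_that("checkpoints round-trip to identical predictions", {
  tile <- train_tile(6)
  cfg <- SegModelConfig(inputSize = c(64, 64), baseChannels = 4, nBranches = 2,
                        stemABlocks = 1, stemBottlenecks = 1, branchBlocks = 1)
  m <- buildSegModel(cfg, seed = 1)
  trainSegModel(m, list(tile$image), list(tile$mask),
                TrainConfig(maxSteps = 3, convergenceLoss = 1e-9, seed = 1))
  f <- withr::local_tempfile(fileext = ".ckpt")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(predictTiles(m2, tile$image), predictTiles(m, tile$image))
  expect_equal(m2@env$step, m@env$step)
})

test_that("tiled inference blends per-tile predictions correctly", {
  # constant stub: blending equal values is the identity
  stub_const <- function(patch) matrix(0.42, dim(patch)[1], dim(patch)[2])
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  pm <- predictMap(stub_const, img, tile = 32, overlap = 8)
  expect_equal(unique(as.numeric(mapValues(pm))), 0.42)

  # overlap 0: tiles partition the image, output is per-tile paste
  stub_mean <- function(patch) matrix(mean(patch), dim(patch)[1], dim(patch)[2])
  pm0 <- predictMap(stub_mean, img, tile = 48, overlap = 0)
  want <- matrix(0, 96, 96)
  for (r0 in c(0, 48)) for (c0 in c(0, 48)) {
    want[r0 + 1:48, c0 + 1:48] <- mean(img[r0 + 1:48, c0 + 1:48, ])
  }
  expect_equal(mapValues(pm0), want)

  # overlapping tiles against the per-pixel blending oracle
  img2 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pm1 <- predictMap(stub_mean, img2, tile = 32, overlap = 16)
  expect_equal(mapValues(pm1), oracle_blend(img2, 32, 16, stub_mean),
               tolerance = 1e-6)

  # an image smaller than the tile is reflect-padded and cropped back
  img3 <- array(runif(40 * 40 * 3), c(40, 40, 3))
  pm3 <- predictMap(stub_mean, img3, tile = 64)
  expect_equal(dim(mapValues(pm3)), c(40, 40))
})
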