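test_that("pyramid smoothing matches its definition", {
  set.seed(2)
  m <- matrix(runif(64 * 48), 64, 48)
  expect_identical(pyramidSmooth(m, 0), m)

  cm <- matrix(0.37, 32, 32)
  expect_equal(pyramidSmooth(cm, 2), cm, tolerance = 1e-6)

  imp <- matrix(0, 64, 64); imp[32, 32] <- 1
  expect_equal(pyramidSmooth(imp, 1), oracle_pyramid(imp, 1), tolerance = 1e-12)
  expect_equal(pyramidSmooth(m, 2), oracle_pyramid(m, 2), tolerance = 1e-12)
  # odd sizes exercise the ceil(n/2) decimation
  mo <- matrix(runif(45 * 33), 45, 33)
  expect_equal(pyramidSmooth(mo, 2), oracle_pyramid(mo, 2), tolerance = 1e-12)

  expect_error(pyramidSmooth(matrix(0, 3, 3), 2), "too small")
  pm <- ProbabilityMap(m, channel = "nerve")
  expect_s4_class(pyramidSmooth(pm, 1), "ProbabilityMap")
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  # bimodal two-delta histogram: smallest maximizing edge just above 0.1
  v <- c(rep(0.1, 50), rep(0.9, 50))
  t <- otsuThreshold(v)
  expect_gt(as.numeric(t), 0.1)
  expect_lte(as.numeric(t), 0.9)
  expect_equal(as.numeric(t), 26 / 256)
  expect_false(attr(t, "degenerate"))

  t2 <- otsuThreshold(matrix(0.4, 5, 5))
  expect_true(attr(t2, "degenerate"))

  set.seed(11)
  for (i in 1:200) {
    n <- sample(20:1000, 1)
    v <- switch(sample(3, 1),
                runif(n),
                round(rbeta(n, 0.5, 0.5), 2),
                c(runif(n, 0, 0.3), runif(n, 0.6, 1)))
    expect_equal(as.numeric(otsuThreshold(v)), oracle_otsu(v))
  }
})

test_that("PNI binarization combines the constant and Otsu thresholds by max", {
  expect_false(any(binarizePni(matrix(0, 8, 8), 0.5)))

  v <- matrix(c(rep(0.2, 60), rep(0.95, 40)), 10, 10)
  mask <- binarizePni(v, 0.5)
  eff <- max(0.5, oracle_otsu(v))
  expect_identical(unname(which(mask)), which(v == 0.95))
  expect_equal(attr(mask, "effective_threshold"), eff)

  # raising the constant threshold never adds foreground
  set.seed(3)
  m <- matrix(runif(900), 30)
  prev <- binarizePni(m, 0.3)
  for (ct in c(0.5, 0.7, 0.9)) {
    cur <- binarizePni(m, ct)
    expect_true(all(which(cur) %in% which(prev)))
    prev <- cur
  }
})

test_that("nerve-mask extraction applies smoothing then opening/closing", {
  cfg0 <- DecisionConfig(pyramidLevels = 0, smoothingRadiusPx = 0)
  set.seed(8)
  m <- matrix(runif(400), 20)
  expect_identical(extractNerveMask(m, cfg0), m > 0.5)

  # a 40x40 solid square against the set-morphology oracle (radius 3)
  sq <- matrix(0, 60, 60); sq[11:50, 11:50] <- 1
  cfg <- DecisionConfig(pyramidLevels = 0, smoothingRadiusPx = 3)
  got <- extractNerveMask(sq, cfg)
  se <- EBImage::makeBrush(7, "disc") > 0
  want <- oracle_dilate(oracle_erode(sq > 0.5, se), se)       # opening
  want <- oracle_erode(oracle_dilate(want, se), se)           # closing
  expect_identical(got, want)
  # the square survives essentially unchanged: the disk rounds at most a
  # few pixels off each corner and adds none
  expect_true(all(!got[!(sq > 0.5)]))
  expect_lte(sum(xor(got, sq > 0.5)), 16)

  lone <- matrix(0, 20, 20); lone[10, 10] <- 1
  cfg1 <- DecisionConfig(pyramidLevels = 0, smoothingRadiusPx = 1)
  expect_false(any(extractNerveMask(lone, cfg1)))
})

test_that("component labeling matches a flood-fill oracle", {
  empty <- extractComponents(matrix(FALSE, 5, 5))
  expect_equal(nComponents(empty), 0)

  diag2 <- matrix(FALSE, 4, 4); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(nComponents(extractComponents(diag2, 8)), 1)
  expect_equal(nComponents(extractComponents(diag2, 4)), 2)

  block <- matrix(FALSE, 10, 10); block[4:6, 5:7] <- TRUE
  cs <- extractComponents(block)
  tab <- componentTable(cs)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$area_px2, 9)
  expect_equal(unlist(tab[1, c("r0", "c0", "r1", "c1")], use.names = FALSE),
               c(3, 4, 6, 7))

  set.seed(21)
  for (i in 1:200) {
    mask <- matrix(runif(64 * 64) < runif(1, 0.05, 0.6), 64, 64)
    conn <- sample(c(4, 8), 1)
    cs <- extractComponents(mask, conn)
    expect_identical(labelMatrix(cs), oracle_label(mask, conn))
    expect_equal(sum(componentTable(cs)$area_px2), sum(mask))
  }
})

test_that("size filter partitions components by the <= rule", {
  # components as horizontal runs: areas 100, 21632, 21633
  areas <- c(100, 21632, 21633)
  mask <- matrix(FALSE, 5, max(areas))
  for (i in seq_along(areas)) mask[2 * i - 1, seq_len(areas[i])] <- TRUE
  cs <- extractComponents(mask)
  f <- sizeFilter(cs, 21632)
  expect_equal(componentTable(f$retained)$area_px2, 21633)
  expect_setequal(componentTable(f$removed)$area_px2, c(100, 21632))

  f0 <- sizeFilter(cs, 0)
  expect_equal(nComponents(f0$removed), 0)
  expect_equal(nComponents(f0$retained), 3)

  # partition property
  expect_equal(sort(c(componentTable(f$retained)$label,
                      componentTable(f$removed)$label)),
               componentTable(cs)$label)

  # 100 components with areas 1..100 and the calibrated cutoff remove 90
  mask <- matrix(FALSE, 199, 100)
  for (a in 1:100) mask[2 * a - 1, seq_len(a)] <- TRUE
  cs <- extractComponents(mask)
  cut <- calibrateCutoff(componentTable(cs)$area_px2, 0.10)@cutoffPx2
  expect_equal(cut, 90)
  expect_equal(nComponents(sizeFilter(cs, cut)$removed), 90)
})

test_that("PNI assignment uses Chebyshev adjacency", {
  H <- 30
  nerve <- matrix(FALSE, H, H); nerve[5:10, 5:10] <- TRUE
  pni <- matrix(FALSE, H, H)

  # overlap with adjacency 0
  pniO <- pni; pniO[10, 10] <- TRUE
  res <- assignPni(extractComponents(nerve), extractComponents(pniO), 0)
  expect_equal(res$predicted_class, "PNI")

  # nearest pair at Chebyshev distance 6
  pni6 <- pni; pni6[16, 16] <- TRUE
  expect_equal(oracle_min_chebyshev(nerve, pni6), 6)
  res5 <- assignPni(extractComponents(nerve), extractComponents(pni6), 5)
  expect_equal(res5$predicted_class, "normal")
  res6 <- assignPni(extractComponents(nerve), extractComponents(pni6), 6)
  expect_equal(res6$predicted_class, "PNI")
  expect_equal(res6$supporting[[1]], 1L)

  # no PNI components at all
  res0 <- assignPni(extractComponents(nerve), extractComponents(pni), 5)
  expect_equal(res0$predicted_class, "normal")
  expect_equal(res0$n_supporting, 0L)

  # random scatter against the brute-force pixel-distance oracle
  set.seed(17)
  for (i in 1:30) {
    nm <- matrix(runif(32 * 32) < 0.03, 32, 32)
    pm <- matrix(runif(32 * 32) < 0.03, 32, 32)
    a <- sample(0:6, 1)
    nc <- extractComponents(nm); pc <- extractComponents(pm)
    res <- assignPni(nc, pc, a)
    for (j in seq_len(nrow(res))) {
      d <- oracle_min_chebyshev(labelMatrix(nc) == res$id[j], pm)
      expect_equal(res$predicted_class[j] == "PNI", d <= a)
    }
  }
})

test_that("the full rule flow recovers planted truth on synthetic scenes", {
  empty <- runDecisionFlow(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(nrow(nerveTable(empty)), 0)

  cfg <- DecisionConfig(sizeCutoffPx2 = 8000, adjacencyPx = 5)
  for (seed in c(2, 9)) {
    sc <- generateScene(small_scene_spec(seed, nNerves = 4))
    maps <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.05, seed = seed)
    res <- runDecisionFlow(maps$nerve, maps$pni, cfg)
    expect_equal(nrow(nerveTable(res)), 4)
    cm <- matchStructures(res, sc)
    cc <- confusionCounts(cm)
    expect_equal(cc[["fp"]] + cc[["fn"]], 0)

    # identical inputs and config give identical decisions
    res2 <- runDecisionFlow(maps$nerve, maps$pni, cfg)
    expect_identical(nerveTable(res), nerveTable(res2))

    # an infinite cutoff removes every PNI component
    resInf <- runDecisionFlow(maps$nerve, maps$pni,
                              DecisionConfig(sizeCutoffPx2 = Inf))
    expect_true(all(nerveTable(resInf)$predicted_class == "normal"))
  }
})

test_that("the PNI-positive set shrinks as the cutoff grows", {
  sc <- generateScene(small_scene_spec(4, nNerves = 4))
  maps <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.05, seed = 4)
  prev <- NULL
  for (cut in c(0, 2000, 8000, 20000, 1e9)) {
    res <- runDecisionFlow(maps$nerve, maps$pni,
                           DecisionConfig(sizeCutoffPx2 = cut))
    pos <- nerveTable(res)$id[nerveTable(res)$predicted_class == "PNI"]
    if (!is.null(prev)) expect_true(all(pos %in% prev))
    prev <- pos
  }
})
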