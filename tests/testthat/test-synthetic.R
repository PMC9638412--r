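test_that("scene generation is seeded, class-balanced and validated", {
  sp <- small_scene_spec(1, nNerves = 3, pniFraction = 0)
  sc <- generateScene(sp)
  expect_equal(nrow(sc@nerveRecords), 3)
  expect_true(all(sc@nerveRecords$class == "normal"))
  expect_false(any(sc@pniTruth))

  # bit-identical regeneration from the same spec
  sp7 <- small_scene_spec(7)
  expect_identical(generateScene(sp7), generateScene(sp7))

  # class balance across fractions and counts
  for (f in c(0.25, 0.5, 1)) {
    for (n in c(3, 4)) {
      sc <- generateScene(small_scene_spec(n + 10 * f, nNerves = n, pniFraction = f))
      expect_equal(sum(sc@nerveRecords$class == "PNI"), round(f * n))
    }
  }

  expect_error(SceneSpec(nNerves = -1), "count")
  expect_error(SceneSpec(pniFraction = 1.5), "pniFraction")
  expect_error(SceneSpec(nerveAxisRangePx = c(50, 40)), "min <= max")
  # canvas too small for the requested nerve envelopes
  expect_error(generateScene(SceneSpec(heightPx = 200, widthPx = 200)),
               "canvas")
})

test_that("noise blob areas reproduce their target distribution", {
  sp <- SceneSpec(heightPx = 1536, widthPx = 1536, nNerves = 0, pniFraction = 0,
                  nNoiseBlobs = 50,
                  noiseSizeDist = list(name = "lognormal", meanlog = 9, sdlog = 0.8),
                  nSpecks = 0, seed = 3)
  sc <- generateScene(sp)
  expect_equal(length(sc@noiseAreas), 50)
  comps <- extractComponents(sc@noiseTruth)
  expect_equal(nComponents(comps), 50)
  # rendered areas track the drawn areas; the empirical 90th percentile
  # matches the sort-based nearest-rank oracle on the same draws
  obs <- sort(componentTable(comps)$area_px2)
  drawn <- sort(sc@noiseAreas)
  expect_lt(max(abs(obs - drawn) / drawn), 0.06)
  q_obs <- obs[ceiling(0.9 * 50)]
  expect_equal(q_obs, oracle_quantile(drawn, 0.9), tolerance = 0.05)
})

test_that("scene geometry honours its separation invariants", {
  for (seed in c(5, 23)) {
    sc <- generateScene(small_scene_spec(seed, nNerves = 4))
    # noise never touches a (dilated) nerve
    se <- EBImage::makeBrush(3, "box")
    dil <- EBImage::imageData(EBImage::dilate(
      matrix(as.numeric(sc@nerveTruth), nrow(sc@nerveTruth)), se)) > 0.5
    expect_false(any(sc@noiseTruth & dil))
    # every planted nest supports exactly one nerve within the default
    # adjacency, and nest count equals the number of PNI nerves
    nests <- extractComponents(sc@pniTruth)
    expect_equal(nComponents(nests), sum(sc@nerveRecords$class == "PNI"))
    for (i in seq_len(nComponents(nests))) {
      hit <- unique(sc@nerveLabels[EBImage::imageData(EBImage::dilate(
        matrix(as.numeric(labelMatrix(nests) == i), nrow(sc@pniTruth)),
        EBImage::makeBrush(11, "box"))) > 0.5 & sc@nerveLabels > 0])
      expect_equal(length(hit), 1)
    }
    # truth masks and image share dimensions (class validity)
    expect_identical(dim(sc@image)[1:2], dim(sc@pniTruth))
  }
})

test_that("simulated probability maps honour the blur/noise contract", {
  sc <- generateScene(small_scene_spec(2))
  m0 <- sceneToProbabilityMaps(sc, blurSigma = 0, noiseSd = 0, seed = 1)
  expect_identical(mapValues(m0$nerve),
                   matrix(as.numeric(sc@nerveTruth), nrow(sc@nerveTruth)))
  expect_identical(mapValues(m0$pni),
                   matrix(as.numeric(sc@pniTruth | sc@noiseTruth),
                          nrow(sc@pniTruth)))

  m1 <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.1, seed = 9)
  m2 <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.1, seed = 9)
  expect_identical(m1, m2)
  v <- mapValues(m1$pni)
  expect_true(all(v >= 0 & v <= 1))

  # with small blur, every nest and noise object survives thresholding
  mb <- sceneToProbabilityMaps(sc, blurSigma = 0.8, noiseSd = 0, seed = 1)
  comps <- extractComponents(mapValues(mb$pni) > 0.5)
  want <- nComponents(extractComponents(sc@pniTruth | sc@noiseTruth))
  expect_gte(nComponents(comps), want)

  expect_error(sceneToProbabilityMaps(sc, blurSigma = -1), "blurSigma")
  expect_error(sceneToProbabilityMaps(sc, noiseSd = 0.7), "noiseSd")
})

test_that("scenes serialize to image/mask/record files and YAML specs load", {
  sc <- generateScene(small_scene_spec(6, nNerves = 2))
  dir <- withr::local_tempdir()
  writeScene(sc, dir, slideId = "s6")
  expect_true(all(file.exists(file.path(dir,
    c("image.tiff", "nerve_truth.png", "pni_truth.png", "noise_truth.png",
      "records.json")))))
  expect_identical(readMask(file.path(dir, "nerve_truth.png")), sc@nerveTruth)
  rec <- readAnnotations(file.path(dir, "records.json"))
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$label == "PNI"), sum(sc@nerveRecords$class == "PNI"))

  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(heightPx = 576, widthPx = 576, nNerves = 2,
                        pniFraction = 0.5,
                        noiseSizeDist = list(name = "lognormal",
                                             meanlog = 8, sdlog = 0.6),
                        seed = 4), f)
  sp <- readSceneSpec(f)
  expect_s4_class(sp, "SceneSpec")
  expect_equal(sp@nNerves, 2)
  yaml::write_yaml(list(bogus = 1), f)
  expect_error(readSceneSpec(f), "unknown")
})
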