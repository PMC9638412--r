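test_that("metrics reproduce the clinical confusion-table arithmetic", {
  # nerve-identification test set (rounded display in the source table)
  r3 <- metrics(ConfusionMatrix(106, 3, 8, 15))
  expect_equal(r3@sensitivity, 92.98, tolerance = 0.01 / 92.98)
  expect_equal(r3@specificity, 83.33, tolerance = 0.01 / 83.33)
  expect_equal(r3@accuracy, 91.67, tolerance = 0.01 / 91.67)

  # PNI ROI test set
  r4 <- metrics(ConfusionMatrix(116, 14, 7, 54))
  expect_equal(r4@sensitivity, 94.31, tolerance = 0.01 / 94.31)
  expect_equal(r4@specificity, 79.41, tolerance = 0.01 / 79.41)
  expect_equal(r4@accuracy, 89.01, tolerance = 0.01 / 89.01)

  # WSI reader validation (truncated display in the source table)
  expect_equal(unname(displayedMetrics(metrics(ConfusionMatrix(12, 7, 4, 384)))),
               c(75.00, 98.20, 97.29))
  expect_equal(unname(displayedMetrics(metrics(ConfusionMatrix(11, 8, 1, 385)))),
               c(91.66, 97.96, 97.77))

  expect_equal(unname(displayedMetrics(metrics(ConfusionMatrix(1, 0, 0, 1)))),
               c(100, 100, 100))

  # zero denominators are undefined, not zero
  r0 <- metrics(ConfusionMatrix(0, 0, 0, 5))
  expect_true(is.na(r0@sensitivity))
  expect_equal(r0@specificity, 100)
  expect_error(ConfusionMatrix(-1, 0, 0, 0), "non-negative")
})

test_that("mean accuracy averages truncated displayed accuracies", {
  r1 <- metrics(ConfusionMatrix(12, 7, 4, 384))
  r2 <- metrics(ConfusionMatrix(11, 8, 1, 385))
  expect_equal(meanAccuracy(list(r1, r2)), 97.53)
  expect_equal(meanAccuracy(list(r1)), 97.29)
  expect_equal(meanAccuracy(list(metrics(ConfusionMatrix(0, 5, 5, 0)),
                                 metrics(ConfusionMatrix(5, 0, 0, 5)))), 50)
  expect_error(meanAccuracy(list()), "at least one")
  expect_error(metrics(ConfusionMatrix(0, 0, 0, 0)), "at least one")
})

test_that("diagnostic-time reduction uses round-half-up percentages", {
  df <- data.frame(slide_id = c("s810", "s201"),
                   t_without_sec = c(54, 37), t_with_sec = c(19, 126))
  tr <- timeReduction(df)
  expect_equal(tr$perSlide$change_pct, c(64.8, -240.5))

  expect_equal(timeReduction(data.frame(slide_id = "t", t_without_sec = 708,
                                        t_with_sec = 602))$totalChangePct, 15.0)
  expect_equal(timeReduction(data.frame(slide_id = "t", t_without_sec = 718,
                                        t_with_sec = 548))$totalChangePct, 23.7)
  expect_equal(timeReduction(data.frame(slide_id = "e", t_without_sec = 50,
                                        t_with_sec = 50))$perSlide$change_pct, 0)
  expect_error(timeReduction(data.frame(slide_id = "b", t_without_sec = 0,
                                        t_with_sec = 10)), "positive")
})

# Build a DecisionResult directly from a truth labeling, optionally flipping
# predicted classes, so matching can be tested without running the flow.
fake_decision <- function(truthLabels, classes, flip = FALSE) {
  comps <- extractComponents(truthLabels > 0)
  tab <- componentTable(comps)
  # map each predicted component to the truth nerve it covers
  pred_class <- vapply(tab$label, function(l) {
    t <- unique(truthLabels[labelMatrix(comps) == l])
    classes[t[t > 0][1]]
  }, character(1))
  if (flip) pred_class <- ifelse(pred_class == "PNI", "normal", "PNI")
  nerves <- data.frame(id = tab$label, area_px2 = tab$area_px2,
                       r0 = tab$r0, c0 = tab$c0, r1 = tab$r1, c1 = tab$c1,
                       predicted_class = pred_class,
                       n_supporting = as.integer(pred_class == "PNI"))
  nerves$supporting <- replicate(nrow(nerves), integer(0), simplify = FALSE)
  new("DecisionResult", nerves = nerves, nerveMask = truthLabels > 0,
      pniMask = matrix(FALSE, nrow(truthLabels), ncol(truthLabels)),
      nerveComponents = comps, pniComponents = comps,
      retained = tab[0, ], removed = tab[0, ], config = DecisionConfig())
}

random_truth <- function(seed, n = 4, size = 64) {
  set.seed(seed)
  cells <- sample(16, n)  # distinct 16x16 grid cells keep squares apart
  lab <- matrix(0L, size, size)
  for (i in seq_len(n)) {
    cr <- (cells[i] - 1) %% 4; cc <- (cells[i] - 1) %/% 4
    r <- cr * 16 + sample(2:6, 1); c <- cc * 16 + sample(2:6, 1)
    lab[r:(r + 6), c:(c + 6)] <- i
  }
  classes <- sample(c("PNI", "normal"), n, replace = TRUE)
  list(labels = lab, classes = classes)
}

test_that("structure matching counts matched and unmatched nerves correctly", {
  tr <- random_truth(2)
  dec <- fake_decision(tr$labels, tr$classes)
  cm <- confusionCounts(matchStructures(dec, tr))
  expect_equal(cm[["fp"]] + cm[["fn"]], 0)
  expect_equal(cm[["tp"]], sum(tr$classes == "PNI"))

  # flipping every prediction mirrors the off-diagonals
  decF <- fake_decision(tr$labels, tr$classes, flip = TRUE)
  cmF <- confusionCounts(matchStructures(decF, tr))
  expect_equal(cmF[["fp"]], cm[["tn"]])
  expect_equal(cmF[["fn"]], cm[["tp"]])
  expect_equal(cmF[["tp"]] + cmF[["fp"]] + cmF[["fn"]] + cmF[["tn"]],
               sum(cm))
})

test_that("matching conserves counts over random cases", {
  for (seed in 1:25) {
    n <- sample(2:6, 1)
    tr <- random_truth(seed, n = n)
    dec <- fake_decision(tr$labels, tr$classes, flip = seed %% 2 == 0)
    cm <- confusionCounts(matchStructures(dec, tr))
    # every truth nerve lands in exactly one cell; nothing else is counted
    # here because every prediction overlaps a truth nerve
    expect_equal(sum(cm), n)
    expect_equal(cm[["tp"]] + cm[["fn"]], sum(tr$classes == "PNI"))
    expect_gte(cm[["fp"]] + cm[["tn"]], sum(tr$classes == "normal"))
  }
})

test_that("cutoff sweeps are monotone and deterministic", {
  inputs <- lapply(c(3, 14, 28), function(seed) {
    sc <- generateScene(small_scene_spec(seed, nNerves = 4))
    maps <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.05, seed = seed)
    list(nerve = maps$nerve, pni = maps$pni, truth = sc)
  })
  cuts <- c(0, 1000, 4000, 9000, 20000, 1e12)
  sw <- cutoffSweep(inputs, cuts, DecisionConfig())
  tab <- sweepTable(sw)
  expect_equal(tab$cutoff_px2, cuts)
  expect_true(all(diff(tab$sensitivity) <= 1e-9))
  expect_true(all(diff(tab$specificity) >= -1e-9))
  # the limit cutoff removes everything: no PNI calls survive
  expect_equal(tab$tp[nrow(tab)], 0)
  expect_equal(tab$sensitivity[nrow(tab)], 0)

  sw2 <- cutoffSweep(inputs, cuts, DecisionConfig())
  expect_identical(sweepTable(sw2), tab)

  expect_error(cutoffSweep(inputs, c(5, 5)), "increasing")
  expect_error(cutoffSweep(list(), c(0, 1)), "at least one")
})
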