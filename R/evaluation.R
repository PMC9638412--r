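# Scoring per-nerve decisions against ground truth: confusion matrices,
# the percentage conventions of the clinical tables, cutoff sweeps and
# diagnostic-time analysis.

#' Compute sensitivity, specificity and accuracy
#'
#' `sensitivity = 100 * tp / (tp + fn)`, `specificity = 100 * tn /
#' (tn + fp)`, `accuracy = 100 * (tp + tn) / total`. Percentages are kept
#' at full precision in the report; [displayedMetrics()] truncates to two
#' decimals for display. A zero denominator yields `NA` (undefined), never
#' zero.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A [MetricsReport-class].
#' @examples
#' displayedMetrics(metrics(ConfusionMatrix(106, 3, 8, 15)))
#' @export
metrics <- function(cm) {
  validObject(cm)
  total <- cm@tp + cm@fp + cm@fn + cm@tn
  assert_that(total >= 1, "confusion matrix must contain at least one count")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  new("MetricsReport",
      sensitivity = rate(cm@tp, cm@tp + cm@fn),
      specificity = rate(cm@tn, cm@tn + cm@fp),
      accuracy = rate(cm@tp + cm@tn, total))
}

#' Mean accuracy over several reports
#'
#' The arithmetic mean of the truncated displayed accuracies, itself
#' truncated to 2 decimals (the convention of the reader-validation
#' summaries).
#'
#' @param reports list of [MetricsReport-class] objects.
#' @return mean accuracy percentage.
#' @examples
#' r1 <- metrics(ConfusionMatrix(12, 7, 4, 384))
#' r2 <- metrics(ConfusionMatrix(11, 8, 1, 385))
#' meanAccuracy(list(r1, r2))  # 97.53
#' @export
meanAccuracy <- function(reports) {
  assert_that(length(reports) > 0, "need at least one report")
  acc <- vapply(reports, function(r) trunc2(r@accuracy), numeric(1))
  assert_that(!anyNA(acc), "accuracy is undefined for some report")
  trunc2(mean(acc))
}

#' Diagnostic-time reduction
#'
#' Per-slide percentage change `100 * (t_without - t_with) / t_without`
#' and the total change computed from summed times, both rounded half-up
#' to one decimal (negative = the assisted reading took longer).
#'
#' @param records data.frame with columns `slide_id`, `t_without_sec`,
#'   `t_with_sec` (positive seconds), e.g. from [readTimingTable()].
#' @return list with `perSlide` (the records plus `change_pct`) and
#'   `totalChangePct`.
#' @export
timeReduction <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data.frame")
  assert_that(all(c("t_without_sec", "t_with_sec") %in% names(records)),
              "records need t_without_sec and t_with_sec columns")
  w <- records$t_without_sec; x <- records$t_with_sec
  assert_that(all(is.finite(w)) && all(is.finite(x)) && all(w > 0) && all(x > 0),
              "times must be positive")
  records$change_pct <- round_half_up(100 * (w - x) / w, 1)
  list(perSlide = records,
       totalChangePct = round_half_up(100 * (sum(w) - sum(x)) / sum(w), 1))
}

#' Match predicted nerve structures to ground truth
#'
#' Predicted and truth nerves are matched greedily by descending pixel
#' overlap; a pair is accepted when the overlap covers at least
#' `minOverlapFrac` of the truth region. A matched pair contributes TP when
#' both are PNI, TN when both normal, FP for predicted-PNI/truth-normal and
#' FN for predicted-normal/truth-PNI. Unmatched truth nerves count FN if
#' PNI, TN if normal (a normal nerve that was never flagged); unmatched
#' predictions count FP if labeled PNI and are otherwise not counted.
#'
#' @param decision a [DecisionResult-class].
#' @param truth a [SyntheticScene-class], or a list with `labels` (integer
#'   matrix of truth nerve ids) and `classes` (character vector,
#'   `"PNI"`/`"normal"`, indexed by id).
#' @param minOverlapFrac minimum overlap as a fraction of the truth region.
#' @return A [ConfusionMatrix-class].
#' @export
matchStructures <- function(decision, truth, minOverlapFrac = 0.1) {
  assert_that(minOverlapFrac > 0 && minOverlapFrac <= 1,
              "minOverlapFrac must lie in (0, 1]")
  if (is(truth, "SyntheticScene")) {
    truth <- list(labels = truth@nerveLabels,
                  classes = truth@nerveRecords$class[order(truth@nerveRecords$id)])
  }
  predLabels <- decision@nerveComponents@labels
  assert_that(identical(dim(predLabels), dim(truth$labels)),
              "prediction and truth masks must share dimensions")
  predTab <- decision@nerves
  predClass <- stats::setNames(predTab$predicted_class, predTab$id)
  truthAreas <- tabulate(truth$labels[truth$labels > 0],
                         nbins = length(truth$classes))

  sel <- truth$labels > 0 & predLabels > 0
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  matchedT <- integer(0); matchedP <- integer(0)
  if (any(sel)) {
    ov <- as.data.frame(table(t = truth$labels[sel], p = predLabels[sel]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$t <- as.integer(ov$t); ov$p <- as.integer(ov$p)
    ov <- ov[order(-ov$Freq), ]
    for (i in seq_len(nrow(ov))) {
      t <- ov$t[i]; p <- ov$p[i]
      if (t %in% matchedT || p %in% matchedP) next
      if (ov$Freq[i] < minOverlapFrac * truthAreas[t]) next
      matchedT <- c(matchedT, t); matchedP <- c(matchedP, p)
      tc <- truth$classes[t]; pc <- predClass[[as.character(p)]]
      key <- if (tc == "PNI" && pc == "PNI") "tp"
             else if (tc == "normal" && pc == "normal") "tn"
             else if (pc == "PNI") "fp" else "fn"
      counts[key] <- counts[key] + 1
    }
  }
  for (t in setdiff(seq_along(truth$classes), matchedT)) {
    key <- if (truth$classes[t] == "PNI") "fn" else "tn"
    counts[key] <- counts[key] + 1
  }
  unmatchedP <- setdiff(predTab$id, matchedP)
  counts["fp"] <- counts["fp"] +
    sum(predClass[as.character(unmatchedP)] == "PNI")
  ConfusionMatrix(counts[["tp"]], counts[["fp"]], counts[["fn"]], counts[["tn"]])
}

#' Sweep the size-filter cutoff
#'
#' Re-runs the decision rule flow over a set of map pairs for each cutoff,
#' with everything else fixed, pooling nerve-level confusion counts. Only
#' the size filter and the per-nerve inspection depend on the cutoff, so
#' the smoothing/thresholding/labeling stages are computed once per input.
#' As the cutoff grows the PNI-positive set can only shrink: sensitivity is
#' non-increasing and specificity non-decreasing in the cutoff.
#'
#' @param inputs list; each element a list with `nerve` and `pni`
#'   probability maps and `truth` (see [matchStructures()]), e.g. built
#'   from [generateScene()] + [sceneToProbabilityMaps()].
#' @param cutoffs numeric vector of at least 2 strictly increasing cutoffs.
#' @param cfg a [DecisionConfig-class] (its `sizeCutoffPx2` is ignored).
#' @param minOverlapFrac passed to [matchStructures()].
#' @return A [SweepResult-class].
#' @export
cutoffSweep <- function(inputs, cutoffs, cfg = DecisionConfig(),
                        minOverlapFrac = 0.1) {
  assert_that(length(inputs) >= 1, "need at least one input")
  assert_that(length(cutoffs) >= 2 && !is.unsorted(cutoffs, strictly = TRUE),
              "cutoffs must be >= 2 strictly increasing values")
  base <- lapply(inputs, function(inp) {
    nerveMask <- extractNerveMask(as_map_matrix(inp$nerve), cfg)
    list(nerveComponents = extractComponents(nerveMask, cfg@connectivity),
         pniComponents = extractComponents(
           binarizePni(as_map_matrix(inp$pni), cfg@pniConstThreshold),
           cfg@connectivity),
         nerveMask = nerveMask,
         truth = inp$truth)
  })
  rows <- lapply(cutoffs, function(cut) {
    tot <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    cfg_c <- cfg
    cfg_c@sizeCutoffPx2 <- cut
    for (b in base) {
      filt <- sizeFilter(b$pniComponents, cut)
      nerves <- assignPni(b$nerveComponents, filt$retained, cfg@adjacencyPx)
      dec <- new("DecisionResult", nerves = nerves, nerveMask = b$nerveMask,
                 pniMask = b$pniComponents@labels > 0,
                 nerveComponents = b$nerveComponents,
                 pniComponents = b$pniComponents,
                 retained = filt$retained@table, removed = filt$removed@table,
                 config = cfg_c)
      tot <- tot + confusionCounts(matchStructures(dec, b$truth, minOverlapFrac))
    }
    rep <- metrics(ConfusionMatrix(tot[["tp"]], tot[["fp"]], tot[["fn"]],
                                   tot[["tn"]]))
    data.frame(cutoff_px2 = cut, tp = tot[["tp"]], fp = tot[["fp"]],
               fn = tot[["fn"]], tn = tot[["tn"]],
               sensitivity = rep@sensitivity, specificity = rep@specificity,
               accuracy = rep@accuracy)
  })
  new("SweepResult", table = do.call(rbind, rows))
}
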