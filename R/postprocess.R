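# The decision rule flow: Gaussian-pyramid smoothing, combined
# constant/Otsu thresholding, connected components, size filtering and the
# per-nerve invasion decision.
#
# Coordinate convention (used package-wide): 0-based, row-major, origin at
# the top-left pixel; bounding boxes are half-open (r0, c0, r1, c1).

as_map_matrix <- function(map) {
  if (is(map, "ProbabilityMap")) map@values else map
}

# One binomial reduce step: separable [1,4,6,4,1]/16 with symmetric reflect
# padding, then x2 decimation keeping indices 1, 3, 5, ... (output size
# ceiling(n/2)).
reduce_once <- function(m) {
  w <- c(1, 4, 6, 4, 1) / 16
  n <- nrow(m)
  p <- m[c(2, 1, seq_len(n), n, n - 1), , drop = FALSE]
  m <- w[1] * p[seq_len(n), , drop = FALSE] +
       w[2] * p[seq_len(n) + 1, , drop = FALSE] +
       w[3] * p[seq_len(n) + 2, , drop = FALSE] +
       w[4] * p[seq_len(n) + 3, , drop = FALSE] +
       w[5] * p[seq_len(n) + 4, , drop = FALSE]
  k <- ncol(m)
  p <- m[, c(2, 1, seq_len(k), k, k - 1), drop = FALSE]
  m <- w[1] * p[, seq_len(k), drop = FALSE] +
       w[2] * p[, seq_len(k) + 1, drop = FALSE] +
       w[3] * p[, seq_len(k) + 2, drop = FALSE] +
       w[4] * p[, seq_len(k) + 3, drop = FALSE] +
       w[5] * p[, seq_len(k) + 4, drop = FALSE]
  m[seq(1, n, by = 2), seq(1, k, by = 2), drop = FALSE]
}

#' Gaussian-pyramid smoothing
#'
#' Applies `levels` pyramid reduce steps (5-tap binomial kernel
#' \[1, 4, 6, 4, 1\]/16, separable, symmetric reflect padding, x2
#' decimation) followed by `levels` bilinear expand steps back to the
#' original dimensions. This is the noise suppression applied to the nerve
#' probability map ahead of thresholding.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix.
#' @param levels number of reduce/expand steps (>= 0; 0 is the identity).
#' @return Same type as `map`, smoothed, values still in \[0, 1\].
#' @export
pyramidSmooth <- function(map, levels = 2) {
  m <- as_map_matrix(map)
  assert_that(is_count(levels), "levels must be a count >= 0")
  assert_that(min(dim(m)) >= 2^levels,
              "map of %d x %d is too small for %d pyramid levels",
              nrow(m), ncol(m), levels)
  if (levels > 0) {
    sizes <- vector("list", levels)
    for (l in seq_len(levels)) {
      sizes[[l]] <- dim(m)
      m <- reduce_once(m)
    }
    for (l in rev(seq_len(levels))) {
      m <- cpp_resize_bilinear(m, sizes[[l]][1], sizes[[l]][2])
    }
    m <- pmin(pmax(m, 0), 1)
  }
  if (is(map, "ProbabilityMap")) {
    ProbabilityMap(m, mpp = map@mpp, channel = map@channel)
  } else m
}

#' Otsu's threshold on a probability map
#'
#' The values are histogrammed into `bins` equal-width bins of \[0, 1\] and
#' the bin upper edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` is returned (bin centers serve as class
#' values); ties break toward the smallest threshold. A degenerate
#' histogram (a single occupied bin) returns that bin's upper edge with the
#' `degenerate` attribute set.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix with values in
#'   \[0, 1\].
#' @param bins number of histogram bins.
#' @return Threshold in \[0, 1\) (upper edge of the optimal bin), with
#'   attribute `degenerate` (logical).
#' @export
otsuThreshold <- function(map, bins = 256) {
  v <- as_map_matrix(map)
  assert_that(length(v) > 0, "map must be non-empty")
  bin <- pmin(floor(v * bins), bins - 1)  # 0-based bin index
  counts <- tabulate(bin + 1, nbins = bins)
  occupied <- which(counts > 0)
  if (length(occupied) == 1) {
    t <- occupied / bins  # upper edge of the single occupied bin
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  n <- sum(counts)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(counts) / n
  s0 <- cumsum(counts * mids)
  mu <- s0[bins]
  # split after bin k: class 0 = bins 1..k, class 1 = rest
  k <- seq_len(bins - 1)
  w1 <- 1 - w0[k]
  mu0 <- ifelse(w0[k] > 0, s0[k] / (w0[k] * n), 0)
  mu1 <- ifelse(w1 > 0, (mu - s0[k]) / (w1 * n), 0)
  sigma_b <- w0[k] * w1 * (mu0 - mu1)^2
  # smallest threshold among (near-)ties; the tolerance absorbs float noise
  # on plateaus where the variance is mathematically constant
  best <- which(sigma_b >= max(sigma_b) - 1e-12)[1]
  t <- best / bins
  attr(t, "degenerate") <- FALSE
  t
}

#' Binarize the PNI probability map
#'
#' Combines constant thresholding with Otsu's technique: the effective
#' threshold is `max(constThreshold, otsuThreshold(map))`, so weak signal
#' "undetectable to the human eye" is suppressed even when Otsu's split is
#' low. A degenerate Otsu result (single-bin histogram) falls back to the
#' constant threshold alone. Foreground means value strictly greater than
#' the effective threshold.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix.
#' @param constThreshold constant threshold in (0, 1).
#' @param bins histogram bins for Otsu's method.
#' @return logical matrix (TRUE = foreground), with attribute
#'   `effective_threshold`.
#' @export
binarizePni <- function(map, constThreshold = 0.5, bins = 256) {
  assert_that(constThreshold > 0 && constThreshold < 1,
              "constThreshold must lie in (0, 1)")
  v <- as_map_matrix(map)
  t <- otsuThreshold(v, bins = bins)
  eff <- if (isTRUE(attr(t, "degenerate"))) constThreshold
         else max(constThreshold, as.numeric(t))
  mask <- v > eff
  attr(mask, "effective_threshold") <- eff
  mask
}

# Morphological opening/closing on a logical mask with an EBImage brush,
# returning a logical matrix.
morph_open_close <- function(mask, radius) {
  if (radius == 0 || !any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask))
  m <- EBImage::closing(EBImage::opening(m, kern), kern)
  matrix(as.logical(EBImage::imageData(m) > 0.5), nrow(mask))
}

#' Extract the nerve mask from a nerve probability map
#'
#' Pyramid smoothing, constant thresholding, then a smoothing construction:
#' morphological opening followed by closing with a disk of radius
#' `smoothingRadiusPx`. The opening removes protrusions and the staircase
#' ("right angle") artifacts of blocky segmentation output; the closing
#' fills notches.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix (nerve channel).
#' @param cfg a [DecisionConfig-class].
#' @return logical matrix of nerve pixels.
#' @export
extractNerveMask <- function(map, cfg = DecisionConfig()) {
  validObject(cfg)
  m <- as_map_matrix(pyramidSmooth(map, cfg@pyramidLevels))
  mask <- m > cfg@nerveThreshold
  morph_open_close(mask, cfg@smoothingRadiusPx)
}

#' Label connected components of a binary mask
#'
#' Standard connected-component labeling under 4- or 8-connectivity.
#' Labels are ordered by the first pixel encountered in a row-major scan.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal contact joins).
#' @return A [ComponentSet-class].
#' @export
extractComponents <- function(mask, connectivity = 8) {
  assert_that(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  mode(mask) <- "logical"
  labels <- cpp_label_components(mask, as.integer(connectivity))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    tab <- data.frame(label = integer(0), area_px2 = numeric(0),
                      r0 = numeric(0), c0 = numeric(0),
                      r1 = numeric(0), c1 = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0))
    return(new("ComponentSet", labels = labels, table = tab,
               connectivity = connectivity))
  }
  lab <- labels[idx]
  r <- idx[, 1]; cc <- idx[, 2]
  tab <- data.frame(
    label = sort(unique(lab)),
    area_px2 = as.numeric(tabulate(lab)),
    r0 = as.numeric(tapply(r, lab, min)) - 1,
    c0 = as.numeric(tapply(cc, lab, min)) - 1,
    r1 = as.numeric(tapply(r, lab, max)),
    c1 = as.numeric(tapply(cc, lab, max)),
    centroid_r = as.numeric(tapply(r, lab, mean)) - 1,
    centroid_c = as.numeric(tapply(cc, lab, mean)) - 1
  )
  rownames(tab) <- NULL
  new("ComponentSet", labels = labels, table = tab, connectivity = connectivity)
}

#' Size-filter a set of components
#'
#' Components with `area_px2 <= cutoffPx2` are removed, the rest retained
#' (a partition of the input). The `<=` rule makes a cutoff equal to the
#' nearest-rank calibration quantile remove exactly the calibrated fraction
#' on the calibration sample.
#'
#' @param components a [ComponentSet-class].
#' @param cutoffPx2 cutoff in pixel^2 (>= 0; may be `Inf`).
#' @return list of two [ComponentSet-class]s, `retained` and `removed`,
#'   sharing the input's label matrix.
#' @export
sizeFilter <- function(components, cutoffPx2) {
  assert_that(length(cutoffPx2) == 1 && !is.na(cutoffPx2) && cutoffPx2 >= 0,
              "cutoff must be a single value >= 0")
  tab <- components@table
  drop <- tab$area_px2 <= cutoffPx2
  mk <- function(t) new("ComponentSet", labels = components@labels,
                        table = t, connectivity = components@connectivity)
  list(retained = mk(tab[!drop, , drop = FALSE]),
       removed = mk(tab[drop, , drop = FALSE]))
}

# Dilate the pixels of one labeled component by a Chebyshev ball (box brush)
# of radius `a`, working on a bbox crop for speed. Returns the nerve labels
# hit by the dilated component.
labels_within_chebyshev <- function(compLabels, row, nerveLabels, a) {
  H <- nrow(compLabels); W <- ncol(compLabels)
  r0 <- max(1, row$r0 + 1 - a); r1 <- min(H, row$r1 + a)
  c0 <- max(1, row$c0 + 1 - a); c1 <- min(W, row$c1 + a)
  sub <- compLabels[r0:r1, c0:c1, drop = FALSE] == row$label
  if (a > 0) {
    kern <- EBImage::makeBrush(2 * a + 1, shape = "box")
    sub <- EBImage::imageData(
      EBImage::dilate(matrix(as.numeric(sub), nrow(sub)), kern)) > 0.5
  }
  hit <- nerveLabels[r0:r1, c0:c1, drop = FALSE][sub]
  unique(hit[hit > 0])
}

#' Assign PNI status to nerve structures
#'
#' A nerve is labeled `PNI` exactly when some retained PNI component has a
#' pixel within Chebyshev distance `adjacencyPx` of a pixel of that nerve
#' (`adjacencyPx = 0` requires actual overlap). One PNI component may
#' support several nerves. The supporting component labels are recorded per
#' nerve.
#'
#' @param nerveComponents a [ComponentSet-class] of nerve structures.
#' @param pniComponents a [ComponentSet-class] of (retained) PNI
#'   components; both must come from masks of identical dimensions.
#' @param adjacencyPx Chebyshev adjacency distance in pixels.
#' @return data.frame, one row per nerve: `id`, `area_px2`, bounding box,
#'   `predicted_class`, `n_supporting`, and a `supporting` list column of
#'   PNI component labels.
#' @export
assignPni <- function(nerveComponents, pniComponents, adjacencyPx = 5) {
  assert_that(identical(dim(nerveComponents@labels), dim(pniComponents@labels)),
              "nerve and PNI masks must share dimensions")
  assert_that(length(adjacencyPx) == 1 && adjacencyPx >= 0,
              "adjacencyPx must be >= 0")
  ntab <- nerveComponents@table
  support <- rep(list(integer(0)), nrow(ntab))
  names(support) <- as.character(ntab$label)
  ptab <- pniComponents@table
  if (nrow(ptab) > 0 && nrow(ntab) > 0) {
    for (i in seq_len(nrow(ptab))) {
      hits <- labels_within_chebyshev(pniComponents@labels, ptab[i, ],
                                      nerveComponents@labels, adjacencyPx)
      for (h in hits) {
        key <- as.character(h)
        support[[key]] <- c(support[[key]], ptab$label[i])
      }
    }
  }
  nsup <- vapply(support, length, integer(1))
  out <- data.frame(
    id = ntab$label, area_px2 = ntab$area_px2,
    r0 = ntab$r0, c0 = ntab$c0, r1 = ntab$r1, c1 = ntab$c1,
    predicted_class = ifelse(nsup > 0, "PNI", "normal"),
    n_supporting = as.integer(nsup)
  )
  out$supporting <- unname(support)
  rownames(out) <- NULL
  out
}

#' Run the full PNI decision rule flow
#'
#' Composition of the post-processing stages: the nerve map is pyramid
#' smoothed, thresholded and morphologically cleaned, then labeled into
#' nerve structures; the PNI map is binarized by the combined constant/Otsu
#' threshold, labeled, size filtered; finally each nerve structure is
#' inspected for a retained PNI component within the adjacency distance.
#' Deterministic for identical inputs and configuration.
#'
#' @param nerveMap,pniMap [ProbabilityMap-class]s (or numeric matrices) of
#'   identical dimensions.
#' @param cfg a [DecisionConfig-class].
#' @return A [DecisionResult-class] with the per-nerve table and all
#'   intermediate masks/components for audit.
#' @examples
#' spec <- SceneSpec(seed = 11)
#' sc <- generateScene(spec)
#' maps <- sceneToProbabilityMaps(sc, blurSigma = 1, noiseSd = 0.05, seed = 2)
#' res <- runDecisionFlow(maps$nerve, maps$pni)
#' nerveTable(res)[, c("id", "area_px2", "predicted_class")]
#' @export
runDecisionFlow <- function(nerveMap, pniMap, cfg = DecisionConfig()) {
  validObject(cfg)
  nm <- as_map_matrix(nerveMap); pm <- as_map_matrix(pniMap)
  assert_that(identical(dim(nm), dim(pm)), "maps must share dimensions")
  if (is(nerveMap, "ProbabilityMap") && is(pniMap, "ProbabilityMap")) {
    assert_that(isTRUE(all.equal(nerveMap@mpp, pniMap@mpp)),
                "maps must share the pixel scale")
  }
  nerveMask <- extractNerveMask(nm, cfg)
  nerveComponents <- extractComponents(nerveMask, cfg@connectivity)
  pniMask <- binarizePni(pm, cfg@pniConstThreshold)
  pniComponents <- extractComponents(pniMask, cfg@connectivity)
  filt <- sizeFilter(pniComponents, cfg@sizeCutoffPx2)
  nerves <- assignPni(nerveComponents, filt$retained, cfg@adjacencyPx)
  new("DecisionResult", nerves = nerves, nerveMask = nerveMask,
      pniMask = pniMask, nerveComponents = nerveComponents,
      pniComponents = pniComponents, retained = filt$retained@table,
      removed = filt$removed@table, config = cfg)
}
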