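# Synthetic histology-like scenes with ground truth, so that every
# downstream stage (segmentation, rule flow, calibration, evaluation) is
# testable without clinical slides.
#
# Draw order from the scene seed is fixed and documented: nerve geometry ->
# PNI nerve selection -> nests -> noise blobs -> perineural specks ->
# background texture. Adding noise objects therefore never perturbs nerve
# placement.

# Logical mask of an ellipse over a bbox crop; returns row/col ranges and
# the submatrix.
ellipse_patch <- function(H, W, cy, cx, a, b, theta) {
  reach <- max(a, b)
  r0 <- max(1, floor(cy - reach)); r1 <- min(H, ceiling(cy + reach))
  c0 <- max(1, floor(cx - reach)); c1 <- min(W, ceiling(cx + reach))
  rr <- r0:r1; cc <- c0:c1
  dr <- matrix(rr - cy, length(rr), length(cc))
  dc <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  list(rows = rr, cols = cc, mask = (u / a)^2 + (v / b)^2 <= 1)
}

paint <- function(canvas, patch, value) {
  sub <- canvas[patch$rows, patch$cols]
  sub[patch$mask] <- value
  canvas[patch$rows, patch$cols] <- sub
  canvas
}

or_patch <- function(mask, patch) {
  mask[patch$rows, patch$cols] <- mask[patch$rows, patch$cols] | patch$mask
  mask
}

# Hex-lattice offsets (rotated) for a nest of k tumor cells with spacing s;
# the k points nearest the origin, with a little jitter.
nest_offsets <- function(k, s, rotation, jitterSd = 1.5) {
  m <- 1
  while (3 * m * (m + 1) + 1 < k) m <- m + 1
  q <- rep(-m:m, each = 2 * m + 1)
  r <- rep(-m:m, times = 2 * m + 1)
  keep <- abs(q + r) <= m
  q <- q[keep]; r <- r[keep]
  x <- s * (q + r / 2)
  y <- s * r * sqrt(3) / 2
  rot <- cbind(x * cos(rotation) - y * sin(rotation),
               x * sin(rotation) + y * cos(rotation))
  rot <- rot + pmax(pmin(matrix(stats::rnorm(length(rot), 0, jitterSd),
                                ncol = 2), 4), -4)
  d <- sqrt(rowSums(rot^2))
  rot[order(d)[seq_len(k)], , drop = FALSE]
}

# How far (px) a nest can extend beyond its anchor point on the perineurium.
nest_reach <- function(kmax, cellDiameter) {
  s <- 0.92 * cellDiameter
  m <- 1
  while (3 * m * (m + 1) + 1 < kmax) m <- m + 1
  m * s + 4 + cellDiameter / 2 + 2
}

scene_palette <- list(
  background  = c(0.91, 0.79, 0.85),
  nerve       = c(0.84, 0.64, 0.74),
  perineurium = c(0.58, 0.39, 0.52),
  tumor       = c(0.38, 0.22, 0.47),
  noise       = c(0.45, 0.30, 0.52)
)

#' Generate a synthetic histology scene
#'
#' Renders an H&E-like RGB phantom with consistent ground-truth masks:
#' elliptical nerves with a darker perineurium ring; for a fraction of
#' nerves, a nest of disk-shaped tumor cells anchored on (and crossing) the
#' perineurium -- the planted perineural invasion; far-from-nerve noise
#' blobs whose areas drive size-filter calibration; and small perineural
#' "specks" 2-4 px off a nerve boundary emulating spurious segmentation
#' signal from peri-nerve fibroblasts and inflammatory cells. Deterministic
#' for a fixed `spec@seed`.
#'
#' Nerves are placed on a jittered grid (stratified placement) so that
#' nerve-plus-nest envelopes can never collide; noise objects are placed by
#' rejection sampling with a bounded retry count. A noise blob from the far
#' upper tail of the size distribution that cannot fit between the nerve
#' envelopes is redrawn from the same distribution (at most 50 times).
#' Exhausting the retries, or a canvas too small to hold the requested
#' nerve geometry, is an error.
#'
#' @param spec a [SceneSpec-class].
#' @param maxTries retry bound for rejection sampling.
#' @return A [SyntheticScene-class].
#' @examples
#' sc <- generateScene(SceneSpec(nNerves = 2, pniFraction = 0.5, seed = 3))
#' sc@nerveRecords
#' @export
generateScene <- function(spec, maxTries = 1000) {
  validObject(spec)
  H <- spec@heightPx; W <- spec@widthPx
  n <- spec@nNerves
  t <- spec@perineuriumThicknessPx
  d <- spec@tumorCellDiameterPx
  maxAxis <- spec@nerveAxisRangePx[2]
  reach <- if (spec@pniFraction > 0 && n > 0) nest_reach(spec@pniNestCells[2], d) else 0
  R <- maxAxis + t + max(reach, 8)

  nerveTruth <- matrix(FALSE, H, W)
  pniTruth <- matrix(FALSE, H, W)
  noiseTruth <- matrix(FALSE, H, W)
  nerveLabels <- matrix(0L, H, W)
  # render into per-channel matrices (assembled into the RGB array at the end)
  chans <- lapply(scene_palette$background, function(v) matrix(v, H, W))

  with_seed(spec@seed, {
    centers <- NULL
    geom <- NULL
    if (n > 0) {
      g <- ceiling(sqrt(n))
      cellH <- H / g; cellW <- W / g
      assert_that(min(cellH, cellW) >= 2 * R + 4,
                  paste0("canvas of %d x %d px cannot hold %d nerves with an ",
                         "envelope radius of %.0f px (need grid cells >= %.0f px)"),
                  H, W, n, R, 2 * R + 4)
      jitH <- min(cellH - 2 * R - 4, cellH / 3)
      jitW <- min(cellW - 2 * R - 4, cellW / 3)
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        cells <- sample.int(g * g, n) - 1L
        cy <- (cells %% g) * cellH + cellH / 2 + stats::runif(n, -jitH / 2, jitH / 2)
        cx <- (cells %/% g) * cellW + cellW / 2 + stats::runif(n, -jitW / 2, jitW / 2)
        if (n == 1 || min(stats::dist(cbind(cy, cx))) >= 2 * R + 2) { ok <- TRUE; break }
      }
      assert_that(ok, "nerve placement failed after %d tries", maxTries)
      centers <- cbind(cy, cx)
      geom <- data.frame(a = numeric(n), b = numeric(n), theta = numeric(n))
      for (i in seq_len(n)) {
        ax <- sort(stats::runif(2, spec@nerveAxisRangePx[1], spec@nerveAxisRangePx[2]),
                   decreasing = TRUE)
        th <- stats::runif(1, 0, pi)
        geom$a[i] <- ax[1]; geom$b[i] <- ax[2]; geom$theta[i] <- th
        outer_p <- ellipse_patch(H, W, cy[i], cx[i], ax[1] + t, ax[2] + t, th)
        inner_p <- ellipse_patch(H, W, cy[i], cx[i], ax[1], ax[2], th)
        nerveTruth <- or_patch(nerveTruth, outer_p)
        lab <- nerveLabels[outer_p$rows, outer_p$cols]
        lab[outer_p$mask] <- i
        nerveLabels[outer_p$rows, outer_p$cols] <- lab
        for (ch in 1:3) {
          chans[[ch]] <- paint(chans[[ch]], outer_p, scene_palette$perineurium[ch])
          chans[[ch]] <- paint(chans[[ch]], inner_p, scene_palette$nerve[ch])
        }
      }
    }

    # PNI nerve selection and nests
    nPni <- round(spec@pniFraction * n)
    pniIds <- if (nPni > 0) sort(sample.int(n, nPni)) else integer(0)
    for (i in pniIds) {
      k <- sample(seq(spec@pniNestCells[1], spec@pniNestCells[2]), 1)
      phi <- stats::runif(1, 0, 2 * pi)
      th <- geom$theta[i]
      a <- geom$a[i] + t; b <- geom$b[i] + t
      px <- a * cos(phi); py <- b * sin(phi)
      anchor <- c(centers[i, 1] + px * cos(th) - py * sin(th),
                  centers[i, 2] + px * sin(th) + py * cos(th))
      offs <- nest_offsets(k, 0.92 * d, stats::runif(1, 0, 2 * pi))
      for (j in seq_len(k)) {
        patch <- ellipse_patch(H, W, anchor[1] + offs[j, 1], anchor[2] + offs[j, 2],
                               d / 2, d / 2, 0)
        pniTruth <- or_patch(pniTruth, patch)
        for (ch in 1:3) chans[[ch]] <- paint(chans[[ch]], patch,
                                             scene_palette$tumor[ch])
      }
    }

    # Noise blobs away from every nerve (calibration sample)
    blobAreas <- draw_areas(spec@noiseSizeDist, spec@nNoiseBlobs)
    distToStructures <- if (n > 0 || any(pniTruth)) {
      EBImage::imageData(EBImage::distmap(matrix(
        as.numeric(!(nerveTruth | pniTruth)), H)))
    } else matrix(Inf, H, W)
    placedC <- matrix(numeric(0), ncol = 2)
    placedR <- numeric(0)
    for (i in seq_along(blobAreas)) {
      # a blob from the far upper tail may not fit between the nerve
      # envelopes; such blobs are redrawn from the same distribution
      # (bounded number of redraws, then an error)
      ok <- FALSE
      for (redraw in seq_len(50)) {
        rb <- sqrt(blobAreas[i] / pi)
        if (rb + 9 < H - rb - 8 && rb + 9 < W - rb - 8) {
          for (try in seq_len(maxTries)) {
            yc <- stats::runif(1, rb + 9, H - rb - 8)
            xc <- stats::runif(1, rb + 9, W - rb - 8)
            if (distToStructures[round(yc), round(xc)] < rb + 15) next
            if (nrow(placedC) > 0 &&
                min(sqrt((placedC[, 1] - yc)^2 + (placedC[, 2] - xc)^2) -
                    placedR) < rb + 8) next
            ok <- TRUE; break
          }
        }
        if (ok) break
        blobAreas[i] <- draw_areas(spec@noiseSizeDist, 1)
      }
      assert_that(ok, "noise blob placement failed after %d tries", maxTries)
      patch <- ellipse_patch(H, W, yc, xc, rb, rb, 0)
      noiseTruth <- or_patch(noiseTruth, patch)
      for (ch in 1:3) chans[[ch]] <- paint(chans[[ch]], patch,
                                           scene_palette$noise[ch])
      placedC <- rbind(placedC, c(yc, xc))
      placedR <- c(placedR, rb)
    }

    # Perineural specks: small false-signal blobs 2-4 px off a nerve boundary
    speckAreas <- if (n > 0) draw_areas(spec@speckSizeDist, spec@nSpecks) else numeric(0)
    for (i in seq_along(speckAreas)) {
      rs <- sqrt(speckAreas[i] / pi)
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        j <- sample.int(n, 1)
        phi <- stats::runif(1, 0, 2 * pi)
        gap <- stats::runif(1, 2, 4)
        th <- geom$theta[j]
        a <- geom$a[j] + t; b <- geom$b[j] + t
        px <- a * cos(phi); py <- b * sin(phi)
        anchor <- c(centers[j, 1] + px * cos(th) - py * sin(th),
                    centers[j, 2] + px * sin(th) + py * cos(th))
        nrm <- c(cos(phi) / a, sin(phi) / b)
        nrm <- c(nrm[1] * cos(th) - nrm[2] * sin(th),
                 nrm[1] * sin(th) + nrm[2] * cos(th))
        nrm <- nrm / sqrt(sum(nrm^2))
        yc <- anchor[1] + nrm[1] * (gap + rs)
        xc <- anchor[2] + nrm[2] * (gap + rs)
        if (yc < rs + 9 || yc > H - rs - 8 || xc < rs + 9 || xc > W - rs - 8) next
        # crop checks: no overlap with any nerve, >= 8 px from other signal
        r0 <- max(1, floor(yc - rs - 8)); r1 <- min(H, ceiling(yc + rs + 8))
        c0 <- max(1, floor(xc - rs - 8)); c1 <- min(W, ceiling(xc + rs + 8))
        rr <- r0:r1; cc <- c0:c1
        dr <- matrix(rr - yc, length(rr), length(cc))
        dc <- matrix(cc - xc, length(rr), length(cc), byrow = TRUE)
        d2 <- dr^2 + dc^2
        inDisk <- d2 <= rs^2
        near <- d2 <= (rs + 8)^2
        if (any(nerveTruth[rr, cc] & inDisk)) next
        if (any((pniTruth[rr, cc] | noiseTruth[rr, cc]) & near)) next
        ok <- TRUE; break
      }
      assert_that(ok, "speck placement failed after %d tries", maxTries)
      patch <- ellipse_patch(H, W, yc, xc, rs, rs, 0)
      noiseTruth <- or_patch(noiseTruth, patch)
      for (ch in 1:3) chans[[ch]] <- paint(chans[[ch]], patch,
                                           scene_palette$noise[ch])
    }

    # Background texture
    if (spec@backgroundTexture > 0) {
      tex <- matrix(stats::rnorm(H * W, 0, spec@backgroundTexture), H, W)
      for (ch in 1:3) chans[[ch]] <- chans[[ch]] + tex
    }
    image <- array(0, c(H, W, 3))
    for (ch in 1:3) image[, , ch] <- chans[[ch]]
    image <- pmin(pmax(image, 0), 1)
    noiseAreas <- c(blobAreas, speckAreas)

    # Nerve records with half-open 0-based bounding boxes and true class
    records <- data.frame(id = integer(0), r0 = numeric(0), c0 = numeric(0),
                          r1 = numeric(0), c1 = numeric(0), class = character(0))
    if (n > 0) {
      idx <- which(nerveLabels > 0, arr.ind = TRUE)
      lab <- nerveLabels[idx]
      records <- data.frame(
        id = seq_len(n),
        r0 = as.numeric(tapply(idx[, 1], lab, min)) - 1,
        c0 = as.numeric(tapply(idx[, 2], lab, min)) - 1,
        r1 = as.numeric(tapply(idx[, 1], lab, max)),
        c1 = as.numeric(tapply(idx[, 2], lab, max)),
        class = ifelse(seq_len(n) %in% pniIds, "PNI", "normal")
      )
    }

    new("SyntheticScene", image = image, nerveTruth = nerveTruth,
        pniTruth = pniTruth, noiseTruth = noiseTruth,
        nerveLabels = nerveLabels, nerveRecords = records,
        noiseAreas = noiseAreas, spec = spec)
  })
}

#' Simulate segmentation output for a synthetic scene
#'
#' Emulates the inference stage so the rule flow can be exercised without a
#' trained model: the ground-truth masks are softened by a Gaussian blur and
#' corrupted by clipped additive pixel noise. The PNI map carries the noise
#' blobs and perineural specks as foreground signal in addition to the
#' planted nests -- exactly the spurious components the size filter exists
#' to remove.
#'
#' @param scene a [SyntheticScene-class].
#' @param blurSigma Gaussian sigma in pixels (>= 0; 0 = no blur).
#' @param noiseSd standard deviation of additive Gaussian pixel noise, in
#'   \[0, 0.5).
#' @param seed RNG seed for the pixel noise.
#' @return list with elements `nerve` and `pni`, both
#'   [ProbabilityMap-class]; with `blurSigma = 0, noiseSd = 0` the maps
#'   equal the binary truth masks exactly.
#' @export
sceneToProbabilityMaps <- function(scene, blurSigma = 1, noiseSd = 0.05,
                                   seed = 1) {
  assert_that(blurSigma >= 0, "blurSigma must be >= 0")
  assert_that(noiseSd >= 0 && noiseSd < 0.5, "noiseSd must lie in [0, 0.5)")
  nerve <- matrix(as.numeric(scene@nerveTruth), nrow(scene@nerveTruth))
  pni <- matrix(as.numeric(scene@pniTruth | scene@noiseTruth),
                nrow(scene@pniTruth))
  if (blurSigma > 0) {
    nerve <- EBImage::imageData(EBImage::gblur(nerve, sigma = blurSigma))
    pni <- EBImage::imageData(EBImage::gblur(pni, sigma = blurSigma))
  }
  if (noiseSd > 0) {
    with_seed(seed, {
      nerve <- nerve + matrix(stats::rnorm(length(nerve), 0, noiseSd), nrow(nerve))
      pni <- pni + matrix(stats::rnorm(length(pni), 0, noiseSd), nrow(pni))
    })
  }
  clip <- function(m) pmin(pmax(m, 0), 1)
  list(nerve = ProbabilityMap(clip(nerve), mpp = scene@spec@mpp, channel = "nerve"),
       pni = ProbabilityMap(clip(pni), mpp = scene@spec@mpp, channel = "pni"))
}

#' Annotation records for a scene's ground truth
#'
#' @param scene a [SyntheticScene-class].
#' @param slideId slide identifier to attach.
#' @return data.frame in the annotation-record format (source `"human"`).
#' @export
sceneAnnotationRecords <- function(scene, slideId = "synthetic") {
  rec <- scene@nerveRecords
  data.frame(slide_id = slideId,
             label = ifelse(rec$class == "PNI", "PNI", "normal_nerve"),
             source = "human",
             r0 = rec$r0, c0 = rec$c0, r1 = rec$r1, c1 = rec$c1)
}

#' Write a scene and its ground truth to a directory
#'
#' Writes `image.tiff` (RGB), `nerve_truth.png`, `pni_truth.png`,
#' `noise_truth.png` (8-bit 0/255) and `records.json`.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param slideId slide identifier for the records.
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir, slideId = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(scene@image, file.path(dir, "image.tiff"), bits.per.sample = 8L)
  writeMask(scene@nerveTruth, file.path(dir, "nerve_truth.png"))
  writeMask(scene@pniTruth, file.path(dir, "pni_truth.png"))
  writeMask(scene@noiseTruth, file.path(dir, "noise_truth.png"))
  writeAnnotations(sceneAnnotationRecords(scene, slideId),
                   file.path(dir, "records.json"))
  invisible(dir)
}

#' Read a SceneSpec from a YAML file
#'
#' Field names mirror the [SceneSpec()] arguments; distributions are maps
#' with a `name` field, e.g. `noiseSizeDist: {name: lognormal, meanlog: 9,
#' sdlog: 0.8}`.
#'
#' @param path YAML file.
#' @return A [SceneSpec-class].
#' @export
readSceneSpec <- function(path) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(SceneSpec))
  extra <- setdiff(names(y), known)
  assert_that(length(extra) == 0, "unknown SceneSpec fields: %s",
              paste(extra, collapse = ", "))
  do.call(SceneSpec, y)
}
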