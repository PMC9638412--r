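#' @useDynLib nervePNI, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Probability maps
# ---------------------------------------------------------------------------

#' Single-channel probability map
#'
#' The per-pixel output of a segmentation stage: a 2-D grid of values in
#' \[0, 1\] with its physical pixel scale (microns per pixel) and the channel
#' it describes (`"nerve"` or `"pni"`).
#'
#' @slot values numeric matrix with all entries in \[0, 1\].
#' @slot mpp microns per pixel (> 0).
#' @slot channel `"nerve"` or `"pni"`.
#' @export
setClass("ProbabilityMap",
  representation(values = "matrix", mpp = "numeric", channel = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (length(v) == 0) return("values must be non-empty")
    if (anyNA(v) || min(v) < 0 || max(v) > 1) {
      return("all probability values must lie in [0, 1]")
    }
    if (length(object@mpp) != 1 || !is.finite(object@mpp) || object@mpp <= 0) {
      return("mpp must be a single positive number")
    }
    if (!object@channel %in% c("nerve", "pni")) {
      return("channel must be 'nerve' or 'pni'")
    }
    TRUE
  }
)

#' Construct a ProbabilityMap
#'
#' @param values numeric matrix in \[0, 1\] (rows = image rows).
#' @param mpp microns per pixel; default 0.23, the scale of a 400x
#'   whole-slide scan.
#' @param channel which signal the map encodes: `"nerve"` or `"pni"`.
#' @return A [ProbabilityMap-class] object.
#' @examples
#' pm <- ProbabilityMap(matrix(runif(64), 8), channel = "pni")
#' dim(mapValues(pm))
#' @export
ProbabilityMap <- function(values, mpp = 0.23, channel = c("nerve", "pni")) {
  channel <- match.arg(channel)
  new("ProbabilityMap", values = values, mpp = mpp, channel = channel)
}

# ---------------------------------------------------------------------------
# Synthetic scenes
# ---------------------------------------------------------------------------

#' Specification of a synthetic histology scene
#'
#' Describes a reproducible H&E-like phantom: elliptical nerve fascicles with
#' a darker perineurium ring, tumor-cell nests planted against a subset of
#' nerves (the perineural-invasion cases), scattered noise blobs far from any
#' nerve (the calibration sample for the size filter) and small perineural
#' "specks" close to nerve boundaries that emulate spurious segmentation
#' signal from fibroblasts and inflammatory cells.
#'
#' @slot heightPx,widthPx canvas size in pixels.
#' @slot mpp microns per pixel (default 0.23).
#' @slot nNerves number of nerve structures.
#' @slot pniFraction fraction of nerves with a planted invasion nest.
#' @slot nerveAxisRangePx min/max ellipse semi-axes in pixels.
#' @slot perineuriumThicknessPx thickness of the perineurium ring.
#' @slot tumorCellDiameterPx rendered tumor-cell diameter in pixels
#'   (default 13.5 um / 0.23 um/px).
#' @slot pniNestCells min/max number of cells per planted nest.
#' @slot nNoiseBlobs number of far-from-nerve noise blobs.
#' @slot noiseSizeDist named distribution for blob areas in pixel^2.
#' @slot nSpecks number of small near-nerve false-signal blobs.
#' @slot speckSizeDist named distribution for speck areas in pixel^2.
#' @slot backgroundTexture amplitude of the background texture noise.
#' @slot seed integer seed driving all placement and texture draws.
#' @export
setClass("SceneSpec",
  representation(
    heightPx = "numeric", widthPx = "numeric", mpp = "numeric",
    nNerves = "numeric", pniFraction = "numeric",
    nerveAxisRangePx = "numeric", perineuriumThicknessPx = "numeric",
    tumorCellDiameterPx = "numeric", pniNestCells = "numeric",
    nNoiseBlobs = "numeric", noiseSizeDist = "list",
    nSpecks = "numeric", speckSizeDist = "list",
    backgroundTexture = "numeric", seed = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (!is_count(object@heightPx) || !is_count(object@widthPx) ||
        object@heightPx < 1 || object@widthPx < 1) {
      msg <- c(msg, "canvas dimensions must be positive integers")
    }
    for (f in c("nNerves", "nNoiseBlobs", "nSpecks")) {
      if (!is_count(slot(object, f))) msg <- c(msg, paste(f, "must be a count >= 0"))
    }
    if (object@pniFraction < 0 || object@pniFraction > 1) {
      msg <- c(msg, "pniFraction must lie in [0, 1]")
    }
    ax <- object@nerveAxisRangePx
    if (length(ax) != 2 || any(ax <= 0) || ax[1] > ax[2]) {
      msg <- c(msg, "nerveAxisRangePx must be positive with min <= max")
    }
    nc <- object@pniNestCells
    if (length(nc) != 2 || any(nc < 1) || nc[1] > nc[2]) {
      msg <- c(msg, "pniNestCells must be >= 1 with min <= max")
    }
    if (object@mpp <= 0) msg <- c(msg, "mpp must be > 0")
    if (object@tumorCellDiameterPx <= 0) msg <- c(msg, "tumorCellDiameterPx must be > 0")
    if (object@perineuriumThicknessPx < 0) msg <- c(msg, "perineuriumThicknessPx must be >= 0")
    if (object@backgroundTexture < 0) msg <- c(msg, "backgroundTexture must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SceneSpec
#'
#' Defaults describe the phantom used throughout the package's tests: a
#' 960 x 960 canvas at 0.23 um/px with 4 nerves, half of them carrying a
#' planted invasion nest of 12-18 tumor cells (58.7 px diameter, i.e.
#' 13.5 um), 8 far-from-nerve noise blobs with lognormal(9, 0.8) areas that
#' straddle the 21,632 px^2 size-filter cutoff, and 3 small perineural
#' specks (lognormal(7.3, 0.5) areas) hugging nerve boundaries.
#'
#' @param heightPx,widthPx canvas size in pixels.
#' @param mpp microns per pixel.
#' @param nNerves number of nerves.
#' @param pniFraction fraction of nerves with planted invasion.
#' @param nerveAxisRangePx length-2 numeric, min/max ellipse semi-axes (px).
#' @param perineuriumThicknessPx perineurium ring thickness (px).
#' @param tumorCellDiameterPx tumor-cell diameter (px).
#' @param pniNestCells length-2 numeric, min/max cells per nest.
#' @param nNoiseBlobs number of noise blobs.
#' @param noiseSizeDist named list distribution for blob areas (px^2),
#'   e.g. `list(name = "lognormal", meanlog = 9, sdlog = 0.8)`.
#' @param nSpecks number of near-nerve specks.
#' @param speckSizeDist named list distribution for speck areas (px^2).
#' @param backgroundTexture background texture noise amplitude.
#' @param seed integer seed.
#' @return A [SceneSpec-class] object.
#' @export
SceneSpec <- function(heightPx = 960, widthPx = 960, mpp = 0.23,
                      nNerves = 4, pniFraction = 0.5,
                      nerveAxisRangePx = c(40, 70),
                      perineuriumThicknessPx = 6,
                      tumorCellDiameterPx = 13.5 / 0.23,
                      pniNestCells = c(12, 18),
                      nNoiseBlobs = 8,
                      noiseSizeDist = list(name = "lognormal", meanlog = 9, sdlog = 0.8),
                      nSpecks = 3,
                      speckSizeDist = list(name = "lognormal", meanlog = 7.3, sdlog = 0.5),
                      backgroundTexture = 0.03, seed = 1) {
  new("SceneSpec",
      heightPx = heightPx, widthPx = widthPx, mpp = mpp, nNerves = nNerves,
      pniFraction = pniFraction, nerveAxisRangePx = as.numeric(nerveAxisRangePx),
      perineuriumThicknessPx = perineuriumThicknessPx,
      tumorCellDiameterPx = tumorCellDiameterPx,
      pniNestCells = as.numeric(pniNestCells), nNoiseBlobs = nNoiseBlobs,
      noiseSizeDist = noiseSizeDist, nSpecks = nSpecks,
      speckSizeDist = speckSizeDist, backgroundTexture = backgroundTexture,
      seed = seed)
}

#' A rendered synthetic scene with ground truth
#'
#' @slot image H x W x 3 array in \[0, 1\] (RGB).
#' @slot nerveTruth logical matrix, all nerve pixels (incl. perineurium).
#' @slot pniTruth logical matrix, tumor pixels of planted invasion nests.
#' @slot noiseTruth logical matrix, noise blobs and perineural specks.
#' @slot nerveLabels integer matrix assigning each nerve pixel its nerve id.
#' @slot nerveRecords data.frame with columns `id`, `r0`, `c0`, `r1`, `c1`
#'   (half-open, 0-based bounding box) and `class` (`"PNI"`/`"normal"`).
#' @slot noiseAreas numeric, the drawn target areas of blobs then specks.
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("SyntheticScene",
  representation(
    image = "array", nerveTruth = "matrix", pniTruth = "matrix",
    noiseTruth = "matrix", nerveLabels = "matrix", nerveRecords = "data.frame",
    noiseAreas = "numeric", spec = "SceneSpec"
  ),
  validity = function(object) {
    d <- dim(object@image)
    msg <- character(0)
    for (f in c("nerveTruth", "pniTruth", "noiseTruth", "nerveLabels")) {
      if (!identical(dim(slot(object, f)), d[1:2])) {
        msg <- c(msg, paste(f, "must share the image dimensions"))
      }
    }
    n <- object@spec@nNerves
    if (nrow(object@nerveRecords) != n) {
      msg <- c(msg, "number of nerve records must equal spec nNerves")
    }
    want <- round(object@spec@pniFraction * n)
    if (sum(object@nerveRecords$class == "PNI") != want) {
      msg <- c(msg, "count of PNI records must equal round(pniFraction * nNerves)")
    }
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# Rule-flow configuration and results
# ---------------------------------------------------------------------------

#' Configuration of the PNI decision rule flow
#'
#' @slot pyramidLevels Gaussian-pyramid reduce/expand levels for the nerve map.
#' @slot nerveThreshold constant threshold on the smoothed nerve map.
#' @slot smoothingRadiusPx disk radius for morphological opening/closing.
#' @slot pniConstThreshold constant threshold combined (by max) with Otsu's
#'   threshold on the PNI map.
#' @slot sizeCutoffPx2 size-filter cutoff; components with area <= cutoff are
#'   removed. Default 21632 px^2, the calibrated 10%-significance cutoff.
#' @slot adjacencyPx Chebyshev distance within which a retained PNI component
#'   marks a nerve as invaded (0 = overlap required).
#' @slot connectivity 4 or 8, pixel connectivity for component labeling.
#' @export
setClass("DecisionConfig",
  representation(
    pyramidLevels = "numeric", nerveThreshold = "numeric",
    smoothingRadiusPx = "numeric", pniConstThreshold = "numeric",
    sizeCutoffPx2 = "numeric", adjacencyPx = "numeric", connectivity = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (!is_count(object@pyramidLevels)) msg <- c(msg, "pyramidLevels must be a count >= 0")
    for (f in c("nerveThreshold", "pniConstThreshold")) {
      v <- slot(object, f)
      if (length(v) != 1 || v <= 0 || v >= 1) {
        msg <- c(msg, paste(f, "must lie in (0, 1)"))
      }
    }
    if (!is_count(object@smoothingRadiusPx)) msg <- c(msg, "smoothingRadiusPx must be a count >= 0")
    if (length(object@sizeCutoffPx2) != 1 || is.na(object@sizeCutoffPx2) ||
        object@sizeCutoffPx2 < 0) {
      msg <- c(msg, "sizeCutoffPx2 must be >= 0")
    }
    if (!(length(object@adjacencyPx) == 1 && object@adjacencyPx >= 0 &&
          (is.infinite(object@adjacencyPx) || object@adjacencyPx == floor(object@adjacencyPx)))) {
      msg <- c(msg, "adjacencyPx must be an integer >= 0")
    }
    if (!object@connectivity %in% c(4, 8)) msg <- c(msg, "connectivity must be 4 or 8")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a DecisionConfig
#'
#' @param pyramidLevels,nerveThreshold,smoothingRadiusPx,pniConstThreshold,sizeCutoffPx2,adjacencyPx,connectivity
#'   see [DecisionConfig-class] slots.
#' @return A [DecisionConfig-class] object.
#' @examples
#' cfg <- DecisionConfig(sizeCutoffPx2 = 36864)
#' @export
DecisionConfig <- function(pyramidLevels = 2, nerveThreshold = 0.5,
                           smoothingRadiusPx = 3, pniConstThreshold = 0.5,
                           sizeCutoffPx2 = 21632, adjacencyPx = 5,
                           connectivity = 8) {
  new("DecisionConfig",
      pyramidLevels = pyramidLevels, nerveThreshold = nerveThreshold,
      smoothingRadiusPx = smoothingRadiusPx,
      pniConstThreshold = pniConstThreshold, sizeCutoffPx2 = sizeCutoffPx2,
      adjacencyPx = adjacencyPx, connectivity = connectivity)
}

#' Connected components of a binary mask
#'
#' @slot labels integer matrix; 0 = background, components numbered by the
#'   first pixel encountered in a row-major scan.
#' @slot table data.frame, one row per component: `label`, `area_px2`,
#'   half-open bounding box `r0`, `c0`, `r1`, `c1` (0-based) and
#'   `centroid_r`, `centroid_c`.
#' @slot connectivity 4 or 8.
#' @export
setClass("ComponentSet",
  representation(labels = "matrix", table = "data.frame", connectivity = "numeric"))

#' Result of the PNI decision rule flow
#'
#' @slot nerves data.frame, one row per detected nerve: `id`, `area_px2`,
#'   bounding box, `predicted_class` and `n_supporting`; the
#'   `supporting` list column holds the labels of the retained PNI
#'   components within the adjacency distance.
#' @slot nerveMask,pniMask logical matrices (post-thresholding, the PNI mask
#'   before size filtering).
#' @slot nerveComponents,pniComponents [ComponentSet-class] audit artifacts.
#' @slot retained,removed component tables split by the size filter.
#' @slot config the [DecisionConfig-class] used.
#' @export
setClass("DecisionResult",
  representation(
    nerves = "data.frame", nerveMask = "matrix", pniMask = "matrix",
    nerveComponents = "ComponentSet", pniComponents = "ComponentSet",
    retained = "data.frame", removed = "data.frame", config = "DecisionConfig"))

# ---------------------------------------------------------------------------
# Calibration
# ---------------------------------------------------------------------------

#' Size-filter calibration
#'
#' Holds a sample of irregular-component areas, the significance level and
#' the nearest-rank cutoff derived from them. Removing all components with
#' area at or below the cutoff removes at least a fraction `1 - alpha` of the
#' calibration sample.
#'
#' @slot sampleAreasPx2 observed component areas (pixel^2).
#' @slot alpha retained upper-tail fraction in (0, 1); 0.10 retains the
#'   largest 10% of irregular components.
#' @slot cutoffPx2 the resulting cutoff; always a member of the sample.
#' @export
setClass("SizeFilterCalibration",
  representation(sampleAreasPx2 = "numeric", alpha = "numeric", cutoffPx2 = "numeric"),
  validity = function(object) {
    if (length(object@sampleAreasPx2) == 0) return("sample must be non-empty")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0, 1)")
    if (!object@cutoffPx2 %in% object@sampleAreasPx2) {
      return("cutoff must be a member of the sample (nearest-rank quantile)")
    }
    TRUE
  }
)

#' Physical pixel geometry
#'
#' @slot mpp microns per pixel (default 0.23).
#' @slot cellDiameterUm mean tumor-cell diameter in microns (default 13.5,
#'   the measured mean for malignant squamous cells, cited range 13 +/- 2).
#' @export
setClass("PixelGeometry",
  representation(mpp = "numeric", cellDiameterUm = "numeric"),
  validity = function(object) {
    if (object@mpp <= 0 || object@cellDiameterUm <= 0) {
      return("mpp and cellDiameterUm must be > 0")
    }
    TRUE
  }
)

#' Construct a PixelGeometry
#' @param mpp microns per pixel.
#' @param cellDiameterUm mean tumor-cell diameter (um).
#' @return A [PixelGeometry-class] object.
#' @export
PixelGeometry <- function(mpp = 0.23, cellDiameterUm = 13.5) {
  new("PixelGeometry", mpp = mpp, cellDiameterUm = cellDiameterUm)
}

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

#' Confusion matrix at nerve-structure or slide level
#'
#' @slot tp,fp,fn,tn non-negative counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
      return("tp, fp, fn, tn must be non-negative integers")
    }
    TRUE
  }
)

#' Construct a ConfusionMatrix
#' @param tp,fp,fn,tn counts of true/false positives/negatives.
#' @return A [ConfusionMatrix-class] object.
#' @examples
#' cm <- ConfusionMatrix(tp = 106, fp = 3, fn = 8, tn = 15)
#' metrics(cm)
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Sensitivity / specificity / accuracy report
#'
#' Percentages are stored at full precision; the display convention
#' (see [displayedMetrics()]) truncates to 2 decimals. An undefined metric
#' (zero denominator) is `NA`, never 0.
#'
#' @slot sensitivity,specificity,accuracy percentages in \[0, 100\] or `NA`.
#' @export
setClass("MetricsReport",
  representation(sensitivity = "numeric", specificity = "numeric", accuracy = "numeric"))

# ---------------------------------------------------------------------------
# Patch grids
# ---------------------------------------------------------------------------

#' Patch grid over a source image
#'
#' @slot patchSize,stride length-2 (h, w).
#' @slot origins integer matrix of 0-based (row, col) patch origins.
#' @slot imageSize length-2 (h, w) of the source image.
#' @export
setClass("PatchGrid",
  representation(patchSize = "numeric", stride = "numeric",
                 origins = "matrix", imageSize = "numeric"))

# ---------------------------------------------------------------------------
# Segmentation model
# ---------------------------------------------------------------------------

#' Configuration of the multi-resolution segmentation network
#'
#' The network maps an RGB tile (values in \[0, 1\]) to a single-channel
#' probability map of the same spatial size through parallel branches held
#' at full, 1/2, 1/4, ... resolution. Resolution is decreased by stride-2
#' convolution and recovered by bilinear upsampling; the final stage
#' concatenates all branch outputs at full resolution ahead of a sigmoid
#' head.
#'
#' @slot inputSize length-2 (H, W); both divisible by 2^(nBranches - 1).
#' @slot baseChannels channels of the full-resolution branch (study value 32).
#' @slot nBranches number of resolution branches (study value 4).
#' @slot stemABlocks number of conv + batch-norm + ReLU blocks in the stem.
#' @slot stemBottlenecks number of bottleneck blocks after the stem.
#' @slot branchBlocks number of basic residual blocks per branch.
#' @export
setClass("SegModelConfig",
  representation(inputSize = "numeric", baseChannels = "numeric",
                 nBranches = "numeric", stemABlocks = "numeric",
                 stemBottlenecks = "numeric", branchBlocks = "numeric"),
  validity = function(object) {
    msg <- character(0)
    sz <- object@inputSize
    if (length(sz) != 2 || any(sz < 4) || any(sz != floor(sz))) {
      msg <- c(msg, "inputSize must be two positive integers")
    }
    if (object@baseChannels < 1) msg <- c(msg, "baseChannels must be >= 1")
    if (object@nBranches < 1) msg <- c(msg, "nBranches must be >= 1")
    div <- 2^(object@nBranches - 1)
    if (length(sz) == 2 && (sz[1] %% div != 0 || sz[2] %% div != 0)) {
      msg <- c(msg, sprintf("inputSize must be divisible by 2^(nBranches-1) = %d", div))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SegModelConfig
#'
#' The full-size profile (`baseChannels = 32`, `nBranches = 4`,
#' 256 x 256 input) mirrors the study network; the reduced desk-scale
#' profile used in the tests is `SegModelConfig(inputSize = c(128, 128),
#' baseChannels = 8, nBranches = 2)`.
#'
#' @param inputSize,baseChannels,nBranches,stemABlocks,stemBottlenecks,branchBlocks
#'   see [SegModelConfig-class].
#' @return A [SegModelConfig-class] object.
#' @export
SegModelConfig <- function(inputSize = c(256, 256), baseChannels = 32,
                           nBranches = 4, stemABlocks = 2,
                           stemBottlenecks = 4, branchBlocks = 2) {
  new("SegModelConfig", inputSize = as.numeric(inputSize),
      baseChannels = baseChannels, nBranches = nBranches,
      stemABlocks = stemABlocks, stemBottlenecks = stemBottlenecks,
      branchBlocks = branchBlocks)
}

#' Photometric/geometric augmentation configuration
#'
#' @slot brightnessDelta additive brightness jitter, drawn from
#'   +/- this value (study value 0.30).
#' @slot saturationRange,contrastRange multiplicative ranges containing 1.
#' @slot hflip,vflip whether random horizontal/vertical flips are enabled.
#' @slot cropRescaleTo output (h, w) after random crop and rescale.
#' @slot augmentationFactor nominal dataset-size multiplier realized by
#'   sampling with replacement (study value 2048).
#' @export
setClass("AugmentationConfig",
  representation(brightnessDelta = "numeric", saturationRange = "numeric",
                 contrastRange = "numeric", hflip = "logical", vflip = "logical",
                 cropRescaleTo = "numeric", augmentationFactor = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@brightnessDelta < 0) msg <- c(msg, "brightnessDelta must be >= 0")
    for (f in c("saturationRange", "contrastRange")) {
      r <- slot(object, f)
      if (length(r) != 2 || r[1] > 1 || r[2] < 1) {
        msg <- c(msg, paste(f, "must be a range containing 1.0"))
      }
    }
    if (object@augmentationFactor < 1) msg <- c(msg, "augmentationFactor must be >= 1")
    if (length(object@cropRescaleTo) != 2 || any(object@cropRescaleTo < 1)) {
      msg <- c(msg, "cropRescaleTo must be two positive integers")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AugmentationConfig
#' @param brightnessDelta,saturationRange,contrastRange,hflip,vflip,cropRescaleTo,augmentationFactor
#'   see [AugmentationConfig-class].
#' @return An [AugmentationConfig-class] object.
#' @export
AugmentationConfig <- function(brightnessDelta = 0.30,
                               saturationRange = c(0.7, 1.3),
                               contrastRange = c(0.7, 1.3),
                               hflip = TRUE, vflip = TRUE,
                               cropRescaleTo = c(256, 256),
                               augmentationFactor = 2048) {
  new("AugmentationConfig", brightnessDelta = brightnessDelta,
      saturationRange = as.numeric(saturationRange),
      contrastRange = as.numeric(contrastRange), hflip = hflip, vflip = vflip,
      cropRescaleTo = as.numeric(cropRescaleTo),
      augmentationFactor = augmentationFactor)
}

#' Training configuration
#'
#' @slot optimizer only `"adam"` is implemented.
#' @slot initialLr initial learning rate (study value 0.001).
#' @slot maxSteps maximum optimization steps.
#' @slot convergenceLoss stop once the mean-squared-error loss falls to this
#'   value. The study's models converged at 0.0082 (nerve) and 0.0077 (PNI);
#'   those values are metadata of the original training runs, not defaults.
#' @slot batchSize mini-batch size.
#' @slot seed RNG seed for initialization and batch sampling.
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", initialLr = "numeric",
                 maxSteps = "numeric", convergenceLoss = "numeric",
                 batchSize = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@optimizer != "adam") msg <- c(msg, "only the adam optimizer is implemented")
    if (object@initialLr <= 0) msg <- c(msg, "initialLr must be > 0")
    if (object@convergenceLoss <= 0) msg <- c(msg, "convergenceLoss must be > 0")
    if (!is_count(object@maxSteps) || object@maxSteps < 1) msg <- c(msg, "maxSteps must be >= 1")
    if (!is_count(object@batchSize) || object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a TrainConfig
#' @param optimizer,initialLr,maxSteps,convergenceLoss,batchSize,seed
#'   see [TrainConfig-class].
#' @return A [TrainConfig-class] object.
#' @export
TrainConfig <- function(optimizer = "adam", initialLr = 0.001,
                        maxSteps = 500, convergenceLoss = 0.008,
                        batchSize = 4, seed = 1) {
  new("TrainConfig", optimizer = optimizer, initialLr = initialLr,
      maxSteps = maxSteps, convergenceLoss = convergenceLoss,
      batchSize = batchSize, seed = seed)
}

#' Segmentation model handle
#'
#' Parameters, batch-norm running statistics and the optimizer state live in
#' the `env` environment so that training updates in place; use
#' [saveModel()] / [loadModel()] for a serializable checkpoint.
#'
#' @slot config the [SegModelConfig-class].
#' @slot env environment holding `params`, `stats` and `step`.
#' @export
setClass("SegModel",
  representation(config = "SegModelConfig", env = "environment"))

#' Sweep of the size-filter cutoff
#'
#' @slot table data.frame with one row per cutoff: `cutoff_px2`, the pooled
#'   confusion counts and full-precision `sensitivity`, `specificity`,
#'   `accuracy` percentages.
#' @export
setClass("SweepResult", representation(table = "data.frame"))
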