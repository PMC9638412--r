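# Reading and writing the formats the pipeline touches: TIFF/PNG images,
# binary masks, 16-bit probability maps, JSON annotation records, patch
# grids and CSV timing tables.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stopf("unsupported image format '%s' (use TIFF or PNG)", ext)
}

# Read an image as a numeric array scaled to [0, 1] plus its integer bit
# range, independent of container.
read_image_raw <- function(path) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  if (img_format(path) == "tiff") {
    v <- tiff::readTIFF(path, as.is = TRUE)
    bps <- if (max(v) > 255) 16L else 8L
    list(values = v / (2^bps - 1), maxval = 2^bps - 1)
  } else {
    v <- png::readPNG(path)
    list(values = v, maxval = 255L)
  }
}

#' Read a binary mask from a TIFF/PNG file
#'
#' Single-channel images are used as stored; RGB images are converted to
#' grayscale by Rec. 601 luminance. A pixel is foreground when its stored
#' 8-bit value is at least `foregroundThreshold`.
#'
#' @param path TIFF or PNG file.
#' @param foregroundThreshold integer threshold on the stored 8-bit value.
#' @return logical matrix.
#' @export
readMask <- function(path, foregroundThreshold = 128) {
  img <- read_image_raw(path)
  v <- img$values
  if (length(dim(v)) == 3) {
    assert_that(dim(v)[3] %in% c(2, 3, 4), "unsupported channel count in '%s'", path)
    v <- if (dim(v)[3] == 2) v[, , 1] else rgb_luminance(v)
  }
  v * 255 >= foregroundThreshold
}

#' Write a binary mask as an 8-bit image (0/255)
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param path output path; `.png` or `.tif(f)`.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask))
  if (img_format(path) == "tiff") {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}

#' Write a probability map as 16-bit grayscale TIFF
#'
#' Values are quantized with round-half-up to `round(p * 65535)`, so the
#' round trip has per-pixel error at most 1/65535 and Otsu thresholds
#' computed on a reloaded map are unaffected at 256-bin resolution.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix in \[0, 1\].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeProbabilityMap <- function(map, path) {
  v <- as_map_matrix(map)
  assert_that(all(v >= 0 & v <= 1), "probability values must lie in [0, 1]")
  assert_that(img_format(path) == "tiff", "probability maps are stored as TIFF")
  q <- floor(v * 65535 + 0.5)  # round half up
  # writeTIFF truncates when quantizing; offset by half a quantum so the
  # stored integer is exactly q.
  tiff::writeTIFF(pmin((q + 0.5) / 65535, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit probability map written by [writeProbabilityMap()]
#'
#' @param path TIFF path.
#' @param mpp microns per pixel to attach.
#' @param channel map channel (`"nerve"` or `"pni"`).
#' @return A [ProbabilityMap-class].
#' @export
readProbabilityMap <- function(path, mpp = 0.23, channel = c("nerve", "pni")) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  v <- tiff::readTIFF(path, as.is = TRUE)
  assert_that(length(dim(v)) == 2, "probability maps must be single-channel")
  ProbabilityMap(v / 65535, mpp = mpp, channel = match.arg(channel))
}

#' Build a patch grid covering an image
#'
#' Patch origins lie at multiples of the stride; where a final patch would
#' overrun the image, its origin is clamped so that the patch ends exactly
#' at the image edge. Every pixel is covered at least once for any
#' `stride <= patchSize`, exactly once when `stride == patchSize` divides
#' the image evenly.
#'
#' @param imageH,imageW image dimensions in pixels.
#' @param patchSize patch (h, w); a scalar is used for both.
#' @param stride step (h, w); defaults to `patchSize` (no overlap).
#' @return A [PatchGrid-class] with 0-based origins.
#' @examples
#' makePatchGrid(5000, 5000, 1024)  # 25 patches, last origin 3976
#' @export
makePatchGrid <- function(imageH, imageW, patchSize, stride = patchSize) {
  patchSize <- rep(as.numeric(patchSize), length.out = 2)
  stride <- rep(as.numeric(stride), length.out = 2)
  assert_that(all(patchSize >= 1) && all(stride >= 1),
              "patchSize and stride must be positive")
  assert_that(all(stride <= patchSize), "stride must not exceed patchSize")
  assert_that(patchSize[1] <= imageH && patchSize[2] <= imageW,
              "patch of %d x %d does not fit a %d x %d image",
              patchSize[1], patchSize[2], imageH, imageW)
  axis_origins <- function(n, p, s) {
    o <- seq(0, n - p, by = s)
    if (o[length(o)] + p < n) o <- c(o, n - p)
    o
  }
  ro <- axis_origins(imageH, patchSize[1], stride[1])
  co <- axis_origins(imageW, patchSize[2], stride[2])
  origins <- as.matrix(expand.grid(row = ro, col = co))
  mode(origins) <- "integer"
  new("PatchGrid", patchSize = patchSize, stride = stride,
      origins = origins, imageSize = c(imageH, imageW))
}

ANNOTATION_LABELS <- c("PNI", "normal_nerve")
ANNOTATION_SOURCES <- c("algorithm", "human")
ANNOTATION_FIELDS <- c("slide_id", "label", "source", "r0", "c0", "r1", "c1")

validate_annotations <- function(df) {
  assert_that(all(ANNOTATION_FIELDS %in% names(df)),
              "annotation records need fields: %s",
              paste(ANNOTATION_FIELDS, collapse = ", "))
  extra <- setdiff(names(df), ANNOTATION_FIELDS)
  assert_that(length(extra) == 0, "unknown annotation fields: %s",
              paste(extra, collapse = ", "))
  assert_that(all(df$label %in% ANNOTATION_LABELS),
              "label must be one of: %s", paste(ANNOTATION_LABELS, collapse = ", "))
  assert_that(all(df$source %in% ANNOTATION_SOURCES),
              "source must be one of: %s", paste(ANNOTATION_SOURCES, collapse = ", "))
  assert_that(all(df$r0 < df$r1) && all(df$c0 < df$c1),
              "bounding boxes must satisfy r0 < r1 and c0 < c1 (half-open)")
  df[, ANNOTATION_FIELDS]
}

#' Write annotation records as JSON
#'
#' Records are labeled rectangles: half-open 0-based bounding boxes with a
#' class label (`PNI` / `normal_nerve`) and provenance
#' (`algorithm` / `human`).
#'
#' @param records data.frame with columns `slide_id`, `label`, `source`,
#'   `r0`, `c0`, `r1`, `c1`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(records, path) {
  if (nrow(records) > 0) records <- validate_annotations(records)
  jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read annotation records from JSON
#'
#' @param path JSON file holding an array of annotation objects.
#' @return data.frame of validated records (possibly 0 rows).
#' @export
readAnnotations <- function(path) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0 || (is.data.frame(df) && nrow(df) == 0)) {
    return(data.frame(slide_id = character(0), label = character(0),
                      source = character(0), r0 = numeric(0), c0 = numeric(0),
                      r1 = numeric(0), c1 = numeric(0)))
  }
  assert_that(is.data.frame(df), "annotation file must hold an array of objects")
  validate_annotations(df)
}

#' Read a diagnostic-time table
#'
#' @param path CSV with columns `slide_id`, `t_without_sec`, `t_with_sec`
#'   (an optional `reader` column distinguishes pathologists).
#' @return data.frame.
#' @export
readTimingTable <- function(path) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "t_without_sec", "t_with_sec")
  assert_that(all(need %in% names(df)),
              "timing table needs columns: %s", paste(need, collapse = ", "))
  df
}
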