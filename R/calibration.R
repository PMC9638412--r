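# Size-filter calibration and pixel-area <-> cell-count conversion.

#' Calibrate the size-filter cutoff from irregular-component areas
#'
#' Nearest-rank empirical quantile: the areas are sorted ascending and the
#' element at rank `ceiling((1 - alpha) * n)` (1-based) is returned, so the
#' cutoff is always an observed component area. Paired with the size
#' filter's `area <= cutoff` removal rule this removes at least a fraction
#' `1 - alpha` of the calibration sample -- exactly `(1 - alpha) * n`
#' components when that product is integral and the areas are distinct.
#' At `alpha = 0.10` the filter discards 90% of the irregular components;
#' the reference clinical calibration gave 21,632 px^2 at `alpha = 0.10`
#' and 36,864 px^2 at `alpha = 0.05`.
#'
#' @param sampleAreasPx2 numeric vector of component areas in pixel^2.
#' @param alpha retained upper-tail fraction, in (0, 1).
#' @return A [SizeFilterCalibration-class]; the cutoff is in `@cutoffPx2`.
#' @examples
#' calibrateCutoff(1:100, alpha = 0.10)@cutoffPx2  # 90
#' @export
calibrateCutoff <- function(sampleAreasPx2, alpha = 0.10) {
  assert_that(length(sampleAreasPx2) > 0, "calibration sample must be non-empty")
  assert_that(all(is.finite(sampleAreasPx2)) && all(sampleAreasPx2 >= 0),
              "component areas must be finite and >= 0")
  assert_that(length(alpha) == 1 && alpha > 0 && alpha < 1,
              "alpha must lie in (0, 1)")
  n <- length(sampleAreasPx2)
  rank <- ceiling((1 - alpha) * n)
  cutoff <- sort(sampleAreasPx2)[rank]
  new("SizeFilterCalibration", sampleAreasPx2 = as.numeric(sampleAreasPx2),
      alpha = alpha, cutoffPx2 = cutoff)
}

#' Convert a pixel area to an equivalent tumor-cell count
#'
#' Cells are treated as circles of diameter `cellDiameterUm`:
#' `cells = area_px2 * mpp^2 / (pi * (cellDiameterUm / 2)^2)`.
#' At the reference geometry (0.23 um/px, 13.5 um cells) the calibrated
#' 21,632 px^2 cutoff corresponds to ~8 cells -- the detection limit of the
#' rule flow -- and 40,000 px^2 to 14-15 cells.
#'
#' @param areaPx2 area in pixel^2 (vectorized).
#' @param geom a [PixelGeometry-class].
#' @return list with `cells` (float count) and `rounded`
#'   (round-half-up integer).
#' @examples
#' pixelsToCells(21632, PixelGeometry())$rounded  # 8
#' @export
pixelsToCells <- function(areaPx2, geom = PixelGeometry()) {
  validObject(geom)
  assert_that(all(areaPx2 >= 0), "area must be >= 0")
  cellAreaUm2 <- pi * (geom@cellDiameterUm / 2)^2
  cells <- areaPx2 * geom@mpp^2 / cellAreaUm2
  list(cells = cells, rounded = as.integer(round_half_up(cells)))
}

#' Convert a cell count to the equivalent pixel area
#'
#' Exact algebraic inverse of [pixelsToCells()], used e.g. to size planted
#' tumor nests in the synthetic generator.
#'
#' @param nCells number of cells (>= 0, vectorized).
#' @param geom a [PixelGeometry-class].
#' @return area in pixel^2.
#' @examples
#' cellsToPixels(8)  # ~21.6k px^2 at the reference geometry
#' @export
cellsToPixels <- function(nCells, geom = PixelGeometry()) {
  validObject(geom)
  assert_that(all(nCells >= 0), "cell count must be >= 0")
  nCells * pi * (geom@cellDiameterUm / 2)^2 / geom@mpp^2
}
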