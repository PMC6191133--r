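#' Detect uncapped comb cells as circles
#'
#' Runs the Hough gradient circle transform on a lightness raster.
#' Uncapped cells show up as dark, nearly circular lumens against brighter
#' wax walls, giving strong, radially coherent gradients; the transform
#' votes each strong edge pixel along its gradient line and keeps
#' accumulator peaks with at least `accumulatorThreshold` votes. Lowering
#' the threshold (see [stepSensitivity()]) admits more circles.
#'
#' When at least two circles are found, the median nearest-neighbour
#' spacing and the effective subtraction radius are filled in via
#' [medianNeighbourSpacing()] and [effectiveCellRadius()]; otherwise both
#' are `NA` (flagged unavailable, not an error).
#'
#' Radius bounds, minimum centre separation and the accumulator geometry
#' default from the expected lattice pitch: bounds
#' `[0.25, 0.75] * pitch`, separation `0.6 * pitch`, with the pitch prior
#' defaulting to `width / 80`. The detection is fully deterministic.
#'
#' @param luminance numeric width x height matrix of L* values in
#'   \[0, 100\] (see [toLuminance()]).
#' @param params a [DetectionParams-class]; see [detectionParams()].
#' @param photoId identifier stored in the result.
#' @return A [CellDetectionSet-class].
#' @examples
#' flat <- matrix(50, 120, 100)
#' nDetections(detectUncappedCells(flat, detectionParams()))  # 0
#' @export
detectUncappedCells <- function(luminance, params = detectionParams(),
                                photoId = "photo") {
  validObject(params)
  if (!is.matrix(luminance) || !is.numeric(luminance))
    invalidImage("expected a single-channel numeric matrix")
  if (length(luminance) == 0L)
    invalidImage("empty raster")
  W <- nrow(luminance); H <- ncol(luminance)

  pitch <- params@expectedPitchPx
  if (is.na(pitch)) pitch <- W / 80
  minR <- params@minRadiusPx
  maxR <- params@maxRadiusPx
  if (is.na(minR)) minR <- 0.25 * pitch
  if (is.na(maxR)) maxR <- 0.75 * pitch
  minDist <- params@minCentreDistancePx
  if (is.na(minDist)) minDist <- 0.6 * pitch
  if (!(minR >= 0 && minR < maxR))
    cqStop("invalid_params", "derived radius bounds are degenerate")
  minR <- max(minR, 1)

  res <- hough_circles_cpp(luminance * 2.55,   # L* 0..100 -> 8-bit scale
                           params@edgeThreshold,
                           params@accumulatorThreshold,
                           minR, maxR, minDist)
  cc <- res$centres
  spacing <- if (nrow(cc) >= 2) medianNeighbourSpacing(cc) else NA_real_
  effR <- if (is.na(spacing)) NA_real_ else effectiveCellRadius(spacing, params)
  new("CellDetectionSet",
      photoId = as.character(photoId),
      centres = cc,
      detectedRadii = as.numeric(res$radii),
      accumulatorThresholdUsed = params@accumulatorThreshold,
      medianSpacingPx = spacing,
      effectiveRadiusPx = effR,
      imageDim = c(W, H))
}

#' Adjust detector sensitivity by one operator step
#'
#' The accumulator threshold moves by `thresholdStep` in the requested
#' direction: a lower threshold detects more circles. The threshold never
#' drops below 1; stepping past that floor clamps with a warning.
#'
#' @param params a [DetectionParams-class].
#' @param direction `"increase_detections"` (threshold down) or
#'   `"decrease_detections"` (threshold up).
#' @return the adjusted [DetectionParams-class].
#' @examples
#' p <- stepSensitivity(detectionParams(), "increase_detections")
#' accumulatorThreshold(p)  # 18
#' @export
stepSensitivity <- function(params,
                            direction = c("increase_detections",
                                          "decrease_detections")) {
  validObject(params)
  direction <- match.arg(direction)
  delta <- if (direction == "increase_detections") -params@thresholdStep
           else params@thresholdStep
  thr <- params@accumulatorThreshold + delta
  if (thr < 1) {
    cqWarn("threshold_clamped",
           sprintf("accumulator threshold clamped to 1 (requested %g)", thr))
    thr <- 1
  }
  params@accumulatorThreshold <- thr
  params
}

#' Median nearest-neighbour spacing of a point set
#'
#' For every centre, the Euclidean distance to its closest other centre is
#' taken; the median of those distances estimates the comb lattice pitch
#' (on a hexagonal lattice every nearest-neighbour distance equals the
#' centre-to-centre cell spacing). An even count averages the two middle
#' values.
#'
#' @param centres numeric n x 2 matrix (n >= 2) or a
#'   [CellDetectionSet-class].
#' @return spacing in the units of the coordinates (px).
#' @export
medianNeighbourSpacing <- function(centres) {
  if (is(centres, "CellDetectionSet")) centres <- centres(centres)
  cc <- as.matrix(centres)
  if (nrow(cc) < 2L)
    cqStop("insufficient_detections",
           "at least 2 centres are needed to estimate a spacing")
  d <- as.matrix(stats::dist(cc))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

#' Effective subtraction radius from the lattice spacing
#'
#' The per-cell disc removed from capped regions has radius
#' `cellInflate * radiusFraction * medianSpacingPx`. With the default
#' `radiusFraction = 0.5` the nearest-neighbour spacing is treated as a
#' cell diameter; `radiusFraction = 1` uses the spacing directly as the
#' radius. `cellInflate` is the operator's calibration for wall thickness
#' and apiary-specific cell size.
#'
#' @param medianSpacingPx positive spacing in px.
#' @param params a [DetectionParams-class].
#' @return radius in px.
#' @examples
#' effectiveCellRadius(18, detectionParams())                    # 9
#' effectiveCellRadius(18, detectionParams(cellInflate = 1.1))   # 9.9
#' @export
effectiveCellRadius <- function(medianSpacingPx, params = detectionParams()) {
  validObject(params)
  if (!is.numeric(medianSpacingPx) || length(medianSpacingPx) != 1L ||
      is.na(medianSpacingPx) || medianSpacingPx <= 0)
    cqStop("domain", "medianSpacingPx must be a positive number")
  params@cellInflate * params@radiusFraction * medianSpacingPx
}
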