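#' @import methods
NULL

.scalarOk <- function(x) is.numeric(x) && length(x) == 1L && !is.nan(x)

#' Tunable parameters of the uncapped-cell detector
#'
#' Holds every knob of the Hough-gradient detection pass. The defaults are
#' the operating point recommended for typical frame photographs: an
#' edge-detector threshold of 200 (on the 8-bit gradient scale), a
#' circle-centre accumulator threshold starting at 20, and a sensitivity
#' step of 2 that the operator applies via [stepSensitivity()] until the
#' segmentation looks right.
#'
#' Radius bounds, the minimum centre separation and the expected lattice
#' pitch may be left `NA`; [detectUncappedCells()] then derives them from
#' the expected pitch (itself defaulting to image width / 80): radius
#' search bounds `[0.25, 0.75] * pitch`, minimum centre distance
#' `0.6 * pitch`.
#'
#' @slot edgeThreshold numeric(1), > 0. Gradient-magnitude threshold for a
#'   pixel to count as an edge (8-bit scale, L1 norm of the Sobel pair).
#' @slot accumulatorThreshold numeric(1), >= 1. Minimum centre votes for a
#'   circle candidate; lower values detect more circles.
#' @slot thresholdStep numeric(1), >= 1. Amount added/subtracted per
#'   operator sensitivity adjustment.
#' @slot cellInflate numeric(1), > 0. Multiplicative inflation applied to
#'   the subtraction radius; calibrates for wall thickness and cell-size
#'   variation between apiaries.
#' @slot radiusFraction numeric(1) in (0, 1]. Factor converting the median
#'   nearest-neighbour spacing (approximately one cell diameter) to the
#'   base subtraction radius. The default 0.5 treats the spacing as a
#'   diameter; 1.0 uses it directly as a radius.
#' @slot minRadiusPx,maxRadiusPx numeric(1) pixel bounds for candidate
#'   circle radii (`NA` = derive from expected pitch).
#' @slot minCentreDistancePx numeric(1) minimum distance between accepted
#'   centres (`NA` = derive).
#' @slot expectedPitchPx numeric(1) prior centre-to-centre cell spacing
#'   (`NA` = image width / 80).
#'
#' @seealso [detectionParams()] for the user-facing constructor.
#' @export
setClass("DetectionParams", representation(
  edgeThreshold = "numeric",
  accumulatorThreshold = "numeric",
  thresholdStep = "numeric",
  cellInflate = "numeric",
  radiusFraction = "numeric",
  minRadiusPx = "numeric",
  maxRadiusPx = "numeric",
  minCentreDistancePx = "numeric",
  expectedPitchPx = "numeric"
))

setValidity("DetectionParams", function(object) {
  msgs <- character()
  for (s in c("edgeThreshold", "accumulatorThreshold", "thresholdStep",
              "cellInflate", "radiusFraction", "minRadiusPx", "maxRadiusPx",
              "minCentreDistancePx", "expectedPitchPx"))
    if (!.scalarOk(slot(object, s)))
      msgs <- c(msgs, sprintf("'%s' must be a numeric scalar", s))
  if (length(msgs)) return(msgs)
  if (object@edgeThreshold <= 0) msgs <- c(msgs, "edgeThreshold must be > 0")
  if (object@accumulatorThreshold < 1) msgs <- c(msgs, "accumulatorThreshold must be >= 1")
  if (object@thresholdStep < 1) msgs <- c(msgs, "thresholdStep must be >= 1")
  if (object@cellInflate <= 0) msgs <- c(msgs, "cellInflate must be > 0")
  if (!(object@radiusFraction > 0 && object@radiusFraction <= 1))
    msgs <- c(msgs, "radiusFraction must lie in (0, 1]")
  if (!is.na(object@minRadiusPx) && !is.na(object@maxRadiusPx) &&
      !(object@minRadiusPx >= 0 && object@minRadiusPx < object@maxRadiusPx))
    msgs <- c(msgs, "need 0 <= minRadiusPx < maxRadiusPx")
  if (!is.na(object@expectedPitchPx) && object@expectedPitchPx <= 0)
    msgs <- c(msgs, "expectedPitchPx must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct detection parameters
#'
#' @param edgeThreshold voting-edge threshold (default 200).
#' @param accumulatorThreshold initial circle-centre accumulator threshold
#'   (default 20).
#' @param thresholdStep sensitivity increment (default 2).
#' @param cellInflate inflation factor on the subtraction radius (default 1).
#' @param radiusFraction fraction of the median spacing used as base radius
#'   (default 0.5).
#' @param minRadiusPx,maxRadiusPx,minCentreDistancePx,expectedPitchPx
#'   optional pixel-geometry overrides; `NA` means derive from the expected
#'   pitch at detection time.
#' @return A [DetectionParams-class] object.
#' @examples
#' p <- detectionParams()
#' edgeThreshold(p)
#' @export
detectionParams <- function(edgeThreshold = 200,
                            accumulatorThreshold = 20,
                            thresholdStep = 2,
                            cellInflate = 1.0,
                            radiusFraction = 0.5,
                            minRadiusPx = NA_real_,
                            maxRadiusPx = NA_real_,
                            minCentreDistancePx = NA_real_,
                            expectedPitchPx = NA_real_) {
  new("DetectionParams",
      edgeThreshold = as.numeric(edgeThreshold),
      accumulatorThreshold = as.numeric(accumulatorThreshold),
      thresholdStep = as.numeric(thresholdStep),
      cellInflate = as.numeric(cellInflate),
      radiusFraction = as.numeric(radiusFraction),
      minRadiusPx = as.numeric(minRadiusPx),
      maxRadiusPx = as.numeric(maxRadiusPx),
      minCentreDistancePx = as.numeric(minCentreDistancePx),
      expectedPitchPx = as.numeric(expectedPitchPx))
}

#' Detected uncapped cells of one photograph
#'
#' Result container of [detectUncappedCells()]: circle centres and radii,
#' the accumulator threshold in force, and the derived lattice statistics
#' (median nearest-neighbour spacing, effective subtraction radius). The
#' spacing slots are `NA` when fewer than two circles were found.
#'
#' @slot photoId character(1) identifier of the source photograph.
#' @slot centres numeric matrix, one row per detection, columns `x`, `y`
#'   (0-based pixel coordinates, origin top-left, positions refer to pixel
#'   centres).
#' @slot detectedRadii numeric, per-circle radius reported by the detector.
#' @slot accumulatorThresholdUsed numeric(1).
#' @slot medianSpacingPx numeric(1) median distance from each circle to its
#'   nearest neighbour; `NA` if < 2 detections.
#' @slot effectiveRadiusPx numeric(1) = cellInflate * radiusFraction *
#'   medianSpacingPx; `NA` if < 2 detections.
#' @slot imageDim integer(2) width, height of the analysed raster.
#' @export
setClass("CellDetectionSet", representation(
  photoId = "character",
  centres = "matrix",
  detectedRadii = "numeric",
  accumulatorThresholdUsed = "numeric",
  medianSpacingPx = "numeric",
  effectiveRadiusPx = "numeric",
  imageDim = "integer"
))

setValidity("CellDetectionSet", function(object) {
  msgs <- character()
  cc <- object@centres
  if (!is.numeric(cc) || ncol(cc) != 2L)
    return("'centres' must be a numeric matrix with columns x, y")
  if (nrow(cc) != length(object@detectedRadii))
    msgs <- c(msgs, "one radius per centre required")
  if (length(object@imageDim) == 2L && !anyNA(object@imageDim) && nrow(cc) > 0) {
    w <- object@imageDim[1]; h <- object@imageDim[2]
    if (any(cc[, 1] < -0.5 | cc[, 1] > w - 0.5 | cc[, 2] < -0.5 | cc[, 2] > h - 0.5))
      msgs <- c(msgs, "all centres must lie within the image bounds")
  }
  if (nrow(cc) >= 2 && !is.na(object@medianSpacingPx) && object@medianSpacingPx <= 0)
    msgs <- c(msgs, "medianSpacingPx must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Operator annotation of one frame photograph
#'
#' The two pieces of human input the method requires: the four inner
#' corners of the frame (for physical calibration) and the polygons drawn
#' around contiguous capped regions, labelled `capped_brood` or
#' `capped_honey`.
#'
#' @slot photoId character(1).
#' @slot innerCorners numeric 4x2 matrix, corners ordered clockwise from
#'   top-left, 0-based pixel coordinates.
#' @slot regions list of `list(label =, polygon =)` entries; each polygon a
#'   numeric n x 2 matrix (n >= 3) forming a simple polygon.
#' @export
setClass("FrameAnnotation", representation(
  photoId = "character",
  innerCorners = "matrix",
  regions = "list"
))

.REGION_LABELS <- c("capped_brood", "capped_honey")

setValidity("FrameAnnotation", function(object) {
  msgs <- character()
  ic <- object@innerCorners
  if (!is.numeric(ic) || !identical(dim(ic), c(4L, 2L)))
    return("'innerCorners' must be a numeric 4 x 2 matrix")
  if (!isSimplePolygon(ic))
    msgs <- c(msgs, "inner corners must form a simple quadrilateral")
  for (i in seq_along(object@regions)) {
    r <- object@regions[[i]]
    if (!is.list(r) || !all(c("label", "polygon") %in% names(r))) {
      msgs <- c(msgs, sprintf("region %d must have 'label' and 'polygon'", i))
      next
    }
    if (!r$label %in% .REGION_LABELS)
      msgs <- c(msgs, sprintf("region %d label '%s' not in {%s}", i, r$label,
                              paste(.REGION_LABELS, collapse = ", ")))
    p <- r$polygon
    if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L)
      msgs <- c(msgs, sprintf("region %d polygon must be an n>=3 x 2 matrix", i))
    else if (!isSimplePolygon(p))
      msgs <- c(msgs, sprintf("region %d polygon is self-intersecting", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a frame annotation
#'
#' @param photoId photograph identifier.
#' @param innerCorners 4x2 matrix of inner-frame corners, clockwise from
#'   top-left.
#' @param regions list of `list(label = "capped_brood"|"capped_honey",
#'   polygon = <n x 2 matrix>)`.
#' @return A [FrameAnnotation-class].
#' @export
frameAnnotation <- function(photoId, innerCorners, regions = list()) {
  new("FrameAnnotation", photoId = as.character(photoId),
      innerCorners = .asPointMatrix(innerCorners),
      regions = lapply(regions, function(r)
        list(label = as.character(r$label), polygon = .asPointMatrix(r$polygon))))
}

.asPointMatrix <- function(p) {
  m <- as.matrix(p)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' Per-photograph measurement result
#'
#' Output of [quantifyFrame()]: the inner-frame area and, per capped-region
#' label, the gross polygon area, the number of detected uncapped cells
#' inside, the subtracted area and the resulting net capped area in px^2
#' and cm^2.
#'
#' @slot photoId character(1).
#' @slot innerAreaPx2,innerAreaCm2 numeric(1).
#' @slot labels data.frame with one row per label and columns
#'   `label`, `grossPolygonAreaPx2`, `nUncappedInside`, `subtractedAreaPx2`,
#'   `cappedAreaPx2`, `cappedAreaCm2`, `cappedFractionOfInner`.
#' @export
setClass("FrameMeasurement", representation(
  photoId = "character",
  innerAreaPx2 = "numeric",
  innerAreaCm2 = "numeric",
  labels = "data.frame"
))

setValidity("FrameMeasurement", function(object) {
  msgs <- character()
  lb <- object@labels
  need <- c("label", "grossPolygonAreaPx2", "nUncappedInside",
            "subtractedAreaPx2", "cappedAreaPx2", "cappedAreaCm2",
            "cappedFractionOfInner")
  if (!all(need %in% names(lb))) return("labels table is missing columns")
  if (object@innerAreaPx2 < 0) msgs <- c(msgs, "innerAreaPx2 must be >= 0")
  num <- lb[setdiff(need, "label")]
  if (nrow(lb) && any(as.matrix(num) < 0))
    msgs <- c(msgs, "all areas and counts must be >= 0")
  if (nrow(lb) && any(lb$cappedAreaPx2 > lb$grossPolygonAreaPx2 + 1e-9))
    msgs <- c(msgs, "cappedAreaPx2 must not exceed grossPolygonAreaPx2")
  if (nrow(lb) && any(lb$cappedFractionOfInner > 1 + 1e-9))
    msgs <- c(msgs, "cappedFractionOfInner must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Parameterization of a synthetic comb photograph
#'
#' Full analytic description of a rendered frame image: lattice geometry,
#' region layout, luminance levels, illumination gradient and noise. The
#' same spec with the same seed always renders the identical image.
#'
#' @slot widthPx,heightPx integer image size.
#' @slot pitchPx numeric centre-to-centre cell spacing.
#' @slot wallWidthPx numeric bright wall ring width around uncapped lumens.
#' @slot lumenRadiusPx numeric true dark-interior radius; must be
#'   < pitchPx / 2.
#' @slot innerMarginPx numeric border between image edge and comb.
#' @slot regionLayout list of `list(label, polygon)` with label in
#'   `capped_brood`, `capped_honey`, `uncapped`. Uncapped polygons may
#'   overlap capped ones; uncapped wins cell-wise (holes in a brood or
#'   honey patch).
#' @slot wallL,lumenL,capMeanL numeric luminance levels on the L* 0-100
#'   scale.
#' @slot capTextureSd numeric per-pixel texture sd in capped regions.
#' @slot illuminationDirectionDeg,illuminationAmplitude numeric linear
#'   luminance ramp: direction (degrees, 0 = rightward) and peak deviation
#'   (L* units) at the image border.
#' @slot noiseSd numeric Gaussian pixel noise sd (L* units).
#' @slot jitterSd numeric per-cell centre jitter sd (px).
#' @slot seed integer RNG seed; controls jitter, texture and noise only.
#' @export
setClass("CombSceneSpec", representation(
  widthPx = "integer", heightPx = "integer",
  pitchPx = "numeric", wallWidthPx = "numeric", lumenRadiusPx = "numeric",
  innerMarginPx = "numeric",
  regionLayout = "list",
  wallL = "numeric", lumenL = "numeric",
  capMeanL = "numeric", capTextureSd = "numeric",
  illuminationDirectionDeg = "numeric", illuminationAmplitude = "numeric",
  noiseSd = "numeric", jitterSd = "numeric",
  seed = "integer"
))

.SCENE_LABELS <- c(.REGION_LABELS, "uncapped")

setValidity("CombSceneSpec", function(object) {
  msgs <- character()
  if (object@widthPx < 1L || object@heightPx < 1L)
    msgs <- c(msgs, "image size must be positive")
  if (object@pitchPx <= 0) msgs <- c(msgs, "pitchPx must be > 0")
  if (object@lumenRadiusPx <= 0 || object@lumenRadiusPx >= object@pitchPx / 2)
    msgs <- c(msgs, "need 0 < lumenRadiusPx < pitchPx / 2")
  for (L in c(object@wallL, object@lumenL, object@capMeanL))
    if (L < 0 || L > 100) msgs <- c(msgs, "luminance levels must be in [0, 100]")
  if (object@capTextureSd < 0 || object@noiseSd < 0 || object@jitterSd < 0)
    msgs <- c(msgs, "sd parameters must be >= 0")
  for (i in seq_along(object@regionLayout)) {
    r <- object@regionLayout[[i]]
    if (!r$label %in% .SCENE_LABELS) {
      msgs <- c(msgs, sprintf("layout label '%s' unknown", r$label)); next
    }
    p <- r$polygon
    if (!is.numeric(p) || ncol(p) != 2 || nrow(p) < 3 || !isSimplePolygon(p)) {
      msgs <- c(msgs, sprintf("layout polygon %d invalid", i)); next
    }
    if (any(p[, 1] < 0 | p[, 1] > object@widthPx - 1 |
            p[, 2] < 0 | p[, 2] > object@heightPx - 1))
      msgs <- c(msgs, sprintf("layout polygon %d leaves the image", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Analytic ground truth of a synthetic comb scene
#'
#' @slot uncappedCentres numeric n x 2 matrix of true uncapped-cell centres
#'   (post-jitter).
#' @slot trueCappedAreaPx2 named numeric: per capped label, polygon area
#'   minus the lumen discs of uncapped cells whose centre falls inside.
#' @slot innerCorners numeric 4 x 2 matrix.
#' @slot pitchPx numeric(1).
#' @export
setClass("GroundTruth", representation(
  uncappedCentres = "matrix",
  trueCappedAreaPx2 = "numeric",
  innerCorners = "matrix",
  pitchPx = "numeric"
))
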