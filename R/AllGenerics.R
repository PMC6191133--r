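#' @rdname DetectionParams-class
#' @param object,x a \code{DetectionParams}
#' @export
setGeneric("edgeThreshold", function(x) standardGeneric("edgeThreshold"))
#' @rdname DetectionParams-class
#' @export
setGeneric("accumulatorThreshold", function(x) standardGeneric("accumulatorThreshold"))
#' @rdname DetectionParams-class
#' @export
setGeneric("thresholdStep", function(x) standardGeneric("thresholdStep"))
#' @rdname DetectionParams-class
#' @export
setGeneric("cellInflate", function(x) standardGeneric("cellInflate"))
#' @rdname DetectionParams-class
#' @export
setGeneric("radiusFraction", function(x) standardGeneric("radiusFraction"))

#' @rdname CellDetectionSet-class
#' @param x,object a \code{CellDetectionSet}
#' @export
setGeneric("centres", function(x) standardGeneric("centres"))
#' @rdname CellDetectionSet-class
#' @export
setGeneric("detectedRadii", function(x) standardGeneric("detectedRadii"))
#' @rdname CellDetectionSet-class
#' @export
setGeneric("nDetections", function(x) standardGeneric("nDetections"))
#' @rdname CellDetectionSet-class
#' @export
setGeneric("medianSpacing", function(x) standardGeneric("medianSpacing"))
#' @rdname CellDetectionSet-class
#' @export
setGeneric("effectiveRadius", function(x) standardGeneric("effectiveRadius"))
#' @rdname CellDetectionSet-class
#' @export
setGeneric("photoId", function(x) standardGeneric("photoId"))

#' @rdname FrameAnnotation-class
#' @param x a \code{FrameAnnotation}
#' @export
setGeneric("innerCorners", function(x) standardGeneric("innerCorners"))
#' @rdname FrameAnnotation-class
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname FrameMeasurement-class
#' @param x a \code{FrameMeasurement}
#' @export
setGeneric("innerArea", function(x, units = c("px2", "cm2")) standardGeneric("innerArea"))
#' @rdname FrameMeasurement-class
#' @export
setGeneric("cappedAreas", function(x) standardGeneric("cappedAreas"))

setMethod("edgeThreshold", "DetectionParams", function(x) x@edgeThreshold)
setMethod("accumulatorThreshold", "DetectionParams", function(x) x@accumulatorThreshold)
setMethod("thresholdStep", "DetectionParams", function(x) x@thresholdStep)
setMethod("cellInflate", "DetectionParams", function(x) x@cellInflate)
setMethod("radiusFraction", "DetectionParams", function(x) x@radiusFraction)

setMethod("centres", "CellDetectionSet", function(x) x@centres)
setMethod("detectedRadii", "CellDetectionSet", function(x) x@detectedRadii)
setMethod("nDetections", "CellDetectionSet", function(x) nrow(x@centres))
setMethod("medianSpacing", "CellDetectionSet", function(x) x@medianSpacingPx)
setMethod("effectiveRadius", "CellDetectionSet", function(x) x@effectiveRadiusPx)
setMethod("photoId", "CellDetectionSet", function(x) x@photoId)
setMethod("photoId", "FrameAnnotation", function(x) x@photoId)
setMethod("photoId", "FrameMeasurement", function(x) x@photoId)

setMethod("innerCorners", "FrameAnnotation", function(x) x@innerCorners)
setMethod("regions", "FrameAnnotation", function(x) x@regions)
setMethod("innerCorners", "GroundTruth", function(x) x@innerCorners)

setMethod("innerArea", "FrameMeasurement", function(x, units = c("px2", "cm2")) {
  units <- match.arg(units)
  if (units == "px2") x@innerAreaPx2 else x@innerAreaCm2
})

setMethod("cappedAreas", "FrameMeasurement", function(x) x@labels)

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams\n",
      sprintf("  edge threshold        : %g\n", object@edgeThreshold),
      sprintf("  accumulator threshold : %g (step %g)\n",
              object@accumulatorThreshold, object@thresholdStep),
      sprintf("  cell inflate          : %g, radius fraction %g\n",
              object@cellInflate, object@radiusFraction),
      sprintf("  radius bounds [px]    : [%s, %s], min centre dist %s, pitch prior %s\n",
              format(object@minRadiusPx), format(object@maxRadiusPx),
              format(object@minCentreDistancePx), format(object@expectedPitchPx)),
      sep = "")
})

setMethod("show", "CellDetectionSet", function(object) {
  cat(sprintf("CellDetectionSet '%s': %d circles (accumulator threshold %g)\n",
              object@photoId, nrow(object@centres),
              object@accumulatorThresholdUsed))
  cat(sprintf("  median neighbour spacing: %s px, effective radius: %s px\n",
              format(object@medianSpacingPx, digits = 4),
              format(object@effectiveRadiusPx, digits = 4)))
})

setMethod("show", "FrameAnnotation", function(object) {
  labs <- vapply(object@regions, `[[`, "", "label")
  cat(sprintf("FrameAnnotation '%s': %d region(s)", object@photoId,
              length(object@regions)))
  if (length(labs)) cat(" [", paste(labs, collapse = ", "), "]", sep = "")
  cat("\n")
})

setMethod("show", "FrameMeasurement", function(object) {
  cat(sprintf("FrameMeasurement '%s': inner area %.0f px^2 (%.1f cm^2)\n",
              object@photoId, object@innerAreaPx2, object@innerAreaCm2))
  if (nrow(object@labels)) print(object@labels, row.names = FALSE)
})

setMethod("show", "CombSceneSpec", function(object) {
  cat(sprintf("CombSceneSpec %dx%d px, pitch %g px, %d region(s), seed %d\n",
              object@widthPx, object@heightPx, object@pitchPx,
              length(object@regionLayout), object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d uncapped centres; capped areas [px^2]: %s\n",
              nrow(object@uncappedCentres),
              paste(sprintf("%s=%.0f", names(object@trueCappedAreaPx2),
                            object@trueCappedAreaPx2), collapse = ", ")))
})

#' Flatten a FrameMeasurement to one data.frame row per label
#'
#' @param x a [FrameMeasurement-class]
#' @param row.names,optional,... passed conventions of the generic; unused.
#' @return data.frame with the photo-level columns repeated per label row.
#' @export
as.data.frame.FrameMeasurement <- function(x, row.names = NULL, optional = FALSE, ...) {
  lb <- x@labels
  if (!nrow(lb)) {
    lb <- lb[NA_integer_, , drop = FALSE][0, , drop = FALSE]
  }
  data.frame(photo_id = rep(x@photoId, nrow(lb)),
             inner_area_px2 = rep(x@innerAreaPx2, nrow(lb)),
             inner_area_cm2 = rep(x@innerAreaCm2, nrow(lb)),
             lb, row.names = row.names, check.names = FALSE)
}
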