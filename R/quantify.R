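#' Quantify capped brood and honey on one annotated photograph
#'
#' Combines the operator annotation (inner-frame corners, capped-region
#' polygons) with the detected uncapped cells: for each region the gross
#' polygon area is reduced by one effective-radius disc per uncapped cell
#' whose centre lies inside ([cappedArea()]), clamped at zero per polygon.
#' Multiple polygons sharing a label are summed. Pixel areas are converted
#' to cm^2 through the inner-frame quadrilateral ([scaleToPhysical()]).
#'
#' Overlapping polygons of different labels are accepted but flagged with
#' a warning, since the per-label areas then no longer partition the comb
#' surface.
#'
#' @param annotation a [FrameAnnotation-class].
#' @param detections a [CellDetectionSet-class] for the same photograph.
#' @param innerFrameCm2 physical area of the inner frame in cm^2.
#' @return A [FrameMeasurement-class] with one labels-table row per label
#'   present in the annotation (both labels always reported; absent labels
#'   get zero areas).
#' @export
quantifyFrame <- function(annotation, detections, innerFrameCm2) {
  stopifnot(is(annotation, "FrameAnnotation"),
            is(detections, "CellDetectionSet"))
  validObject(annotation)
  if (!identical(photoId(annotation), photoId(detections)))
    cqWarn("photo_mismatch",
           sprintf("annotation '%s' paired with detections '%s'",
                   photoId(annotation), photoId(detections)))
  labs <- vapply(regions(annotation), `[[`, "", "label")
  bad <- setdiff(labs, .REGION_LABELS)
  if (length(bad))
    cqStop("invalid_annotation",
           paste("unknown region label(s):", paste(bad, collapse = ", ")))

  innerPx2 <- polygonArea(innerCorners(annotation))
  if (innerPx2 <= 0) invalidGeometry("degenerate inner quadrilateral")
  innerCm2 <- scaleToPhysical(innerPx2, innerCorners(annotation), innerFrameCm2)

  .checkOverlaps(annotation)

  rows <- lapply(.REGION_LABELS, function(lab) {
    polys <- lapply(regions(annotation)[labs == lab], `[[`, "polygon")
    gross <- 0; nIn <- 0L; net <- 0
    for (p in polys) {
      gross <- gross + polygonArea(p)
      nIn <- nIn + countCellsInRegion(detections, p)
      net <- net + cappedArea(p, detections)
    }
    data.frame(label = lab,
               grossPolygonAreaPx2 = gross,
               nUncappedInside = nIn,
               subtractedAreaPx2 = gross - net,
               cappedAreaPx2 = net,
               cappedAreaCm2 = scaleToPhysical(net, innerCorners(annotation),
                                               innerFrameCm2),
               cappedFractionOfInner = net / innerPx2)
  })
  new("FrameMeasurement",
      photoId = photoId(annotation),
      innerAreaPx2 = innerPx2,
      innerAreaCm2 = innerCm2,
      labels = do.call(rbind, rows))
}

## warn when polygons of different labels overlap (bounding-box prefilter,
## then edge intersection or containment)
.checkOverlaps <- function(annotation) {
  rg <- regions(annotation)
  n <- length(rg)
  if (n < 2L) return(invisible())
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (rg[[i]]$label == rg[[j]]$label) next
    a <- rg[[i]]$polygon; b <- rg[[j]]$polygon
    if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
        max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) next
    if (any(pointInPolygon(a, b)) || any(pointInPolygon(b, a))) {
      cqWarn("overlapping_regions",
             sprintf("regions %d (%s) and %d (%s) overlap",
                     i, rg[[i]]$label, j, rg[[j]]$label))
      return(invisible())
    }
  }
  invisible()
}
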