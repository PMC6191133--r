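#' Read a frame photograph
#'
#' Thin wrapper over `EBImage::readImage` that enforces the 3-channel RGB
#' contract of the pipeline (greyscale or RGBA input is rejected, not
#' silently promoted).
#'
#' @param path PNG or JPEG file.
#' @return an `EBImage::Image`, colour mode, 3 channels, values in
#'   \[0, 1\].
#' @export
readFrameImage <- function(path) {
  if (!file.exists(path)) invalidImage(sprintf("no such file: %s", path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    invalidImage(sprintf("%s: expected an 8-bit RGB image (3 channels), got %s",
                         path, paste(d, collapse = "x")))
  img
}

## generic "KEY = value" parser; '#' starts a comment
.readKeyValue <- function(path) {
  if (!file.exists(path)) cqStop("io", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      cqStop("io", sprintf("malformed config line: '%s'", ln))
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

.CONFIG_KEYS <- c(EDGE_THRESHOLD = "edgeThreshold",
                  ACC_THRESHOLD = "accumulatorThreshold",
                  THRESHOLD_INC = "thresholdStep",
                  CELL_INFLATE = "cellInflate",
                  RADIUS_FRACTION = "radiusFraction",
                  MIN_RADIUS = "minRadiusPx",
                  MAX_RADIUS = "maxRadiusPx",
                  MIN_DIST = "minCentreDistancePx",
                  EXPECTED_PITCH = "expectedPitchPx")

#' Read detection parameters from a plain-text config file
#'
#' The file holds `KEY = value` lines (`#` comments allowed); recognised
#' keys are `EDGE_THRESHOLD`, `ACC_THRESHOLD`, `THRESHOLD_INC` (the
#' sensitivity step), `CELL_INFLATE`, `RADIUS_FRACTION`, `MIN_RADIUS`,
#' `MAX_RADIUS`, `MIN_DIST` and `EXPECTED_PITCH`. Missing keys keep the
#' [detectionParams()] defaults; unknown keys are ignored (they may belong
#' to the run config).
#'
#' @param path config file.
#' @return A [DetectionParams-class].
#' @export
readDetectionConfig <- function(path) {
  kv <- .readKeyValue(path)
  args <- list()
  for (key in names(.CONFIG_KEYS)) {
    if (!is.null(kv[[key]])) {
      v <- suppressWarnings(as.numeric(kv[[key]]))
      if (is.na(v)) cqStop("io", sprintf("%s: non-numeric value '%s'", key, kv[[key]]))
      args[[.CONFIG_KEYS[[key]]]] <- v
    }
  }
  do.call(detectionParams, args)
}

#' Read mass constants from a plain-text config file
#'
#' Keys: `HONEY_MASS_PER_CM2`, `BROOD_MASS_PER_CM2`, `EMPTY_FRAME_MASS`
#' (g and g/cm^2). All three are required; there are no defaults.
#'
#' @param path config file.
#' @return a [massConstants()] object.
#' @export
readMassConstants <- function(path) {
  kv <- .readKeyValue(path)
  need <- c("HONEY_MASS_PER_CM2", "BROOD_MASS_PER_CM2", "EMPTY_FRAME_MASS")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    cqStop("io", paste("missing mass constant(s):", paste(miss, collapse = ", ")))
  massConstants(as.numeric(kv$HONEY_MASS_PER_CM2),
                as.numeric(kv$BROOD_MASS_PER_CM2),
                as.numeric(kv$EMPTY_FRAME_MASS))
}

#' Read / write frame annotations as JSON
#'
#' One JSON document per photo:
#' `{"photo_id": ..., "inner_corners": [[x,y] x 4],`
#' `"regions": [{"label": ..., "polygon": [[x,y], ...]}, ...]}`
#' with 0-based pixel coordinates.
#'
#' @param path JSON file.
#' @return [readAnnotation()]: a [FrameAnnotation-class].
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) cqStop("io", sprintf("no such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  regions <- list()
  if (!is.null(doc$regions) && length(doc$regions)) {
    polys <- if (is.data.frame(doc$regions)) {
      lapply(seq_len(nrow(doc$regions)), function(i)
        list(label = doc$regions$label[i], polygon = doc$regions$polygon[[i]]))
    } else {
      doc$regions
    }
    regions <- polys
  }
  frameAnnotation(doc$photo_id, doc$inner_corners, regions)
}

#' @rdname readAnnotation
#' @param annotation a [FrameAnnotation-class] to serialize.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "FrameAnnotation"))
  doc <- list(
    photo_id = photoId(annotation),
    inner_corners = unname(innerCorners(annotation)),
    regions = lapply(regions(annotation), function(r)
      list(label = r$label, polygon = unname(r$polygon)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export detections to CSV
#'
#' Columns: `photo_id`, `x`, `y`, `detected_radius`,
#' `accumulator_threshold_used` (RFC-4180, UTF-8, header row).
#'
#' @param detections a [CellDetectionSet-class].
#' @param path output CSV path.
#' @export
writeDetectionsCsv <- function(detections, path) {
  stopifnot(is(detections, "CellDetectionSet"))
  cc <- centres(detections)
  df <- data.frame(
    photo_id = rep(photoId(detections), nrow(cc)),
    x = cc[, 1], y = cc[, 2],
    detected_radius = detectedRadii(detections),
    accumulator_threshold_used = rep(detections@accumulatorThresholdUsed, nrow(cc)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeDetectionsCsv
#' @param imageDim integer(2) width, height of the source image (stored in
#'   the reconstructed object).
#' @return [readDetectionsCsv()]: a [CellDetectionSet-class] (spacing and
#'   effective radius recomputed with `params`).
#' @param params [DetectionParams-class] used to recompute the effective
#'   radius.
#' @export
readDetectionsCsv <- function(path, imageDim, params = detectionParams()) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  cc <- .asPointMatrix(cbind(df$x, df$y))
  spacing <- if (nrow(cc) >= 2) medianNeighbourSpacing(cc) else NA_real_
  new("CellDetectionSet",
      photoId = if (nrow(df)) as.character(df$photo_id[1]) else "unknown",
      centres = cc,
      detectedRadii = as.numeric(df$detected_radius),
      accumulatorThresholdUsed =
        if (nrow(df)) df$accumulator_threshold_used[1] else NA_real_,
      medianSpacingPx = spacing,
      effectiveRadiusPx = if (is.na(spacing)) NA_real_
                          else effectiveCellRadius(spacing, params),
      imageDim = as.integer(imageDim))
}
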