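## Synthetic comb photographs with analytic ground truth.
##
## The renderer emulates what matters to the detector: a hexagonal cell
## lattice, dark near-circular uncapped lumens ringed by brighter wax
## walls, granular capped texture, a smooth illumination gradient and
## sensor noise. It does not attempt photometric realism (bees, pollen
## colour, specular wax highlights); see the methods vignette for what
## that implies about test coverage.

## run expr under a private RNG stream; the caller's .Random.seed is
## restored afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a synthetic comb scene specification
#'
#' Defaults describe a typical flash photograph of one Langstroth frame
#' side at roughly 3.3 px/mm: an 18 px cell pitch (5.4 mm cells), 6 px
#' lumen radius, 2 px wall, bright walls (L* 72), dark lumens (L* 20),
#' mid-toned granular cappings (L* 52 +/- 5), a lateral illumination ramp
#' of +/- 8 L* units and mild sensor noise. Cell centres are jittered by
#' 0.4 px (comb drawn on embossed foundation is highly regular).
#'
#' @param widthPx,heightPx image size in px.
#' @param pitchPx centre-to-centre cell spacing in px.
#' @param wallWidthPx,lumenRadiusPx cell geometry in px.
#' @param innerMarginPx border between image edge and comb in px.
#' @param regionLayout list of `list(label, polygon)`; labels
#'   `capped_brood`, `capped_honey`, `uncapped`. Uncapped polygons may
#'   overlap capped ones: a cell whose centre falls in an uncapped polygon
#'   is always rendered as an open lumen.
#' @param wallL,lumenL,capMeanL,capTextureSd luminance levels, L* 0-100.
#' @param illuminationDirectionDeg,illuminationAmplitude linear luminance
#'   ramp (degrees; peak L* deviation at the border).
#' @param noiseSd Gaussian pixel noise sd (L* units).
#' @param jitterSd per-cell centre jitter sd (px).
#' @param seed integer seed controlling jitter, texture and noise.
#' @return A [CombSceneSpec-class].
#' @export
combSceneSpec <- function(widthPx = 1200L, heightPx = 800L,
                          pitchPx = 18, wallWidthPx = 2, lumenRadiusPx = 6,
                          innerMarginPx = 40,
                          regionLayout = list(),
                          wallL = 72, lumenL = 20,
                          capMeanL = 52, capTextureSd = 5,
                          illuminationDirectionDeg = 0,
                          illuminationAmplitude = 8,
                          noiseSd = 1.5, jitterSd = 0.4,
                          seed = 0L) {
  new("CombSceneSpec",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      pitchPx = as.numeric(pitchPx), wallWidthPx = as.numeric(wallWidthPx),
      lumenRadiusPx = as.numeric(lumenRadiusPx),
      innerMarginPx = as.numeric(innerMarginPx),
      regionLayout = lapply(regionLayout, function(r)
        list(label = as.character(r$label), polygon = .asPointMatrix(r$polygon))),
      wallL = as.numeric(wallL), lumenL = as.numeric(lumenL),
      capMeanL = as.numeric(capMeanL), capTextureSd = as.numeric(capTextureSd),
      illuminationDirectionDeg = as.numeric(illuminationDirectionDeg),
      illuminationAmplitude = as.numeric(illuminationAmplitude),
      noiseSd = as.numeric(noiseSd), jitterSd = as.numeric(jitterSd),
      seed = as.integer(seed))
}

## un-jittered hexagonal lattice sites (flat rows, odd rows offset by
## pitch/2, row spacing pitch * sqrt(3)/2) inside the comb margin
.latticeSites <- function(spec) {
  m <- spec@innerMarginPx
  W <- spec@widthPx; H <- spec@heightPx
  rowSp <- spec@pitchPx * sqrt(3) / 2
  ys <- seq(m, H - 1 - m, by = rowSp)
  out <- vector("list", length(ys))
  for (j in seq_along(ys)) {
    off <- if (j %% 2 == 0) spec@pitchPx / 2 else 0
    xs <- seq(m + off, W - 1 - m, by = spec@pitchPx)
    out[[j]] <- cbind(x = xs, y = rep(ys[j], length(xs)))
  }
  do.call(rbind, out)
}

.innerCornersOf <- function(spec) {
  m <- spec@innerMarginPx
  W <- spec@widthPx; H <- spec@heightPx
  .asPointMatrix(rbind(c(m, m), c(W - 1 - m, m),
                       c(W - 1 - m, H - 1 - m), c(m, H - 1 - m)))
}

## logical W x H mask of pixels (pixel centres) inside a polygon,
## evaluated only over the polygon's bounding box
.polyMask <- function(polygon, W, H) {
  mask <- matrix(FALSE, W, H)
  x0 <- max(0L, floor(min(polygon[, 1]))); x1 <- min(W - 1L, ceiling(max(polygon[, 1])))
  y0 <- max(0L, floor(min(polygon[, 2]))); y1 <- min(H - 1L, ceiling(max(polygon[, 2])))
  if (x1 < x0 || y1 < y0) return(mask)
  gx <- x0:x1; gy <- y0:y1
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- pointInPolygon(pts, polygon)
  mask[cbind(pts[, 1] + 1L, pts[, 2] + 1L)] <- inside
  mask
}

## paint a filled disc into canvas (by reference semantics: returns canvas)
.paintDisc <- function(canvas, cx, cy, r, value) {
  W <- nrow(canvas); H <- ncol(canvas)
  x0 <- max(0L, floor(cx - r)); x1 <- min(W - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(H - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(canvas)
  gx <- x0:x1; gy <- y0:y1
  d2 <- outer((gx - cx)^2, (gy - cy)^2, `+`)
  sel <- d2 <= r^2
  sub <- canvas[gx + 1L, gy + 1L, drop = FALSE]
  sub[sel] <- value
  canvas[gx + 1L, gy + 1L] <- sub
  canvas
}

#' Render a synthetic comb photograph with its ground truth
#'
#' Cells whose (jittered) centre lies in an `uncapped` layout polygon are
#' drawn as dark lumens ringed by bright wall; pixels of `capped_brood` /
#' `capped_honey` polygons get granular capping texture; everything else
#' is bare wall. An illumination ramp and Gaussian noise are applied last,
#' and the grey luminance image is lifted to 8-bit sRGB by replicating the
#' matching grey level into the three channels. Identical spec and seed
#' give a bit-identical image.
#'
#' The ground truth records every uncapped centre and, per capped label,
#' the analytic capped area: polygon area minus one lumen disc per
#' uncapped centre inside the polygon.
#'
#' @param spec a [CombSceneSpec-class].
#' @return `list(image = <EBImage Image, RGB>, truth = <GroundTruth>)`.
#' @export
generateCombImage <- function(spec) {
  validObject(spec)
  W <- spec@widthPx; H <- spec@heightPx
  labs <- vapply(spec@regionLayout, `[[`, "", "label")
  uncappedPolys <- lapply(spec@regionLayout[labs == "uncapped"], `[[`, "polygon")
  cappedIdx <- which(labs %in% .REGION_LABELS)

  sites <- .latticeSites(spec)
  out <- .withSeed(spec@seed, {
    jit <- matrix(stats::rnorm(2 * nrow(sites), 0, spec@jitterSd), ncol = 2)
    centres <- sites + jit
    texture <- matrix(stats::rnorm(W * H, 0, spec@capTextureSd), W, H)
    noise <- matrix(stats::rnorm(W * H, 0, spec@noiseSd), W, H)
    list(centres = centres, texture = texture, noise = noise)
  })
  centres <- out$centres

  inUncapped <- rep(FALSE, nrow(centres))
  for (p in uncappedPolys)
    inUncapped <- inUncapped | pointInPolygon(centres, p)
  uncapped <- centres[inUncapped, , drop = FALSE]

  canvas <- matrix(spec@wallL, W, H)
  for (i in cappedIdx) {
    mask <- .polyMask(spec@regionLayout[[i]]$polygon, W, H)
    canvas[mask] <- spec@capMeanL + out$texture[mask]
  }
  rOuter <- spec@lumenRadiusPx + spec@wallWidthPx
  for (k in seq_len(nrow(uncapped))) {
    canvas <- .paintDisc(canvas, uncapped[k, 1], uncapped[k, 2], rOuter, spec@wallL)
    canvas <- .paintDisc(canvas, uncapped[k, 1], uncapped[k, 2],
                         spec@lumenRadiusPx, spec@lumenL)
  }

  if (spec@illuminationAmplitude != 0) {
    th <- spec@illuminationDirectionDeg * pi / 180
    s <- outer((0:(W - 1)) * cos(th), (0:(H - 1)) * sin(th), `+`)
    rng <- range(s)
    sn <- if (diff(rng) > 0) 2 * (s - rng[1]) / diff(rng) - 1 else s * 0
    canvas <- canvas + spec@illuminationAmplitude * sn
  }
  canvas <- pmin(100, pmax(0, canvas + out$noise))

  grey <- round(.srgbGreyFromL(canvas) * 255) / 255   # 8-bit quantization
  img <- EBImage::Image(array(grey, dim = c(W, H, 3)), colormode = "Color")

  areas <- c(capped_brood = 0, capped_honey = 0)
  lumenA <- pi * spec@lumenRadiusPx^2
  for (i in cappedIdx) {
    p <- spec@regionLayout[[i]]$polygon
    nIn <- if (nrow(uncapped)) sum(pointInPolygon(uncapped, p)) else 0L
    areas[labs[i]] <- areas[labs[i]] + polygonArea(p) - nIn * lumenA
  }

  truth <- new("GroundTruth",
               uncappedCentres = .asPointMatrix(uncapped),
               trueCappedAreaPx2 = areas,
               innerCorners = .innerCornersOf(spec),
               pitchPx = spec@pitchPx)
  list(image = img, truth = truth)
}

#' Canonical synthetic test scene
#'
#' A fixed 1200 x 800 px layout used throughout the test suite: one capped
#' brood rectangle and one capped honey rectangle, each perforated by
#' three small uncapped "hole" polygons (emerged or skipped cells), plus
#' one large open band of uncapped cells. Only the noise, texture and
#' jitter realizations change with the seed; the layout is constant.
#'
#' @param seed integer seed.
#' @return A [CombSceneSpec-class].
#' @export
defaultFixture <- function(seed = 0L) {
  rect <- function(x0, y0, x1, y1)
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  layout <- list(
    list(label = "capped_brood", polygon = rect(100, 100, 560, 400)),
    list(label = "capped_honey", polygon = rect(640, 420, 1100, 720)),
    list(label = "uncapped",     polygon = rect(100, 480, 560, 720)),
    ## holes inside the brood patch
    list(label = "uncapped",     polygon = rect(180, 150, 260, 230)),
    list(label = "uncapped",     polygon = rect(360, 200, 430, 280)),
    list(label = "uncapped",     polygon = rect(200, 300, 270, 360)),
    ## holes inside the honey patch
    list(label = "uncapped",     polygon = rect(720, 470, 800, 550)),
    list(label = "uncapped",     polygon = rect(900, 560, 980, 640)),
    list(label = "uncapped",     polygon = rect(1000, 470, 1060, 530))
  )
  combSceneSpec(regionLayout = layout, seed = seed)
}

#' Detection parameters calibrated to a synthetic scene
#'
#' The calibration an operator performs on a preliminary sample of their
#' own photos, done analytically here because the scene geometry is known:
#' the expected pitch is the scene pitch, and `cellInflate` is set so the
#' effective subtraction radius (`cellInflate * radiusFraction * spacing`)
#' equals the true lumen radius.
#'
#' @param spec a [CombSceneSpec-class].
#' @param ... further arguments passed to [detectionParams()].
#' @return A [DetectionParams-class].
#' @export
fixtureDetectionParams <- function(spec, ...) {
  detectionParams(expectedPitchPx = spec@pitchPx,
                  cellInflate = 2 * spec@lumenRadiusPx / spec@pitchPx, ...)
}

#' Operator-style annotation of a synthetic scene
#'
#' Builds the [FrameAnnotation-class] a perfect operator would draw: the
#' scene's inner corners and its capped-region polygons (uncapped layout
#' polygons are not annotated; the operator never outlines open comb).
#'
#' @param spec a [CombSceneSpec-class].
#' @param photoId identifier for the annotation.
#' @return A [FrameAnnotation-class].
#' @export
sceneAnnotation <- function(spec, photoId = sprintf("synthetic_seed%d", spec@seed)) {
  labs <- vapply(spec@regionLayout, `[[`, "", "label")
  frameAnnotation(photoId,
                  .innerCornersOf(spec),
                  spec@regionLayout[labs %in% .REGION_LABELS])
}
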