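## Independent oracles and shared fixtures. Every oracle here deliberately
## uses a different algorithm from the package implementation it checks.

## CIELAB L* reference values computed with scikit-image rgb2lab
## (sRGB, D65) for 8-bit RGB triples; frozen.
SKIMAGE_LSTAR <- list(
  list(rgb = c(128, 128, 128), L = 53.585013),
  list(rgb = c(64, 64, 64),    L = 27.093414),
  list(rgb = c(192, 192, 192), L = 77.704364),
  list(rgb = c(50, 100, 150),  L = 41.205362),
  list(rgb = c(200, 30, 80),   L = 43.931543),
  list(rgb = c(10, 220, 140),  L = 77.958011),
  list(rgb = c(137, 90, 42),   L = 42.459053)
)

## exact signed-rank (V, two-sided p) by explicit expansion of all sign
## vectors with expand.grid -- independent of the package's bit/DP code
oracleSignedRank <- function(a, b) {
  d <- (b - a)[b - a != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allV <- as.vector(signs %*% r)
  pGE <- mean(allV >= V - 1e-12)
  pLE <- mean(allV <= V + 1e-12)
  list(V = V, p = min(1, 2 * min(pGE, pLE)))
}

## polygon area by fan triangulation from vertex 1 (valid for convex
## polygons: unsigned triangle areas add up)
oracleFanArea <- function(poly) {
  s <- 0
  for (i in 2:(nrow(poly) - 1)) {
    a <- poly[1, ]; b <- poly[i, ]; c <- poly[i + 1, ]
    s <- s + abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
  }
  s
}

## point-in-polygon by winding number (sum of signed angles) -- points on
## the boundary are resolved separately by a distance test
oracleInPolygon <- function(pt, poly, eps = 1e-9) {
  n <- nrow(poly)
  for (i in seq_len(n)) {   # boundary check
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ab <- b - a; t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    if (sum((pt - (a + t * ab))^2) <= eps^2) return(TRUE)
  }
  ang <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ] - pt; b <- poly[if (i == n) 1 else i + 1, ] - pt
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi
}

randomConvexPolygon <- function(nPts = 12, scale = 10) {
  repeat {
    pts <- matrix(runif(2 * nPts, 0, scale), ncol = 2)
    h <- chull(pts)
    if (length(h) >= 4) return(pts[h, , drop = FALSE])
  }
}

## minimal CellDetectionSet for geometry tests, bypassing the detector
makeDetections <- function(centres, effectiveRadiusPx = NA_real_,
                           photoId = "test", imageDim = c(1000L, 1000L)) {
  centres <- matrix(as.numeric(centres), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  spacing <- if (nrow(centres) >= 2) medianNeighbourSpacing(centres) else NA_real_
  methods::new("CellDetectionSet", photoId = photoId, centres = centres,
               detectedRadii = rep(NA_real_, nrow(centres)),
               accumulatorThresholdUsed = 20,
               medianSpacingPx = spacing,
               effectiveRadiusPx = effectiveRadiusPx,
               imageDim = as.integer(imageDim))
}

rectPoly <- function(x0, y0, x1, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))

## the full-scale canonical scene is expensive (~8 s per seed), so runs
## are computed once and shared across test files
.fixtureCache <- new.env(parent = emptyenv())

fixtureRun <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  spec <- defaultFixture(seed)
  sc <- generateCombImage(spec)
  det <- detectUncappedCells(toLuminance(sc$image), fixtureDetectionParams(spec),
                             photoId = sprintf("synthetic_seed%d", seed))
  ann <- sceneAnnotation(spec)
  res <- list(spec = spec, truth = sc$truth, image = sc$image,
              det = det, ann = ann)
  .fixtureCache[[key]] <- res
  res
}

## recall / precision of a detection run against true centres
## (match = within half a pitch)
matchScore <- function(det, truth) {
  tc <- truth@uncappedCentres
  dc <- centres(det)
  d <- as.matrix(stats::dist(rbind(tc, dc)))[seq_len(nrow(tc)),
                                             nrow(tc) + seq_len(nrow(dc))]
  tol <- 0.5 * truth@pitchPx
  list(recall = mean(apply(d, 1, min) <= tol),
       precision = mean(apply(d, 2, min) <= tol))
}
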