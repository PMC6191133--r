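test_that("lightness conversion hits the black and white anchors", {
  black <- array(0, dim = c(3, 2, 3))
  white <- array(1, dim = c(3, 2, 3))
  expect_equal(unname(toLuminance(black)), matrix(0, 3, 2))
  expect_equal(unname(toLuminance(white)), matrix(100, 3, 2))
  # 8-bit integer encoding accepted too
  white8 <- array(255, dim = c(2, 2, 3))
  expect_equal(max(abs(toLuminance(white8) - 100)), 0)
})

test_that("lightness agrees with an independent CIELAB implementation", {
  for (ref in SKIMAGE_LSTAR) {
    img <- array(rep(ref$rgb / 255, each = 4), dim = c(2, 2, 3))
    expect_lt(abs(toLuminance(img)[1, 1] - ref$L), 0.5)
  }
})

test_that("non-RGB input is rejected as an invalid image", {
  expect_error(toLuminance(array(0.5, dim = c(4, 4, 1))),
               class = "CombQuant_invalid_image")
  expect_error(toLuminance(matrix(0.5, 4, 4)),
               class = "CombQuant_invalid_image")
  expect_error(detectUncappedCells(matrix(numeric(0), 0, 0)),
               class = "CombQuant_invalid_image")
})

test_that("a gradient-free raster yields no detections", {
  det <- detectUncappedCells(matrix(50, 120, 100), detectionParams())
  expect_identical(nDetections(det), 0L)
  expect_true(is.na(medianSpacing(det)))
  expect_true(is.na(effectiveRadius(det)))
})

test_that("one dark disc on a flat background is found at its centre", {
  L <- matrix(70, 200, 160)
  d2 <- outer((0:199 - 99.5)^2, (0:159 - 79.5)^2, `+`)
  L[d2 <= 8^2] <- 20
  det <- detectUncappedCells(
    L, detectionParams(minRadiusPx = 4, maxRadiusPx = 12,
                       minCentreDistancePx = 10), photoId = "disc")
  expect_identical(nDetections(det), 1L)
  expect_lt(sqrt(sum((centres(det)[1, ] - c(99.5, 79.5))^2)), 2)
  expect_lt(abs(detectedRadii(det)[1] - 8), 1.5)
})

test_that("detection is deterministic for identical raster and params", {
  run <- fixtureRun(0)
  again <- detectUncappedCells(toLuminance(run$image),
                               fixtureDetectionParams(run$spec),
                               photoId = photoId(run$det))
  expect_identical(centres(run$det), centres(again))
  expect_identical(detectedRadii(run$det), detectedRadii(again))
  expect_identical(medianSpacing(run$det), medianSpacing(again))
})

test_that("detection count is non-increasing in the accumulator threshold", {
  spec <- combSceneSpec(
    widthPx = 400L, heightPx = 300L, innerMarginPx = 20,
    regionLayout = list(list(label = "uncapped",
                             polygon = rectPoly(30, 30, 370, 270))),
    seed = 1L)
  L <- toLuminance(generateCombImage(spec)$image)
  counts <- vapply(c(10, 20, 30), function(th)
    nDetections(detectUncappedCells(
      L, fixtureDetectionParams(spec, accumulatorThreshold = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("sensitivity stepping moves the threshold by the configured step", {
  p <- detectionParams()  # threshold 20, step 2
  expect_equal(accumulatorThreshold(stepSensitivity(p, "increase_detections")), 18)
  expect_equal(accumulatorThreshold(stepSensitivity(p, "decrease_detections")), 22)
  low <- detectionParams(accumulatorThreshold = 2)
  expect_warning(clamped <- stepSensitivity(low, "increase_detections"),
                 class = "CombQuant_threshold_clamped")
  expect_equal(accumulatorThreshold(clamped), 1)
})

test_that("median neighbour spacing matches direct computation", {
  expect_equal(medianNeighbourSpacing(rbind(c(0, 0), c(10, 0))), 10)
  # perfect hexagonal lattice: every nearest-neighbour distance = pitch
  spec <- combSceneSpec(widthPx = 300L, heightPx = 300L, jitterSd = 0)
  sites <- CombQuant:::.latticeSites(spec)
  expect_equal(medianNeighbourSpacing(sites), 18)
  # brute-force double-loop oracle on random points
  set.seed(42)
  pts <- matrix(runif(60, 0, 100), ncol = 2)
  nn <- vapply(seq_len(nrow(pts)), function(i)
    min(sqrt(rowSums((pts[-i, , drop = FALSE] -
                      matrix(pts[i, ], nrow(pts) - 1, 2, byrow = TRUE))^2))),
    0.0)
  expect_equal(medianNeighbourSpacing(pts), median(nn))
  expect_error(medianNeighbourSpacing(rbind(c(1, 1))),
               class = "CombQuant_insufficient_detections")
})

test_that("spacing estimate under centre jitter matches the simulation oracle", {
  # with iid 2D jitter of sd 1 px on an 18 px lattice, the min over ~6
  # jittered neighbour distances is biased low; the oracle below measures
  # that bias directly rather than assuming the estimate stays at 18
  spec <- combSceneSpec(widthPx = 500L, heightPx = 400L, jitterSd = 0)
  sites <- CombQuant:::.latticeSites(spec)
  set.seed(7)
  est <- replicate(5, {
    jit <- sites + matrix(rnorm(2 * nrow(sites), 0, 1), ncol = 2)
    medianNeighbourSpacing(jit)
  })
  expect_true(all(est > 15.5 & est < 18.5))   # near the pitch, biased low
  expect_lt(mean(est), 18)
})

test_that("spacing is invariant under rotation/translation, equivariant under scaling", {
  set.seed(11)
  pts <- matrix(runif(40, 0, 50), ncol = 2)
  s0 <- medianNeighbourSpacing(pts)
  expect_equal(medianNeighbourSpacing(pts + 13.7), s0)
  th <- 0.61
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(medianNeighbourSpacing(pts %*% R), s0)
  expect_equal(medianNeighbourSpacing(pts * 3.25), 3.25 * s0)
})

test_that("effective radius combines inflation, fraction and spacing", {
  expect_equal(effectiveCellRadius(18, detectionParams()), 9)
  expect_equal(effectiveCellRadius(18, detectionParams(cellInflate = 1.1)), 9.9)
  # literal convention: the spacing itself is the radius
  expect_equal(effectiveCellRadius(18, detectionParams(radiusFraction = 1)), 18)
  expect_error(effectiveCellRadius(0, detectionParams()),
               class = "CombQuant_domain")
  expect_error(effectiveCellRadius(-3, detectionParams()),
               class = "CombQuant_domain")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(detectionParams(edgeThreshold = 0))
  expect_error(detectionParams(accumulatorThreshold = 0))
  expect_error(detectionParams(thresholdStep = 0.5))
  expect_error(detectionParams(cellInflate = -1))
  expect_error(detectionParams(radiusFraction = 0))
  expect_error(detectionParams(radiusFraction = 1.2))
  expect_error(detectionParams(minRadiusPx = 9, maxRadiusPx = 4))
})
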