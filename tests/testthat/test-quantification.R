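test_that("shoelace area is exact on simple shapes, any vertex order", {
  sq <- rectPoly(0, 0, 1, 1)
  expect_equal(polygonArea(sq), 1)
  expect_equal(polygonArea(sq[4:1, ]), 1)  # reversed orientation
  expect_equal(polygonArea(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
})

test_that("shoelace area equals fan triangulation on random convex polygons", {
  set.seed(101)
  for (i in 1:100) {
    poly <- randomConvexPolygon()
    a <- polygonArea(poly)
    expect_lt(abs(a - oracleFanArea(poly)) / a, 1e-9)
  }
})

test_that("degenerate polygons raise invalid-geometry errors", {
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1))),
               class = "CombQuant_invalid_geometry")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(polygonArea(bowtie), class = "CombQuant_invalid_geometry")
  expect_error(pointInPolygon(c(0.5, 0.5), bowtie),
               class = "CombQuant_invalid_geometry")
})

test_that("point-in-polygon is boundary inclusive and matches the winding oracle", {
  sq <- rectPoly(0, 0, 1, 1)
  expect_true(pointInPolygon(c(0.5, 0.5), sq))
  expect_false(pointInPolygon(c(2, 2), sq))
  expect_true(pointInPolygon(c(1, 0.5), sq))   # on an edge
  expect_true(pointInPolygon(c(0, 0), sq))     # on a vertex

  set.seed(202)
  poly <- randomConvexPolygon(15, scale = 10)
  pts <- cbind(runif(500, -2, 12), runif(500, -2, 12))
  got <- pointInPolygon(pts, poly)
  want <- vapply(seq_len(500), function(i) oracleInPolygon(pts[i, ], poly), TRUE)
  expect_identical(got, want)
})

test_that("cell counting matches a brute-force per-point test", {
  set.seed(303)
  poly <- randomConvexPolygon(10, scale = 50)
  cc <- matrix(runif(1000, 0, 50), ncol = 2)
  det <- makeDetections(cc)
  want <- sum(vapply(seq_len(nrow(cc)), function(i)
    oracleInPolygon(cc[i, ], poly), TRUE))
  expect_equal(countCellsInRegion(det, poly), want)
  expect_equal(countCellsInRegion(makeDetections(matrix(0, 0, 2)), poly), 0L)
})

test_that("capped area subtracts one disc per inside centre and clamps at zero", {
  r <- 3
  sq <- rectPoly(0, 0, 10, 10)
  none <- makeDetections(matrix(0, 0, 2))
  expect_equal(cappedArea(sq, none), 100)           # nothing to subtract
  # < 2 detections: no effective radius, no subtraction
  one <- makeDetections(c(5, 5))
  expect_equal(cappedArea(sq, one), 100)
  # polygon area 2*pi*r^2 with exactly one disc inside -> pi*r^2 left
  side <- sqrt(2 * pi * r^2)
  sq2 <- rectPoly(0, 0, side, side)
  two <- makeDetections(rbind(c(side / 2, side / 2), c(500, 500)),
                        effectiveRadiusPx = r)
  expect_equal(cappedArea(sq2, two), pi * r^2)
  # over-subtraction clamps to zero (with a message carrying the raw value)
  many <- makeDetections(cbind(runif(50, 1, 9), runif(50, 1, 9)),
                         effectiveRadiusPx = 3)
  expect_message(a <- cappedArea(sq, many), "clamped")
  expect_equal(a, 0)
})

test_that("capped area is non-increasing in circle count and effective radius", {
  set.seed(404)
  sq <- rectPoly(0, 0, 100, 100)
  pts <- cbind(runif(40, 5, 95), runif(40, 5, 95))
  areas <- vapply(seq(2, 40, by = 2), function(k)
    cappedArea(sq, makeDetections(pts[seq_len(k), ], effectiveRadiusPx = 4)), 0.0)
  expect_true(all(diff(areas) <= 1e-9))
  radii <- seq(1, 8, by = 0.5)
  byR <- vapply(radii, function(r)
    cappedArea(sq, makeDetections(pts, effectiveRadiusPx = r)), 0.0)
  expect_true(all(diff(byR) <= 1e-9))
})

test_that("physical scaling is a pure area ratio", {
  ic <- rectPoly(0, 0, 200, 110)
  a <- polygonArea(ic)
  expect_equal(scaleToPhysical(a, ic, 880), 880)
  expect_equal(scaleToPhysical(a / 2, ic, 880), 440)
  expect_equal(scaleToPhysical(0, ic, 880), 0)
  expect_error(scaleToPhysical(10, rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0)), 880),
               class = "CombQuant_invalid_geometry")
})

test_that("frame quantification fills every field and sums repeated labels", {
  ic <- rectPoly(0, 0, 400, 300)
  det <- makeDetections(rbind(c(50, 50), c(68, 50), c(86, 50), c(150, 150)),
                        effectiveRadiusPx = 6)
  ann <- frameAnnotation("p1", ic, list(
    list(label = "capped_brood", polygon = rectPoly(20, 20, 120, 120)),
    list(label = "capped_brood", polygon = rectPoly(200, 20, 280, 100)),
    list(label = "capped_honey", polygon = rectPoly(120, 130, 220, 230))))
  fm <- quantifyFrame(ann, makeDetections(centres(det), 6, photoId = "p1"), 880)
  tab <- cappedAreas(fm)
  expect_setequal(tab$label, c("capped_brood", "capped_honey"))
  brood <- tab[tab$label == "capped_brood", ]
  expect_equal(brood$grossPolygonAreaPx2, 100 * 100 + 80 * 80)
  expect_equal(brood$nUncappedInside, 3L)
  expect_equal(brood$cappedAreaPx2, 16400 - 3 * pi * 36)
  honey <- tab[tab$label == "capped_honey", ]
  expect_equal(honey$nUncappedInside, 1L)
  expect_equal(honey$cappedAreaPx2, 10000 - pi * 36)
  expect_equal(innerArea(fm), 400 * 300)
  expect_equal(innerArea(fm, "cm2"), 880)
  expect_equal(tab$cappedAreaCm2, tab$cappedAreaPx2 * 880 / (400 * 300))
  expect_equal(tab$cappedFractionOfInner, tab$cappedAreaPx2 / 120000)
})

test_that("an annotation without regions yields zero capped areas", {
  ann <- frameAnnotation("p2", rectPoly(0, 0, 100, 100), list())
  fm <- quantifyFrame(ann, makeDetections(matrix(0, 0, 2), photoId = "p2"), 880)
  expect_equal(sum(cappedAreas(fm)$cappedAreaPx2), 0)
  expect_gt(innerArea(fm), 0)
})

test_that("unknown region labels are rejected at construction", {
  expect_error(
    frameAnnotation("p3", rectPoly(0, 0, 10, 10),
                    list(list(label = "pollen", polygon = rectPoly(1, 1, 3, 3)))))
})

test_that("translating annotation and detections together leaves areas unchanged", {
  set.seed(505)
  shift <- c(37.3, -12.9)
  ic <- rectPoly(0, 0, 300, 200)
  pts <- cbind(runif(30, 10, 290), runif(30, 10, 190))
  mk <- function(dx) {
    ann <- frameAnnotation("p", ic + matrix(dx, 4, 2, byrow = TRUE), list(
      list(label = "capped_honey",
           polygon = rectPoly(40, 40, 260, 160) + matrix(dx, 4, 2, byrow = TRUE))))
    det <- makeDetections(pts + matrix(dx, 30, 2, byrow = TRUE),
                          effectiveRadiusPx = 5, photoId = "p")
    cappedAreas(quantifyFrame(ann, det, 880))
  }
  expect_equal(mk(c(0, 0))$cappedAreaPx2, mk(shift)$cappedAreaPx2)
})

test_that("quantification output satisfies the measurement invariants on random inputs", {
  set.seed(606)
  for (rep in 1:20) {
    ic <- rectPoly(0, 0, runif(1, 200, 500), runif(1, 150, 400))
    W <- max(ic[, 1]); H <- max(ic[, 2])
    nPts <- sample(0:60, 1)
    det <- makeDetections(cbind(runif(nPts, 0, W), runif(nPts, 0, H)),
                          effectiveRadiusPx = if (nPts >= 2) runif(1, 2, 10) else NA_real_,
                          photoId = "r", imageDim = c(ceiling(W) + 1L, ceiling(H) + 1L))
    ## two disjoint regions inside the inner quadrilateral
    ann <- frameAnnotation("r", ic, list(
      list(label = "capped_brood", polygon = rectPoly(0.05 * W, 0.05 * H, 0.45 * W, 0.9 * H)),
      list(label = "capped_honey", polygon = rectPoly(0.55 * W, 0.05 * H, 0.95 * W, 0.9 * H))))
    fm <- quantifyFrame(ann, det, innerFrameCm2 = 880)
    tab <- cappedAreas(fm)
    expect_true(all(tab$cappedAreaPx2 >= 0))
    expect_true(all(tab$cappedAreaPx2 <= tab$grossPolygonAreaPx2 + 1e-9))
    expect_lte(sum(tab$cappedAreaPx2), innerArea(fm) + 1e-9)
    expect_true(all(tab$cappedFractionOfInner >= 0 & tab$cappedFractionOfInner <= 1))
    expect_no_error(methods::validObject(fm))
  }
})

test_that("overlapping polygons of different labels are flagged", {
  ic <- rectPoly(0, 0, 100, 100)
  ann <- frameAnnotation("ov", ic, list(
    list(label = "capped_brood", polygon = rectPoly(10, 10, 60, 60)),
    list(label = "capped_honey", polygon = rectPoly(40, 40, 90, 90))))
  expect_warning(
    quantifyFrame(ann, makeDetections(matrix(0, 0, 2), photoId = "ov"), 880),
    class = "CombQuant_overlapping_regions")
})
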