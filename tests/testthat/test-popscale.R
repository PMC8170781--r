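test_that("straight-edge phantom yields exact positions and lengths", {
  mask <- phantomStraight(H = 200, W = 400, leftEdge = 100, rightEdge = 300)
  ep <- edgeFromIDSD(mask, pixelSizeUm = 1.4, frame = 1)
  expect_false(ep$closed)
  expect_equal(ep$left@meanXMm, 100 * 1.4 / 1000)
  expect_equal(ep$right@meanXMm, 300 * 1.4 / 1000)
  expect_equal(ep$left@lengthMm, 200 * 1.4 / 1000)
  expect_equal(ep$right@lengthMm, 200 * 1.4 / 1000)
  expect_lt(ep$left@meanXMm, ep$right@meanXMm)
  # endpoints reach the top and bottom image borders
  expect_setequal(range(ep$left@coords[, "y"]), c(0, 199))
})

test_that("dilate/keep-two/erode is the identity on clean monolayers and drops debris", {
  mask <- phantomStraight()
  clean <- edgeFromCells(mask, dilationRadiusPx = 15, pixelSizeUm = 1.4)
  expect_false(clean$closed)
  expect_equal(clean$left@meanXMm, 0.14)
  expect_equal(clean$left@lengthMm, 0.28)
  # five isolated 10-px debris blobs mid-gap (far from both edges)
  debris <- mask
  for (y in c(30, 60, 100, 140, 170)) debris[y + (0:1), 200:204] <- 1L
  withDebris <- edgeFromCells(debris, dilationRadiusPx = 15, pixelSizeUm = 1.4)
  expect_identical(withDebris$left@coords, clean$left@coords)
  expect_identical(withDebris$right@coords, clean$right@coords)
  expect_equal(withDebris$left@lengthMm, clean$left@lengthMm)
})

test_that("sinusoidal edge length matches the analytic arc length within 5%", {
  x0 <- 100; amp <- 20; period <- 100; H <- 200
  mask <- phantomSinusoid(H = H, W = 400, x0 = x0, amp = amp, period = period)
  ep <- edgeFromIDSD(mask, pixelSizeUm = 1.4)
  # numeric quadrature of integral sqrt(1 + x'(y)^2) dy
  f <- function(y) sqrt(1 + (amp * 2 * pi / period * cos(2 * pi * y / period))^2)
  arcPx <- stats::integrate(f, 0, H - 1, subdivisions = 1000)$value
  expect_lt(abs(ep$left@lengthMm - arcPx * 1.4 / 1000) / (arcPx * 1.4 / 1000),
            0.05)
  # any perturbed edge is at least as long as the straight one
  expect_gte(ep$left@lengthMm, 200 * 1.4 / 1000)
})

test_that("direct-mask route ignores holes inside the monolayer", {
  mask <- phantomStraight()
  mask[80:95, 30:45] <- 0L  # false "gap" hole inside the left monolayer
  ep <- edgeFromIDSD(mask, 1.4)
  clean <- edgeFromIDSD(phantomStraight(), 1.4)
  expect_identical(ep$left@coords, clean$left@coords)
})

test_that("closure is signalled when fewer than two components remain", {
  solid <- matrix(1L, 100, 200)
  ep <- edgeFromCells(solid, dilationRadiusPx = 5)
  expect_true(ep$closed)
})

test_that("canny route finds the monolayers on a textured phantom", {
  mask <- phantomStraight(H = 200, W = 400)
  img <- phantomImage(mask, seed = 2)
  ec <- edgeFromCanny(img, low = 0.05, high = 0.15, sigma = 2, dilatePx = 10,
                      minAreaPx2 = 500, pixelSizeUm = 1.4)
  expect_true(ec$edgeFound)
  expect_false(ec$closed)
  # gap area within 10 % of the true gap area
  gtGap <- sum(mask == 0)
  expect_lt(abs(sum(ec$gap) - gtGap) / gtGap, 0.1)
  # spatially averaged position within 2 px of the true edge
  expect_lt(abs(ec$left@meanXMm - 0.14), 2 * 1.4 / 1000)
  expect_lt(abs(ec$right@meanXMm - 0.42), 2 * 1.4 / 1000)
  # canny edges fray: never shorter than the true straight edge
  expect_gte(ec$left@lengthMm, 0.28)
})

test_that("constant frames give the no-edge signal", {
  ec <- edgeFromCanny(matrix(0.5, 100, 100))
  expect_false(ec$edgeFound)
})

test_that("edge time series: statics, asymmetry, closure bookkeeping", {
  # static phantom -> constant series
  pairs <- lapply(1:3, function(f) edgeFromIDSD(phantomStraight(), 1.4, f))
  ets <- edgeTimeSeries(pairs, dtMin = 15)
  expect_equal(unique(ets@edges$length_mm), 0.28)
  expect_equal(unique(ets@gap$gap_width_mm), (300 - 100) * 1.4 / 1000)
  expect_true(is.na(ets@closureTimeMin))
  # upstream edge advances faster with positive asymmetry; the band is set
  # to the full monolayer width so each sheet migrates coherently
  sc <- simulateScene(sceneConfig(widthPx = 400, heightPx = 240, nFrames = 6,
                                  gapWidthUm = 250, vEdgeMmH = 0.04,
                                  vInnerMmH = 0.005, asymmetry = 0.6,
                                  borderBandUm = 500, seed = 17))
  mono <- gtMonolayer(sc$truth)
  gp <- lapply(seq_along(mono), function(f) edgeFromIDSD(mono[[f]], 1.4, f))
  es <- edgeTimeSeries(gp, 15)
  left <- es@edges[es@edges$side == "left", ]
  right <- es@edges[es@edges$side == "right", ]
  advLeft <- left$mean_x_mm[nrow(left)] - left$mean_x_mm[1]
  advRight <- right$mean_x_mm[1] - right$mean_x_mm[nrow(right)]
  expect_gt(advLeft, 0)
  expect_gt(advLeft, advRight)
  # closure: a closed frame sets the closure time to (frame - 1) * dt
  pairs2 <- list(edgeFromIDSD(phantomStraight(), 1.4, 1),
                 list(closed = TRUE, left = NULL, right = NULL))
  ets2 <- edgeTimeSeries(pairs2, dtMin = 15)
  expect_equal(ets2@closureTimeMin, 15)
})

test_that("relative error series: zeros, hand arithmetic, frame matching", {
  pairs <- lapply(1:2, function(f) edgeFromIDSD(phantomStraight(), 1.4, f))
  ref <- edgeTimeSeries(pairs, 15)
  expect_equal(relativeErrorSeries(ref, ref)$meanRelErrLength, 0)
  # candidate lengths 1.1 and 0.9 of reference -> mean 10 %
  cand <- ref
  scale <- rep(c(1.1, 0.9), each = 2)
  cand@edges$length_mm <- ref@edges$length_mm * scale
  r <- relativeErrorSeries(cand, ref)
  expect_equal(r$meanRelErrLength, 0.1, tolerance = 1e-12)
  expect_equal(r$meanRelErrMeanX, 0)
  # 20 % single-value check
  expect_equal(relativeError(1.2, 1.0)$values, 0.2)
  # mismatched frames rejected
  short <- edgeTimeSeries(pairs[1], 15)
  expect_error(relativeErrorSeries(short, ref), "different")
})

test_that("cell-route edges on GT masks beat the Canny route on rendered frames", {
  sc <- simulateScene(sceneConfig(widthPx = 400, heightPx = 300, nFrames = 2,
                                  gapWidthUm = 250, seed = 23))
  mono <- gtMonolayer(sc$truth)
  ref <- edgeTimeSeries(lapply(1:2, function(f)
    edgeFromIDSD(mono[[f]], 1.4, f)), 15)
  cellMasks <- lapply(gtLabels(sc$truth), function(l) (l > 0) + 0L)
  icd <- edgeTimeSeries(lapply(1:2, function(f)
    edgeFromCells(cellMasks[[f]], 15, pixelSizeUm = 1.4, frame = f)), 15)
  cny <- edgeTimeSeries(lapply(1:2, function(f)
    edgeFromCanny(sc$sequence@frames[[f]], 0.05, 0.15, 2, dilatePx = 12,
                  minAreaPx2 = 500, pixelSizeUm = 1.4, frameIdx = f)), 15)
  errIcd <- relativeErrorSeries(icd, ref)$meanRelErrLength
  errCny <- relativeErrorSeries(cny, ref)$meanRelErrLength
  expect_lt(errIcd, errCny)
})
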