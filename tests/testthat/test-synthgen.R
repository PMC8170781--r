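test_that("generator bookkeeping: one record per rendered cell per frame", {
  sc <- simulateScene(sceneConfig(widthPx = 240, heightPx = 180, nFrames = 1,
                                  gapWidthUm = 120, cellDensityPerMm2 = 600,
                                  seed = 5))
  cells <- gtCells(sc$truth)
  labs <- gtLabels(sc$truth)
  ids <- sort(unique(as.vector(labs[[1]])))
  ids <- ids[ids > 0]
  expect_equal(sort(cells$id), ids)
  expect_equal(nrow(cells), length(ids))
  expect_true(all(cells$area_px2 > 0))
})

test_that("zero speeds freeze the scene; centroids identical across frames", {
  sc <- simulateScene(sceneConfig(widthPx = 200, heightPx = 150, nFrames = 5,
                                  gapWidthUm = 100, vEdgeMmH = 0,
                                  vInnerMmH = 0, deformation = 0, seed = 8))
  cells <- gtCells(sc$truth)
  for (f in 2:5) {
    a <- cells[cells$frame == 1, c("x_px", "y_px")]
    b <- cells[cells$frame == f, c("x_px", "y_px")]
    expect_equal(a$x_px, b$x_px)
    expect_equal(a$y_px, b$y_px)
  }
  v <- cells$vx_mm_h[cells$frame < 5]
  expect_true(all(v == 0))
  expect_identical(sc$truth@labels[[1]], sc$truth@labels[[3]])
})

test_that("border-cell displacement matches the unit-conversion oracle", {
  # 0.03 mm/h at 1.4 um/px and dt = 15 min:
  # 0.03 * 0.25 h / 0.0014 mm/px = 5.357 px per frame
  expectedPx <- 0.03 * (15 / 60) / (1.4 / 1000)
  expect_equal(expectedPx, 5.357142857, tolerance = 1e-9)
  sc <- simulateScene(sceneConfig(widthPx = 400, heightPx = 300, nFrames = 4,
                                  gapWidthUm = 250, vEdgeMmH = 0.03,
                                  vInnerMmH = 0, seed = 12))
  cells <- gtCells(sc$truth)
  border <- cells[cells$border & cells$frame < 4, ]
  dispPx <- sqrt(border$vx_mm_h^2 + border$vy_mm_h^2) *
    (15 / 60) / (1.4 / 1000)
  expect_gt(nrow(border), 10)
  expect_equal(mean(dispPx), expectedPx, tolerance = 0.05)
})

test_that("identical seeds give bit-identical sequences and ground truth", {
  cfg <- sceneConfig(widthPx = 200, heightPx = 160, nFrames = 3,
                     gapWidthUm = 120, divisionRatePerH = 0.2, seed = 42)
  a <- simulateScene(cfg)
  b <- simulateScene(cfg)
  expect_identical(a$sequence@frames, b$sequence@frames)
  expect_identical(gtCells(a$truth), gtCells(b$truth))
})

test_that("cell count is conserved without division, non-decreasing with", {
  noDiv <- simulateScene(sceneConfig(widthPx = 220, heightPx = 160,
                                     nFrames = 4, gapWidthUm = 120, seed = 9))
  counts <- table(gtCells(noDiv$truth)$frame)
  expect_true(all(counts == counts[1]))
  div <- simulateScene(sceneConfig(widthPx = 220, heightPx = 160, nFrames = 6,
                                   gapWidthUm = 120, divisionRatePerH = 0.5,
                                   seed = 9))
  dc <- as.numeric(table(gtCells(div$truth)$frame))
  expect_true(all(diff(dc) >= 0))
  expect_gt(dc[6], dc[1])
})

test_that("rendered mask centroids agree with ground-truth centroids", {
  sc <- smallScene()
  cells <- gtCells(sc$truth)[gtCells(sc$truth)$frame == 1, ]
  lab <- gtLabels(sc$truth)[[1]]
  idx <- which(lab > 0)
  H <- nrow(lab)
  d <- data.frame(id = lab[idx], x = (idx - 1) %/% H, y = (idx - 1) %% H)
  cx <- tapply(d$x, d$id, mean)
  cy <- tapply(d$y, d$id, mean)
  m <- match(cells$id, as.integer(names(cx)))
  expect_true(all(abs(cx[m] - cells$x_px) <= 1))
  expect_true(all(abs(cy[m] - cells$y_px) <= 1))
})

test_that("doubling the pixel size halves pixel displacements at fixed mm/h", {
  mk <- function(px) sceneConfig(widthPx = 300, heightPx = 200, nFrames = 3,
                                 gapWidthUm = 200, pixelSizeUm = px,
                                 vEdgeMmH = 0.03, vInnerMmH = 0, seed = 4)
  a <- gtCells(simulateScene(mk(1.4))$truth)
  b <- gtCells(simulateScene(mk(2.8))$truth)
  stepPx <- function(cells, px) {
    s <- cells[cells$border & cells$frame == 1, ]
    mean(sqrt(s$vx_mm_h^2 + s$vy_mm_h^2)) * (15 / 60) / (px / 1000)
  }
  expect_equal(stepPx(a, 1.4) / stepPx(b, 2.8), 2, tolerance = 0.1)
})

test_that("gap wider than the image is rejected", {
  expect_error(sceneConfig(widthPx = 100, heightPx = 100, gapWidthUm = 200,
                           pixelSizeUm = 1), "gap")
})

test_that("gaussian noise has the requested moments and is seeded", {
  seq <- imageSequence(list(matrix(0.5, 512, 512)))
  noisy <- addGaussianNoise(seq, mean = 0, variance = 0.01, seed = 2)
  v <- stats::var(as.vector(noisy@frames[[1]]))
  expect_equal(v, 0.01, tolerance = 0.05)
  expect_equal(mean(noisy@frames[[1]]), 0.5, tolerance = 0.002)
  again <- addGaussianNoise(seq, mean = 0, variance = 0.01, seed = 2)
  expect_identical(noisy@frames, again@frames)
  # variance 0 is the identity
  expect_identical(addGaussianNoise(seq, 0, 0, seed = 1)@frames, seq@frames)
  expect_error(addGaussianNoise(seq, 0, -1), "variance")
  # output stays in [0, 1]
  expect_true(all(noisy@frames[[1]] >= 0 & noisy@frames[[1]] <= 1))
})

test_that("label rendering produces a border ring of the requested width", {
  # single circular cell of radius 10: ring = disk minus disk eroded by 2,
  # computed here by brute-force pixel enumeration
  lab <- matrix(0L, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 100) lab[i, j] <- 7L
  gt <- new("GroundTruth", cells = data.frame(), labels = list(lab),
            monolayer = list(), edges = list(), config = sceneConfig())
  m3 <- renderLabels(gt, borderWidthPx = 2)[[1]]
  ringOracle <- sum(vapply(1:41, function(i) sum(vapply(1:41, function(j) {
    if ((i - 21)^2 + (j - 21)^2 > 100) return(0L)
    # interior iff every pixel within distance 2 is inside the disk
    for (di in -2:2) for (dj in -2:2) {
      if (di^2 + dj^2 > 4) next
      if ((i + di - 21)^2 + (j + dj - 21)^2 > 100) return(1L)
    }
    0L
  }, integer(1))), integer(1)))
  expect_equal(sum(m3 == 2L), ringOracle)
  expect_equal(sum(m3 > 0), sum(lab > 0))
  # ring area is close to perimeter * width
  expect_equal(sum(m3 == 2L), 2 * pi * 10 * 2, tolerance = 0.25)
})

test_that("empty label frame renders to all background", {
  gt <- new("GroundTruth", cells = data.frame(),
            labels = list(matrix(0L, 20, 20)), monolayer = list(),
            edges = list(), config = sceneConfig())
  expect_true(all(renderLabels(gt, 2)[[1]] == 0L))
})

test_that("touching cells remain distinct components after border removal", {
  lab <- matrix(0L, 30, 40)
  lab[10:20, 5:15] <- 1L
  lab[10:20, 17:27] <- 2L  # 1 px apart
  gt <- new("GroundTruth", cells = data.frame(), labels = list(lab),
            monolayer = list(), edges = list(), config = sceneConfig())
  m3 <- renderLabels(gt, 2)[[1]]
  cellOnly <- (m3 == 1L) + 0L
  dets <- maskToDetections(cellOnly, 1)
  expect_equal(nrow(dets), 2)
})

test_that("patch sampling is deterministic and respects the patch size", {
  sc <- smallScene()
  p1 <- samplePatches(sc, 5, sizePx = 64, seed = 3)
  p2 <- samplePatches(sc, 5, sizePx = 64, seed = 3)
  expect_identical(p1, p2)
  expect_equal(dim(p1[[1]]$image), c(64, 64))
  expect_true(all(p1[[3]]$label %in% 0:2))
})
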