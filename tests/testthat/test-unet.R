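test_that("tversky loss: perfect prediction, hand-counted toy, bounds", {
  # one-hot prediction equal to the target -> loss ~ 0
  lab <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  target <- WoundScope:::.oneHot(lab, 3)
  expect_lt(tverskyLoss(target, target), 1e-6)
  # 2-class toy, 4 pixels: target (1,1,0,0), pred class-1 prob (1,0,1,0)
  # soft counts for class 1: TP = 1, FP = 1, FN = 1
  # TI = 1 / (1 + 0.3*1 + 0.7*1) = 0.5 -> class loss 0.5
  p1 <- c(1, 0, 1, 0)
  pred <- cbind(1 - p1, p1)
  targ <- cbind(c(0, 0, 1, 1), c(1, 1, 0, 0))
  cfg <- tverskyConfig(alpha = 0.3, beta = 0.7, smooth = 0)
  # class 0 mirror: TP = 1, FP = 1, FN = 1 -> same TI; mean loss = 0.5
  expect_equal(tverskyLoss(pred, targ, cfg), 0.5, tolerance = 1e-12)
  # bounds on random inputs
  set.seed(3)
  for (i in 1:10) {
    r <- matrix(runif(20 * 3), 20, 3); r <- r / rowSums(r)
    t1 <- WoundScope:::.oneHot(matrix(sample(0:2, 20, TRUE), 4, 5), 3)
    l <- tverskyLoss(array(r, c(4, 5, 3)), t1)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(tverskyLoss(pred, targ[1:2, ]), "mismatch")
})

test_that("alpha = beta = 0.5 reproduces the soft Dice loss", {
  softDice <- function(p, t) {
    mean(vapply(seq_len(ncol(p)), function(c) {
      1 - 2 * sum(p[, c] * t[, c]) / (sum(p[, c]) + sum(t[, c]))
    }, numeric(1)))
  }
  set.seed(11)
  cfg <- tverskyConfig(alpha = 0.5, beta = 0.5, smooth = 0)
  for (i in 1:50) {
    n <- sample(5:40, 1); C <- sample(2:4, 1)
    p <- matrix(runif(n * C), n, C); p <- p / rowSums(p)
    t1 <- diag(C)[sample(C, n, TRUE), , drop = FALSE]
    expect_equal(tverskyLoss(p, t1, cfg), softDice(p, t1), tolerance = 1e-9)
  }
})

test_that("augmentation: empty list, exact 90-degree rotation, class closure", {
  img <- matrix(runif(64 * 64), 64, 64)
  lab <- matrix(sample(0:2, 64 * 64, TRUE), 64, 64)
  expect_length(augmentPairs(img, lab, 0), 0)
  # rotation by exactly 90 degrees of a square pair is pixel-exact:
  # (x, y) -> (-y, x) about the centre, i.e. out[i, j] = in[n + 1 - j, i]
  w <- warpPair(img, lab, angleDeg = 90)
  expect_identical(w$label, t(lab)[, 64:1])
  expect_equal(w$image, t(img)[, 64:1], tolerance = 1e-9)
  expect_true(all(w$label %in% unique(as.vector(lab))))
  expect_equal(sort(unique(as.vector(w$label))), sort(unique(as.vector(lab))))
  # geometric transform applied identically: labels follow the image
  w2 <- warpPair(img, lab, angleDeg = 37, skewDeg = 5, txFrac = 0.05,
                 tyFrac = -0.03, brightness = 1.1)
  expect_true(all(w2$label %in% 0:2))
  expect_true(all(w2$image >= 0 & w2$image <= 1))
  # augmented draws are seeded
  a1 <- augmentPairs(img, lab, 3, seed = 5)
  a2 <- augmentPairs(img, lab, 3, seed = 5)
  expect_identical(a1, a2)
})

test_that("training contract: empty sets, zero epochs, loss decrease, determinism", {
  expect_error(trainUNet(list(), list()), "empty")
  set.seed(20)
  sc <- smallScene()
  p <- samplePatches(sc, 12, sizePx = 48, seed = 41)
  imgs <- lapply(p, `[[`, "image"); labs <- lapply(p, `[[`, "label")
  ucfg <- unetConfig(nStages = 2, baseFeatures = 4, nClasses = 3,
                     dropoutRate = 0.2)
  # epochs = 0: untrained weights, empty history
  m0 <- trainUNet(imgs, labs, ucfg, trainCfg = trainConfig(epochs = 0, seed = 2))
  expect_length(m0@lossHistory, 0)
  expect_true(is.matrix(m0@weights$enc1a$W))
  # a short run reduces the loss
  m <- trainUNet(imgs, labs, ucfg,
                 trainCfg = trainConfig(epochs = 3, batchSize = 4, seed = 2))
  expect_length(m@lossHistory, 3)
  expect_lt(m@lossHistory[3], m@lossHistory[1])
  # identical seeds give identical loss histories
  m2 <- trainUNet(imgs, labs, ucfg,
                  trainCfg = trainConfig(epochs = 3, batchSize = 4, seed = 2))
  expect_identical(m@lossHistory, m2@lossHistory)
})

test_that("prediction pads and crops arbitrary sizes; probabilities sum to 1", {
  set.seed(8)
  ucfg <- unetConfig(nStages = 3, baseFeatures = 4, nClasses = 3)
  wts <- withr::with_seed(1, WoundScope:::.unetInit(unclass(ucfg)))
  model <- new("UNetModel", weights = wts, config = unclass(ucfg),
               lossHistory = numeric(0))
  for (d in list(c(100, 100), c(150, 97), c(64, 64))) {
    fr <- matrix(runif(prod(d)), d[1], d[2])
    pr <- predictUNet(fr, model)
    expect_equal(dim(pr$labels), d)
    expect_equal(dim(pr$probs), c(d, 3))
    sums <- pr$probs[, , 1] + pr$probs[, , 2] + pr$probs[, , 3]
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
  }
})

test_that("prediction is consistent under extra reflection padding", {
  # pre-padding by 2^nStages pixels keeps the pooling grid aligned, so
  # labels deep in the interior (beyond the receptive field of the border)
  # must be identical
  sc <- smallScene()
  fr <- sc$sequence@frames[[1]][1:120, 1:160]
  ucfg <- unetConfig(nStages = 2, baseFeatures = 4, nClasses = 3)
  wts <- withr::with_seed(2, WoundScope:::.unetInit(unclass(ucfg)))
  model <- new("UNetModel", weights = wts, config = unclass(ucfg),
               lossHistory = numeric(0))
  pad <- 4  # one pooling-grid period at 2 stages
  padded <- WoundScope:::padSymmetric(fr, pad, pad, pad, pad)
  p1 <- predictUNet(fr, model)$labels
  p2 <- predictUNet(padded, model)$labels[pad + seq_len(120), pad + seq_len(160)]
  margin <- 32  # two-stage receptive field is +-28 input pixels
  inner1 <- p1[(margin + 1):(120 - margin), (margin + 1):(160 - margin)]
  inner2 <- p2[(margin + 1):(120 - margin), (margin + 1):(160 - margin)]
  expect_identical(inner1, inner2)
})

test_that("postprocessing separates, filters and denoises detections", {
  # two cell blobs separated by a 1-px border line -> 2 detections
  lab <- matrix(0L, 30, 30)
  lab[5:25, 5:14] <- 1L
  lab[5:25, 15] <- 2L
  lab[5:25, 16:25] <- 1L
  pp <- postprocessICD(lab, minCellAreaPx2 = 20, medianKernel = 1)
  expect_equal(nrow(pp$detections), 2)
  # an isolated 3-px speck is removed by the minimum-size rule
  sp <- matrix(0L, 20, 20); sp[10, 8:10] <- 1L
  expect_equal(nrow(postprocessICD(sp, minCellAreaPx2 = 50)$detections), 0)
  # checkerboard single-pixel noise is healed by the 3x3 median filter
  clean <- matrix(0L, 40, 40); clean[10:30, 10:30] <- 1L
  noisy <- clean
  idx <- expand.grid(i = seq(2, 38, by = 2), j = seq(2, 38, by = 2))
  flip <- (idx$i + idx$j) %% 4 == 0
  noisy[cbind(idx$i[flip], idx$j[flip])] <- 1L - noisy[cbind(idx$i[flip], idx$j[flip])]
  dClean <- postprocessICD(clean, minCellAreaPx2 = 50, medianKernel = 3)$detections
  dNoisy <- postprocessICD(noisy, minCellAreaPx2 = 50, medianKernel = 3)$detections
  expect_equal(dNoisy, dClean)
})

test_that("2-class prediction returns an input-sized monolayer mask", {
  ucfg <- unetConfig(nStages = 3, baseFeatures = 4, nClasses = 2)
  wts <- withr::with_seed(3, WoundScope:::.unetInit(unclass(ucfg)))
  model <- new("UNetModel", weights = wts, config = unclass(ucfg),
               lossHistory = numeric(0))
  fr <- matrix(runif(150 * 97), 150, 97)
  m <- predictIDSD(fr, model)
  expect_equal(dim(m), c(150, 97))
  expect_true(all(m %in% c(0L, 1L)))
  p <- attr(m, "probs")
  expect_equal(max(abs(p[, , 1] + p[, , 2] - 1)), 0, tolerance = 1e-9)
  # 3-class models are rejected
  m3 <- new("UNetModel",
            weights = withr::with_seed(4, WoundScope:::.unetInit(
              unclass(unetConfig(nClasses = 3, baseFeatures = 4)))),
            config = unclass(unetConfig(nClasses = 3, baseFeatures = 4)),
            lossHistory = numeric(0))
  expect_error(predictIDSD(fr, m3), "2-class")
})

test_that("models round-trip through the checkpoint format", {
  ucfg <- unetConfig(nStages = 2, baseFeatures = 4, nClasses = 3)
  wts <- withr::with_seed(5, WoundScope:::.unetInit(unclass(ucfg)))
  model <- new("UNetModel", weights = wts, config = unclass(ucfg),
               lossHistory = c(0.5, 0.4))
  path <- tempfile(fileext = ".rds")
  saveUNetModel(model, path)
  back <- loadUNetModel(path)
  expect_equal(back@weights, model@weights)
  expect_equal(back@lossHistory, model@lossHistory)
  expect_equal(back@config$nStages, 2)
})

test_that("the loss can be restricted to a class subset", {
  set.seed(13)
  p <- matrix(runif(30 * 3), 30, 3); p <- p / rowSums(p)
  t1 <- diag(3)[sample(3, 30, TRUE), ]
  cellOnly <- tverskyConfig(classes = 2, smooth = 0)
  TP <- sum(p[, 2] * t1[, 2]); FP <- sum(p[, 2] * (1 - t1[, 2]))
  FN <- sum((1 - p[, 2]) * t1[, 2])
  byHand <- 1 - TP / (TP + 0.3 * FP + 0.7 * FN)
  expect_equal(tverskyLoss(p, t1, cellOnly), byHand, tolerance = 1e-12)
  # subset mean differs from the all-class mean in general
  expect_false(isTRUE(all.equal(tverskyLoss(p, t1, cellOnly),
                                tverskyLoss(p, t1, tverskyConfig(smooth = 0)))))
})
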