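# Shared fixtures: phantoms, small scenes, brute-force oracles, and a
# lazily trained mini U-net reused by the slower end-to-end checks.

.fixtures <- new.env(parent = emptyenv())

# Straight-edge phantom: monolayers covering x <= leftEdge and x >= rightEdge
# (0-based column coordinates), so the gap-facing boundary pixels sit exactly
# at x = leftEdge and x = rightEdge.
phantomStraight <- function(H = 200, W = 400, leftEdge = 100,
                            rightEdge = 300) {
  m <- matrix(0L, H, W)
  m[, 1:(leftEdge + 1)] <- 1L
  m[, (rightEdge + 1):W] <- 1L
  m
}

# Sinusoidal left edge x(y) = x0 + amp * sin(2*pi*y/period).
phantomSinusoid <- function(H = 200, W = 400, x0 = 100, amp = 20,
                            period = 100, rightEdge = 300) {
  m <- matrix(0L, H, W)
  for (y in 0:(H - 1)) {
    xl <- round(x0 + amp * sin(2 * pi * y / period))
    m[y + 1, 1:(xl + 1)] <- 1L
  }
  m[, (rightEdge + 1):W] <- 1L
  m
}

# Textured image of the straight-edge phantom (for the Canny route): dense
# speckle inside the monolayers, flat background in the gap.
phantomImage <- function(mask, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(0.15, nrow(mask), ncol(mask))
    n <- sum(mask > 0)
    img[mask > 0] <- 0.45 + 0.4 * runif(n)
    img
  })
}

# Small default scene, cached (used by several files).
smallScene <- function() {
  if (is.null(.fixtures$smallScene))
    .fixtures$smallScene <- simulateScene(sceneConfig(
      widthPx = 320, heightPx = 240, nFrames = 3, gapWidthUm = 200,
      seed = 3))
  .fixtures$smallScene
}

# Ground-truth cell label masks -> detections (per-cell centroids measured
# from the rendered mask of each cell id, so touching cells stay distinct).
gtMaskDetections <- function(scene, frames = NULL) {
  labs <- gtLabels(scene$truth)
  frames <- frames %||% seq_along(labs)
  do.call(rbind, lapply(frames, function(f) {
    lab <- labs[[f]]
    idx <- which(lab > 0)
    l <- lab[idx]
    H <- nrow(lab)
    x <- (idx - 1) %/% H
    y <- (idx - 1) %% H
    area <- tapply(x, l, length)
    data.frame(frame = f, id = as.integer(names(area)),
               x_px = as.numeric(tapply(x, l, mean)),
               y_px = as.numeric(tapply(y, l, mean)),
               area_px2 = as.numeric(area))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force oracles -------------------------------------------------

# Sliding-window mean by direct nested loops with mirror reflection.
slidingMeanOracle <- function(frame, wW, wH) {
  H <- nrow(frame); W <- ncol(frame)
  ry <- (wH - 1) / 2; rx <- (wW - 1) / 2
  reflect <- function(i, n) {
    # symmetric (edge-repeating) reflection of 1-based index
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (di in -ry:ry) for (dj in -rx:rx)
      s <- s + frame[reflect(i + di, H), reflect(j + dj, W)]
    out[i, j] <- s / (wW * wH)
  }
  out
}

# Exhaustive greedy matcher: repeatedly pick the globally closest unmatched
# pair within radius (ties by smaller id_t then id_t1), no sorting shortcut.
greedyMatchOracle <- function(detsT, detsT1, rPx) {
  matches <- data.frame(id_t = integer(0), id_t1 = integer(0))
  usedT <- rep(FALSE, nrow(detsT)); usedT1 <- rep(FALSE, nrow(detsT1))
  repeat {
    best <- NULL; bestD <- Inf
    for (i in seq_len(nrow(detsT))) {
      if (usedT[i]) next
      for (j in seq_len(nrow(detsT1))) {
        if (usedT1[j]) next
        d <- sqrt((detsT$x_px[i] - detsT1$x_px[j])^2 +
                    (detsT$y_px[i] - detsT1$y_px[j])^2)
        if (d > rPx) next
        better <- d < bestD ||
          (d == bestD && (detsT$id[i] < detsT$id[best[1]] ||
                            (detsT$id[i] == detsT$id[best[1]] &&
                               detsT1$id[j] < detsT1$id[best[2]])))
        if (is.null(best) || better) { best <- c(i, j); bestD <- d }
      }
    }
    if (is.null(best)) break
    usedT[best[1]] <- TRUE; usedT1[best[2]] <- TRUE
    matches <- rbind(matches, data.frame(id_t = detsT$id[best[1]],
                                         id_t1 = detsT1$id[best[2]]))
  }
  matches
}

# --- trained mini U-net (shared by the slow end-to-end checks) -----------

# 200 labeled 128x128 patches cut from four synthetic scenes, two of them
# noise-distorted so the network sees the distortion level used in the
# robustness experiments.
trainingPatches <- function() {
  if (is.null(.fixtures$patches)) {
    scenes <- lapply(c(31, 32, 33, 34), function(s)
      simulateScene(sceneConfig(widthPx = 512, heightPx = 384, nFrames = 2,
                                gapWidthUm = 300, seed = s)))
    .fixtures$patches <- c(
      samplePatches(scenes[[1]], 60, seed = 31),
      samplePatches(scenes[[2]], 60, seed = 32),
      samplePatches(scenes[[3]], 40, noiseVariance = 0.01, seed = 33),
      samplePatches(scenes[[4]], 40, noiseVariance = 0.005, seed = 34))
  }
  .fixtures$patches
}

miniCellModel <- function() {
  if (is.null(.fixtures$model)) {
    p <- trainingPatches()
    .fixtures$model <- trainUNet(
      lapply(p, `[[`, "image"), lapply(p, `[[`, "label"),
      unetConfig(nStages = 3, baseFeatures = 8, nClasses = 3),
      tverskyConfig(),
      trainConfig(epochs = 6, batchSize = 2, seed = 7))
  }
  .fixtures$model
}
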