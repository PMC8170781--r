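# Training, inference and augmentation for the segmentation U-net.

#' Apply one affine + brightness transform to an image/label pair
#'
#' Geometric transforms (rotation about the image centre, horizontal skew,
#' translation) are applied identically to image and label via inverse
#' mapping: bilinear interpolation for the image, nearest neighbour for the
#' label, both clamped at the image edge. Brightness scales the image only,
#' clipped to `[0, 1]`; label values therefore always remain a subset of the
#' original class set.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param label integer matrix of the same size
#' @param angleDeg rotation angle in degrees (counter-clockwise in image
#'   coordinates)
#' @param skewDeg horizontal skew angle in degrees
#' @param txFrac,tyFrac translation as a fraction of width/height
#' @param brightness multiplicative brightness factor
#' @return list with `image` and `label`
#' @export
warpPair <- function(image, label, angleDeg = 0, skewDeg = 0, txFrac = 0,
                     tyFrac = 0, brightness = 1) {
  stopifnot(identical(dim(image), dim(label)))
  H <- nrow(image); W <- ncol(image)
  th <- angleDeg * pi / 180
  sk <- tan(skewDeg * pi / 180)
  # forward map: p' = R %*% K %*% (p - c) + c + t  (p = (x, y))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  K <- matrix(c(1, 0, sk, 1), 2, 2)
  M <- R %*% K
  Minv <- solve(M)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  tx <- txFrac * W; ty <- tyFrac * H
  xo <- rep(0:(W - 1), each = H)
  yo <- rep(0:(H - 1), W)
  sx <- Minv[1, 1] * (xo - cx - tx) + Minv[1, 2] * (yo - cy - ty) + cx
  sy <- Minv[2, 1] * (xo - cx - tx) + Minv[2, 2] * (yo - cy - ty) + cy
  img <- matrix(bilinearAt(image, sy + 1, sx + 1), H, W)
  ri <- pmin(pmax(round(sy) + 1, 1), H)
  ci <- pmin(pmax(round(sx) + 1, 1), W)
  lab <- matrix(label[cbind(ri, ci)], H, W)
  list(image = clamp01(img * brightness), label = lab)
}

#' Generate augmented image/label pairs
#'
#' Draws `n` random combinations of skew, rotation, translation and
#' brightness variation (ranges: rotation +-180 deg, skew +-10 deg,
#' translation +-10 % of size, brightness +-20 %) and applies them with
#' [warpPair()]. Seeded and deterministic.
#'
#' @param image,label an aligned pair
#' @param n number of augmented pairs (`n = 0` gives an empty list)
#' @param seed RNG seed
#' @param rotationRange,skewRange,translateFrac,brightnessRange half-ranges
#'   of the uniform parameter draws
#' @return list of `n` lists with elements `image` and `label`
#' @export
augmentPairs <- function(image, label, n, seed = 1, rotationRange = 180,
                         skewRange = 10, translateFrac = 0.1,
                         brightnessRange = 0.2) {
  if (n == 0) return(list())
  withSeed(seed, lapply(seq_len(n), function(i) {
    warpPair(image, label,
             angleDeg = runif(1, -rotationRange, rotationRange),
             skewDeg = runif(1, -skewRange, skewRange),
             txFrac = runif(1, -translateFrac, translateFrac),
             tyFrac = runif(1, -translateFrac, translateFrac),
             brightness = runif(1, 1 - brightnessRange, 1 + brightnessRange))
  }))
}

# pad a matrix symmetrically so both dims are divisible by 2^nStages;
# returns list(m, top, left, H, W)
.padToStages <- function(m, nStages, labelPad = FALSE) {
  H <- nrow(m); W <- ncol(m)
  d <- 2^nStages
  padH <- (d - H %% d) %% d
  padW <- (d - W %% d) %% d
  top <- padH %/% 2; bottom <- padH - top
  left <- padW %/% 2; right <- padW - left
  out <- if (padH == 0 && padW == 0) m else
    padSymmetric(m, top, bottom, left, right)
  list(m = out, top = top, left = left, H = H, W = W)
}

.oneHot <- function(label, nClasses) {
  H <- nrow(label); W <- ncol(label)
  out <- array(0, dim = c(H, W, nClasses))
  for (c in seq_len(nClasses)) out[, , c] <- (label == c - 1) + 0
  out
}

# Adam update; st holds m, v, t.
.adamStep <- function(wts, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (p in c("W", "b")) {
      g <- if (p == "W") grads[[nm]]$dW else grads[[nm]]$db
      st$m[[nm]][[p]] <- beta1 * st$m[[nm]][[p]] + (1 - beta1) * g
      st$v[[nm]][[p]] <- beta2 * st$v[[nm]][[p]] + (1 - beta2) * g^2
      mhat <- st$m[[nm]][[p]] / bc1
      vhat <- st$v[[nm]][[p]] / bc2
      wts[[nm]][[p]] <- wts[[nm]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(wts = wts, st = st)
}

#' Train the segmentation U-net
#'
#' Trains on image/label pairs with the Tversky loss and Adam, using the
#' learning-rate schedule `lr_e = lr * decay^(e-1)`, shuffling before each
#' epoch, optional on-the-fly augmentation, and dropout at the bridge.
#' Images are min-max normalized to `[0, 1]`; images and labels are
#' reflection-padded to dimensions divisible by `2^nStages` if needed.
#' Deterministic for a fixed seed under single-threaded execution.
#'
#' @param images list of numeric matrices
#' @param labels list of integer matrices with classes `0..nClasses-1`
#' @param unetCfg a [unetConfig()]
#' @param tverskyCfg a [tverskyConfig()]
#' @param trainCfg a [trainConfig()]
#' @return a [UNetModel-class] with per-epoch mean loss history
#' @export
trainUNet <- function(images, labels, unetCfg = unetConfig(),
                      tverskyCfg = tverskyConfig(),
                      trainCfg = trainConfig()) {
  if (length(images) == 0) stop("empty training set")
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  withSeed(trainCfg$seed, {
    wts <- .unetInit(unetCfg)
    history <- numeric(0)
    if (trainCfg$epochs > 0) {
      prep <- lapply(seq_along(images), function(i) {
        img <- normalizeFrame(images[[i]])
        list(image = .padToStages(img, unetCfg$nStages)$m,
             label = .padToStages(labels[[i]], unetCfg$nStages)$m)
      })
      st <- list(t = 0,
                 m = lapply(wts, function(w) list(W = w$W * 0, b = w$b * 0)),
                 v = lapply(wts, function(w) list(W = w$W * 0, b = w$b * 0)))
      for (e in seq_len(trainCfg$epochs)) {
        lr <- trainCfg$lr * trainCfg$lrDecayPerEpoch^(e - 1)
        pool <- prep
        if (trainCfg$augmentationsPerImage > 0) {
          aug <- unlist(lapply(prep, function(p)
            augmentPairs(p$image, p$label, trainCfg$augmentationsPerImage,
                         seed = floor(runif(1, 1, 2^30)))),
            recursive = FALSE)
          pool <- c(pool, aug)
        }
        ord <- if (trainCfg$shuffleEachEpoch) sample(length(pool)) else
          seq_along(pool)
        epochLoss <- 0
        nb <- 0
        i <- 1
        while (i <= length(ord)) {
          batch <- ord[i:min(i + trainCfg$batchSize - 1, length(ord))]
          i <- i + trainCfg$batchSize
          acc <- NULL
          for (bi in batch) {
            x <- pool[[bi]]$image
            target <- .oneHot(pool[[bi]]$label, unetCfg$nClasses)
            fw <- .unetForward(x, wts, unetCfg, training = TRUE,
                               keepCache = TRUE)
            lg <- .tverskyLossGrad(fw$probs, target, tverskyCfg)
            epochLoss <- epochLoss + lg$loss
            nb <- nb + 1
            dlogits <- .softmaxBwd(fw$probs, lg$dprobs)
            g <- .unetBackward(dlogits, wts, unetCfg, fw$cache)
            if (is.null(acc)) acc <- g else
              for (nm in names(g)) {
                acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
                acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
              }
          }
          for (nm in names(acc)) {
            acc[[nm]]$dW <- acc[[nm]]$dW / length(batch)
            acc[[nm]]$db <- acc[[nm]]$db / length(batch)
          }
          up <- .adamStep(wts, acc, st, lr)
          wts <- up$wts; st <- up$st
        }
        history <- c(history, epochLoss / nb)
      }
    }
    new("UNetModel", weights = wts, config = unclass(unetCfg),
        lossHistory = history)
  })
}

#' Segment a frame with a trained U-net
#'
#' Arbitrary frame sizes are handled by mirror-padding to the next size
#' divisible by `2^nStages`, running inference, and cropping back, so the
#' output has exactly the input size. Per-pixel class probabilities sum
#' to 1.
#'
#' @param frame numeric matrix (any size); min-max normalized internally
#' @param model a [UNetModel-class]
#' @return list with `probs` (array `H x W x nClasses`) and `labels`
#'   (integer matrix of 0-based argmax classes)
#' @export
predictUNet <- function(frame, model) {
  stopifnot(is(model, "UNetModel"))
  cfg <- model@config
  pad <- .padToStages(normalizeFrame(frame), cfg$nStages)
  fw <- .unetForward(pad$m, model@weights, cfg, training = FALSE,
                     keepCache = FALSE)
  probs <- fw$probs[pad$top + seq_len(pad$H), pad$left + seq_len(pad$W), ,
                    drop = FALSE]
  labels <- apply(probs, c(1, 2), which.max) - 1L
  list(probs = probs, labels = matrix(as.integer(labels), pad$H, pad$W))
}

#' Direct monolayer/gap segmentation
#'
#' Runs a 2-class U-net (gap = 0, monolayer = 1) on a frame and returns the
#' binary monolayer mask; the probability map is attached as attribute
#' `"probs"`.
#'
#' @param frame numeric matrix
#' @param model a 2-class [UNetModel-class]
#' @return binary integer matrix (1 = monolayer)
#' @export
predictIDSD <- function(frame, model) {
  stopifnot(is(model, "UNetModel"))
  if (model@config$nClasses != 2)
    stop("predictIDSD requires a 2-class model")
  p <- predictUNet(frame, model)
  structure(matrix(as.integer(p$labels == 1), nrow(frame), ncol(frame)),
            probs = p$probs)
}

#' Post-process a 3-class segmentation into cell detections
#'
#' Median-filters the label map to remove noisy predictions, sets the
#' border class to background so touching cells separate, binarizes the
#' cell class, removes components below the minimum plausible cell size,
#' and extracts detections as in [maskToDetections()].
#'
#' @param labels integer matrix with classes 0 (background), 1 (cell),
#'   2 (border)
#' @param minCellAreaPx2 minimum component area kept
#' @param medianKernel odd median filter size (default 3)
#' @param frameIdx frame index recorded in the detections
#' @return list with `detections` (data.frame) and `mask` (binary matrix)
#' @export
postprocessICD <- function(labels, minCellAreaPx2 = 50, medianKernel = 3,
                           frameIdx = 1) {
  med <- .median_filter_int(matrix(as.integer(labels), nrow(labels),
                                   ncol(labels)), as.integer(medianKernel))
  mask <- matrix(as.integer(med == 1L), nrow(labels), ncol(labels))
  mask <- removeSmall(mask, minCellAreaPx2)
  list(detections = maskToDetections(mask, frameIdx), mask = mask)
}

#' Save / load a U-net model
#'
#' The checkpoint is an RDS file of the weights and loss history, with a
#' JSON sidecar (`<path>.json`) describing the architecture.
#'
#' @param model a [UNetModel-class]
#' @param path checkpoint file path
#' @return `loadUNetModel` returns the restored [UNetModel-class]
#' @export
saveUNetModel <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  saveRDS(list(weights = model@weights, lossHistory = model@lossHistory),
          path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveUNetModel
#' @export
loadUNetModel <- function(path) {
  obj <- readRDS(path)
  cfgj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- unetConfig(nStages = cfgj$nStages, baseFeatures = cfgj$baseFeatures,
                    nClasses = cfgj$nClasses, dropoutRate = cfgj$dropoutRate)
  new("UNetModel", weights = obj$weights, config = unclass(cfg),
      lossHistory = obj$lossHistory)
}
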