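#' Simulate a synthetic wound-healing scene with full ground truth
#'
#' Renders a time-lapse sequence of two confluent monolayers of textured
#' elliptical cells separated by a vertical cell-free gap, together with
#' complete ground truth: per-frame cell records (centroid, area,
#' instantaneous velocity), cell-id label maps, 2-class monolayer/gap masks
#' (union of cells closed with a disk wide enough to seal the intercellular
#' space), and the true leading-edge positions. Cells bordering the gap migrate toward the gap
#' centre at `vEdgeMmH` (left edge scaled by `1 + asymmetry`, right by
#' `1 - asymmetry`); interior cells take isotropic Gaussian steps calibrated
#' so the mean step speed equals `vInnerMmH`. With `divisionRatePerH > 0`
#' cells divide at the given rate and the cell count is non-decreasing.
#' The same seed reproduces the sequence bit-exactly.
#'
#' @param cfg a [SceneConfig-class], see [sceneConfig()]
#' @return list with elements `sequence` ([ImageSequence-class]) and
#'   `truth` ([GroundTruth-class])
#' @examples
#' sc <- simulateScene(sceneConfig(widthPx = 200, heightPx = 150, nFrames = 2,
#'                                 gapWidthUm = 120))
#' length(sc$sequence)
#' @export
simulateScene <- function(cfg) {
  stopifnot(is(cfg, "SceneConfig"))
  validObject(cfg)
  withSeed(cfg@seed, .simulateSceneImpl(cfg))
}

.simulateSceneImpl <- function(cfg) {
  W <- as.integer(cfg@widthPx); H <- as.integer(cfg@heightPx)
  px <- cfg@pixelSizeUm
  dtH <- cfg@dtMin / 60
  gapPx <- cfg@gapWidthUm / px
  gapL <- (W - gapPx) / 2
  gapR <- (W + gapPx) / 2
  rMean <- cfg@cellRadiusUmMean / px
  rSd <- cfg@cellRadiusUmSd / px
  vEdgePx <- cfg@vEdgeMmH * 1000 / px * dtH   # px per frame
  vInnerPx <- cfg@vInnerMmH * 1000 / px * dtH
  band <- cfg@borderBandUm / px                # gap-border band
  mm2 <- function(wPx) (wPx * px / 1000) * (H * px / 1000)

  placeSide <- function(x0, x1, n) {
    # inhibition sampling: centre spacing > twice the largest semi-axis so
    # neighbouring cells stay separated by a visible intercellular border
    dmin <- 2.4 * rMean
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n && tries < 60L * n) {
      tries <- tries + 1L
      cx <- runif(1, x0 + 0.8 * rMean, x1 - 0.8 * rMean)
      cy <- runif(1, 0.8 * rMean, H - 0.8 * rMean)
      if (length(xs) == 0 || min((xs - cx)^2 + (ys - cy)^2) >= dmin^2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    cbind(x = xs, y = ys)
  }

  nL <- max(1L, round(cfg@cellDensityPerMm2 * mm2(gapL)))
  nR <- max(1L, round(cfg@cellDensityPerMm2 * mm2(W - gapR)))
  pl <- placeSide(0, gapL, nL)
  pr <- placeSide(gapR, W, nR)
  n0 <- nrow(pl) + nrow(pr)

  mkSpeckle <- function() matrix(runif(81, -1, 1), 9, 9)
  cells <- data.frame(
    id = seq_len(n0),
    x = c(pl[, "x"], pr[, "x"]),
    y = c(pl[, "y"], pr[, "y"]),
    # radii truncated so the placement spacing guarantees resolvable borders
    a = pmin(pmax(rnorm(n0, rMean, rSd), 0.7 * rMean), 1.15 * rMean),
    ecc = runif(n0, 0.75, 0.95),
    theta = runif(n0, 0, pi),
    amp = runif(n0, 0.45, 0.6),
    side = rep(c(-1, 1), c(nrow(pl), nrow(pr))) # -1 = left monolayer
  )
  cells$b <- cells$a * cells$ecc
  speckles <- replicate(n0, mkSpeckle(), simplify = FALSE)

  isBorder <- function(cl) {
    (cl$side < 0 & cl$x > gapL - band) | (cl$side > 0 & cl$x < gapR + band)
  }

  frames <- vector("list", cfg@nFrames)
  labels <- vector("list", cfg@nFrames)
  mono <- vector("list", cfg@nFrames)
  edges <- vector("list", cfg@nFrames)
  recs <- vector("list", cfg@nFrames)
  # the closing must bridge the largest intercellular spacing left by the
  # inhibition placement (2.4 r centre-to-centre, occasionally more at
  # sparse spots), or the "closed sheet" ground truth keeps false pockets
  closeBrush <- EBImage::makeBrush(2L * max(1L, round(2 * rMean)) + 1L, "disc")
  sigmaInner <- vInnerPx / sqrt(pi / 2)  # Rayleigh mean == vInnerPx

  for (t in seq_len(cfg@nFrames)) {
    border <- isBorder(cells)
    # per-frame axis jitter (cell shape deformation)
    ja <- cells$a * pmax(0.5, 1 + cfg@deformation * rnorm(nrow(cells)))
    jb <- cells$b * pmax(0.5, 1 + cfg@deformation * rnorm(nrow(cells)))
    rf <- .renderFrame(cells, ja, jb, speckles, W, H,
                       cfg@illuminationGradient, cfg@textureContrast)
    frames[[t]] <- rf$img
    labels[[t]] <- rf$lab
    m <- EBImage::closing((rf$lab > 0) + 0, closeBrush)
    m <- matrix(as.integer(m > 0), H, W)
    mono[[t]] <- m
    edges[[t]] <- .trueEdges(m, W)

    # step to next positions (also yields this frame's instantaneous velocity)
    nc <- nrow(cells)
    dx <- numeric(nc); dy <- numeric(nc)
    inner <- !border
    dx[inner] <- rnorm(sum(inner), 0, sigmaInner)
    dy[inner] <- rnorm(sum(inner), 0, sigmaInner)
    if (any(border)) {
      vb <- ifelse(cells$side[border] < 0,
                   vEdgePx * (1 + cfg@asymmetry),
                   vEdgePx * (1 - cfg@asymmetry))
      dirx <- ifelse(cells$side[border] < 0, 1, -1)
      dx[border] <- dirx * vb + rnorm(sum(border), 0, 0.1 * vEdgePx)
      dy[border] <- rnorm(sum(border), 0, 0.1 * vEdgePx)
    }
    # clamp to the frame; the recorded instantaneous velocity is the step
    # actually taken, so ground truth stays consistent with the rendering
    newx <- pmin(pmax(cells$x + dx, 2), W - 2)
    newy <- pmin(pmax(cells$y + dy, 2), H - 2)
    dx <- newx - cells$x
    dy <- newy - cells$y
    area <- tabulate(rf$lab[rf$lab > 0], nbins = max(cells$id))
    recs[[t]] <- data.frame(
      frame = t, id = cells$id, x_px = cells$x, y_px = cells$y,
      area_px2 = area[cells$id],
      vx_mm_h = if (t < cfg@nFrames) dx * px / 1000 / dtH else NA_real_,
      vy_mm_h = if (t < cfg@nFrames) dy * px / 1000 / dtH else NA_real_,
      border = border
    )
    if (t < cfg@nFrames) {
      cells$x <- newx
      cells$y <- newy
      if (cfg@divisionRatePerH > 0) {
        pDiv <- min(1, cfg@divisionRatePerH * dtH)
        div <- which(runif(nrow(cells)) < pDiv)
        if (length(div)) {
          ang <- runif(length(div), 0, 2 * pi)
          d <- 1.5 * cells$a[div]
          kids <- cells[div, ]
          kids$id <- max(cells$id) + seq_along(div)
          kids$x <- pmin(pmax(kids$x + d * cos(ang), 2), W - 2)
          kids$y <- pmin(pmax(kids$y + d * sin(ang), 2), H - 2)
          cells <- rbind(cells, kids)
          speckles <- c(speckles, replicate(length(div), mkSpeckle(),
                                            simplify = FALSE))
        }
      }
    }
  }

  seq <- imageSequence(frames, pixelSizeUm = px, dtMin = cfg@dtMin)
  gt <- new("GroundTruth", cells = do.call(rbind, recs), labels = labels,
            monolayer = mono, edges = edges, config = cfg)
  list(sequence = seq, truth = gt)
}

# Render one frame; returns the image and the cell-id label map. Pixels
# covered by several cells are assigned to the cell whose normalized
# elliptical radius is smallest.
.renderFrame <- function(cells, ja, jb, speckles, W, H, illum, texc) {
  xs <- (seq_len(W) - 1)
  bgRow <- 0.15 + illum * (xs / max(W - 1, 1) - 0.5)
  img <- matrix(rep(pmax(bgRow, 0.02), each = H), H, W)
  lab <- matrix(0L, H, W)
  bestR2 <- matrix(Inf, H, W)
  for (k in seq_len(nrow(cells))) {
    a <- ja[k]; b <- jb[k]
    ext <- ceiling(1.1 * max(a, b)) + 1
    cx <- cells$x[k]; cy <- cells$y[k]
    x0 <- max(0, floor(cx - ext)); x1 <- min(W - 1, ceiling(cx + ext))
    y0 <- max(0, floor(cy - ext)); y1 <- min(H - 1, ceiling(cy + ext))
    if (x1 < x0 || y1 < y0) next
    xr <- x0:x1; yr <- y0:y1
    X <- matrix(rep(xr, each = length(yr)), length(yr)) - cx
    Y <- matrix(rep(yr, length(xr)), length(yr)) - cy
    ct <- cos(cells$theta[k]); st <- sin(cells$theta[k])
    U <- X * ct + Y * st
    V <- -X * st + Y * ct
    r2 <- (U / a)^2 + (V / b)^2
    m <- r2 <= 1
    if (!any(m)) next
    S <- speckles[[k]]
    tex <- matrix(0, nrow(r2), ncol(r2))
    tex[m] <- bilinearAt(S, (U[m] / a + 1) / 2 * 8 + 1, (V[m] / b + 1) / 2 * 8 + 1)
    inten <- cells$amp[k] * exp(-1.2 * r2) * (1 + texc * tex)
    ri <- yr + 1; ci <- xr + 1
    sub <- img[ri, ci, drop = FALSE]
    sub[m] <- sub[m] + inten[m]
    img[ri, ci] <- sub
    lsub <- lab[ri, ci, drop = FALSE]
    bsub <- bestR2[ri, ci, drop = FALSE]
    sel <- m & (r2 < bsub)
    lsub[sel] <- cells$id[k]
    bsub[sel] <- r2[sel]
    lab[ri, ci] <- lsub
    bestR2[ri, ci] <- bsub
  }
  list(img = clamp01(img), lab = lab)
}

# True leading-edge samples x(y) from a 2-class monolayer mask.
.trueEdges <- function(m, W) {
  H <- nrow(m)
  mid <- W / 2
  xim <- matrix(rep(0:(W - 1), each = H), H, W)
  left <- m > 0 & xim < mid
  right <- m > 0 & xim >= mid
  xl <- apply(left, 1, function(r) if (any(r)) max(which(r)) - 1 else NA_real_)
  xr <- apply(right, 1, function(r) if (any(r)) min(which(r)) - 1 else NA_real_)
  data.frame(y = 0:(H - 1), xLeft = xl, xRight = xr)
}

#' Add i.i.d. Gaussian noise to an image sequence
#'
#' Per-pixel additive Gaussian noise followed by clipping to `[0, 1]`, the
#' distortion used in the robustness experiments. Defaults (mean 0, variance
#' 0.01) follow the classic defaults of the standard Gaussian-noise filter.
#'
#' @param seq an [ImageSequence-class] with frames in `[0, 1]`
#' @param mean noise mean
#' @param variance noise variance (>= 0)
#' @param seed RNG seed; identical seeds give identical output
#' @return a new [ImageSequence-class]
#' @export
addGaussianNoise <- function(seq, mean = 0, variance = 0.01, seed = 1) {
  stopifnot(is(seq, "ImageSequence"))
  if (!is.finite(variance) || variance < 0)
    stop("variance must be >= 0")
  if (variance == 0 && mean == 0) return(seq)
  sdv <- sqrt(variance)
  frames <- withSeed(seed, lapply(seq@frames, function(f) {
    clamp01(f + matrix(rnorm(length(f), mean, sdv), nrow(f), ncol(f)))
  }))
  imageSequence(frames, seq@pixelSizeUm, seq@dtMin)
}

#' Render 3-class segmentation labels from ground truth
#'
#' Converts the per-cell label maps of a [GroundTruth-class] into the
#' 3-class training labels used for per-cell segmentation: background = 0,
#' cell interior = 1, cell border = 2. The border class is the ring of cell
#' pixels within `borderWidthPx` (Euclidean) of any pixel with a different
#' label, so two touching cells are always separated by border pixels.
#'
#' @param gt a [GroundTruth-class]
#' @param borderWidthPx border ring width in pixels (>= 1)
#' @return list of integer matrices with values 0/1/2
#' @export
renderLabels <- function(gt, borderWidthPx = 2) {
  stopifnot(is(gt, "GroundTruth"))
  if (borderWidthPx < 1) stop("borderWidthPx must be >= 1")
  lapply(gt@labels, function(lab) .labelsFromIdMap(lab, borderWidthPx))
}

.labelsFromIdMap <- function(lab, borderWidthPx) {
  mm <- diskMinMax(lab, borderWidthPx)
  interior <- lab > 0 & mm$min == lab & mm$max == lab
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- 2L
  out[interior] <- 1L
  out
}

#' Sample labeled training patches from a synthetic scene
#'
#' Draws random square crops from the rendered frames of a scene together
#' with their 3-class labels (see [renderLabels()]), optionally from a
#' noise-distorted copy of the sequence, as training material for the
#' segmentation network.
#'
#' @param scene result of [simulateScene()]
#' @param n number of patches
#' @param sizePx patch side length in pixels
#' @param borderWidthPx border class width for the labels
#' @param noiseVariance if > 0, patches are cut from a noisy copy of the
#'   sequence ([addGaussianNoise()])
#' @param seed RNG seed for crop positions (and noise)
#' @return list of `n` lists with elements `image` and `label`
#' @export
samplePatches <- function(scene, n, sizePx = 128, borderWidthPx = 2,
                          noiseVariance = 0, seed = 1) {
  seq <- scene$sequence
  if (noiseVariance > 0)
    seq <- addGaussianNoise(seq, 0, noiseVariance, seed + 1000)
  labs <- renderLabels(scene$truth, borderWidthPx)
  H <- nrow(seq@frames[[1]]); W <- ncol(seq@frames[[1]])
  if (sizePx > H || sizePx > W) stop("patch larger than the frames")
  withSeed(seed, lapply(seq_len(n), function(i) {
    f <- sample(length(seq@frames), 1)
    y0 <- sample(H - sizePx + 1, 1)
    x0 <- sample(W - sizePx + 1, 1)
    list(image = seq@frames[[f]][y0:(y0 + sizePx - 1), x0:(x0 + sizePx - 1)],
         label = labs[[f]][y0:(y0 + sizePx - 1), x0:(x0 + sizePx - 1)])
  }))
}
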