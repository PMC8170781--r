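#' Configuration for cell image velocimetry (CIV)
#'
#' Two-pass normalized cross-correlation velocimetry on interrogation areas
#' (IA): a coarse pass at `iaMaxPx` predicts the displacement for the final
#' pass at `iaMinPx`. Defaults follow common practice for monolayer imaging:
#' IA between 32 x 32 and 64 x 64 pixels with 50 % overlap.
#'
#' @param iaMinPx,iaMaxPx minimum / maximum IA size (powers of two)
#' @param overlap fractional IA overlap in `[0, 1)`
#' @param snrMin minimum peak ratio (first/second correlation peak) for a
#'   vector to be considered valid
#' @return a classed parameter list
#' @export
civConfig <- function(iaMinPx = 32, iaMaxPx = 64, overlap = 0.5,
                      snrMin = 1.5) {
  isPow2 <- function(n) n >= 2 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0
  if (!isPow2(iaMinPx) || !isPow2(iaMaxPx)) stop("IA sizes must be powers of two")
  if (iaMinPx > iaMaxPx) stop("iaMinPx must be <= iaMaxPx")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(iaMinPx = as.integer(iaMinPx), iaMaxPx = as.integer(iaMaxPx),
                 overlap = overlap, snrMin = snrMin), class = "civConfig")
}

# Normalized cross-correlation of two equally sized square windows.
# Returns the displacement of b relative to a, the peak ratio, and validity.
.nccPeak <- function(a, b, maxShift) {
  a <- a - mean(a); b <- b - mean(b)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 <= 0 || nb2 <= 0)
    return(list(dx = 0, dy = 0, snr = 0, ok = FALSE))
  n <- nrow(a); N <- 2L * n
  A <- matrix(0, N, N); A[1:n, 1:n] <- a
  B <- matrix(0, N, N); B[1:n, 1:n] <- b
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (N * N)
  C <- C / sqrt(na2 * nb2)
  # C[1 + (dy mod N), 1 + (dx mod N)] = correlation at displacement (dy, dx)
  sh <- -maxShift:maxShift
  block <- C[1 + (sh %% N), 1 + (sh %% N), drop = FALSE]
  pk <- which(block == max(block), arr.ind = TRUE)[1, ]
  py <- pk[1]; px <- pk[2]
  p1 <- block[py, px]
  # second peak outside a 5x5 exclusion zone around the first
  excl <- block
  ry <- max(1, py - 2):min(nrow(block), py + 2)
  rx <- max(1, px - 2):min(ncol(block), px + 2)
  excl[ry, rx] <- -Inf
  p2 <- max(excl)
  snr <- if (is.finite(p2) && p2 > 1e-12) p1 / p2 else Inf
  # 3-point Gaussian sub-pixel fit, per axis
  gfit <- function(cm, c0, cp) {
    cm <- max(cm, 1e-12); c0 <- max(c0, 1e-12); cp <- max(cp, 1e-12)
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (abs(den) < 1e-12) 0 else (log(cm) - log(cp)) / den
  }
  suby <- if (py > 1 && py < nrow(block))
    gfit(block[py - 1, px], p1, block[py + 1, px]) else 0
  subx <- if (px > 1 && px < ncol(block))
    gfit(block[py, px - 1], p1, block[py, px + 1]) else 0
  list(dx = sh[px] + subx, dy = sh[py] + suby, snr = snr, ok = TRUE)
}

#' Cross-correlation velocity field between two frames
#'
#' Two-pass normalized cross-correlation: a coarse pass on `iaMaxPx` windows
#' predicts an integer shift that offsets the second-frame window of the
#' final `iaMinPx` pass. Displacement peaks are refined with a 3-point
#' Gaussian sub-pixel fit; vectors whose correlation peak ratio falls below
#' `snrMin`, or whose residual displacement exceeds a quarter window, are
#' flagged invalid.
#'
#' @param frameT,frameT1 two frames of identical size, larger than `iaMaxPx`
#' @param cfg a [civConfig()]
#' @return data.frame with one row per IA: `x_px`, `y_px` (window centre,
#'   0-based), `dx_px`, `dy_px`, `snr`, `valid`
#' @export
civField <- function(frameT, frameT1, cfg = civConfig()) {
  if (!identical(dim(frameT), dim(frameT1)))
    stop("frames must have identical size")
  H <- nrow(frameT); W <- ncol(frameT)
  if (H < cfg$iaMaxPx || W < cfg$iaMaxPx)
    stop("frames smaller than the maximum interrogation area")

  gridStarts <- function(total, ia, step)
    unique(pmin(seq(1L, max(1L, total - ia + 1L), by = step), total - ia + 1L))

  # coarse pass
  ia1 <- cfg$iaMaxPx
  st1 <- max(1L, as.integer(round(ia1 * (1 - cfg$overlap))))
  cx1 <- gridStarts(W, ia1, st1); cy1 <- gridStarts(H, ia1, st1)
  coarse <- expand.grid(y0 = cy1, x0 = cx1)
  coarse$dx <- 0; coarse$dy <- 0
  for (k in seq_len(nrow(coarse))) {
    y0 <- coarse$y0[k]; x0 <- coarse$x0[k]
    a <- frameT[y0:(y0 + ia1 - 1), x0:(x0 + ia1 - 1)]
    b <- frameT1[y0:(y0 + ia1 - 1), x0:(x0 + ia1 - 1)]
    p <- .nccPeak(a, b, maxShift = ia1 %/% 2L)
    if (p$ok && p$snr >= 1) { coarse$dx[k] <- p$dx; coarse$dy[k] <- p$dy }
  }
  coarseCx <- coarse$x0 + ia1 / 2 - 1
  coarseCy <- coarse$y0 + ia1 / 2 - 1

  # final pass
  ia <- cfg$iaMinPx
  st <- max(1L, as.integer(round(ia * (1 - cfg$overlap))))
  xs <- gridStarts(W, ia, st); ys <- gridStarts(H, ia, st)
  out <- expand.grid(y0 = ys, x0 = xs)
  n <- nrow(out)
  res <- data.frame(x_px = out$x0 + ia / 2 - 1, y_px = out$y0 + ia / 2 - 1,
                    dx_px = NA_real_, dy_px = NA_real_, snr = NA_real_,
                    valid = FALSE)
  for (k in seq_len(n)) {
    y0 <- out$y0[k]; x0 <- out$x0[k]
    # nearest coarse prediction, rounded to integer pixels
    d2 <- (coarseCx - res$x_px[k])^2 + (coarseCy - res$y_px[k])^2
    j <- which.min(d2)
    pdx <- round(coarse$dx[j]); pdy <- round(coarse$dy[j])
    # clamp the shifted window into the image
    bx0 <- min(max(x0 + pdx, 1L), W - ia + 1L)
    by0 <- min(max(y0 + pdy, 1L), H - ia + 1L)
    pdx <- bx0 - x0; pdy <- by0 - y0
    a <- frameT[y0:(y0 + ia - 1), x0:(x0 + ia - 1)]
    b <- frameT1[by0:(by0 + ia - 1), bx0:(bx0 + ia - 1)]
    p <- .nccPeak(a, b, maxShift = ia %/% 2L)
    if (!p$ok) next
    res$dx_px[k] <- pdx + p$dx
    res$dy_px[k] <- pdy + p$dy
    res$snr[k] <- p$snr
    res$valid[k] <- p$snr >= cfg$snrMin &&
      abs(p$dx) <= ia / 4 && abs(p$dy) <= ia / 4
  }
  res
}

#' Column-wise speed profile from a CIV vector field
#'
#' Averages the speed magnitudes of valid CIV vectors per column, exactly as
#' [velocityProfile()] does for tracking steps, so the two measurements are
#' directly comparable.
#'
#' @param field output of [civField()]
#' @param widthPx image width in pixels
#' @param pixelSizeUm,dtMin physical calibration
#' @param nColumns number of columns (default 50)
#' @return a [Profile-class] in mm/h
#' @export
civSpeedProfile <- function(field, widthPx, pixelSizeUm = 1.4, dtMin = 15,
                            nColumns = 50) {
  v <- field[field$valid, , drop = FALSE]
  speeds <- pxPerFrameToMmPerH(sqrt(v$dx_px^2 + v$dy_px^2), pixelSizeUm, dtMin)
  colw <- widthPx / nColumns
  values <- rep(NA_real_, nColumns)
  counts <- rep(0, nColumns)
  if (nrow(v) > 0) {
    col <- pmin(floor(v$x_px / colw) + 1L, nColumns)
    counts <- tabulate(col, nbins = nColumns)
    sums <- rep(0, nColumns)
    agg <- rowsum(speeds, col)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    values[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  }
  edgesPx <- seq(0, widthPx, length.out = nColumns + 1)
  new("Profile", values = values, counts = as.numeric(counts),
      edgesPx = edgesPx,
      xCenterMm = pxToMm((edgesPx[-1] + edgesPx[-length(edgesPx)]) / 2,
                         pixelSizeUm),
      defined = counts > 0, units = "mm/h")
}
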