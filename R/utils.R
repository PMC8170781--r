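# internal helpers: seeded evaluation, padding, unit conversion, warps

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Symmetric (edge-repeating) padding of a matrix.
padSymmetric <- function(m, top, bottom, left, right) {
  H <- nrow(m); W <- ncol(m)
  if (top >= H || bottom >= H || left >= W || right >= W)
    stop("padding must be smaller than the image")
  ri <- c(if (top > 0) top:1, seq_len(H), if (bottom > 0) H:(H - bottom + 1))
  ci <- c(if (left > 0) left:1, seq_len(W), if (right > 0) W:(W - right + 1))
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dy, dx) pixels, zero-filling exposed borders.
shiftMat <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Offsets (dy, dx) of a disk of the given radius (Euclidean, includes radius).
diskOffsets <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d[d$dy^2 + d$dx^2 <= r^2, , drop = FALSE]
}

# Disk structuring element as a 0/1 matrix of odd size 2r+1.
diskBrush <- function(r) {
  n <- 2L * as.integer(r) + 1L
  ix <- matrix(rep(-r:r, n), n, n)
  (ix^2 + t(ix)^2 <= r^2) + 0L
}

# Min/max filter of a matrix over a disk, replicate borders (via index clamp).
diskMinMax <- function(m, r) {
  off <- diskOffsets(r)
  H <- nrow(m); W <- ncol(m)
  mn <- m; mx <- m
  for (k in seq_len(nrow(off))) {
    dy <- off$dy[k]; dx <- off$dx[k]
    if (dy == 0 && dx == 0) next
    ri <- pmin(pmax(seq_len(H) + dy, 1), H)
    ci <- pmin(pmax(seq_len(W) + dx, 1), W)
    s <- m[ri, ci, drop = FALSE]
    mn <- pmin(mn, s); mx <- pmax(mx, s)
  }
  list(min = mn, max = mx)
}

#' Convert a per-frame pixel displacement to a speed in mm/h
#'
#' The maximum linkable speed of the nearest-neighbour tracker is the motion
#' radius `R` expressed in physical units: `R` pixels per frame interval.
#' With the default pixel size of 1.4 um/px and a 15 min frame interval,
#' `R = 25` px corresponds to 0.14 mm/h and `R = 30` px to about 0.17 mm/h.
#'
#' @param px displacement in pixels (per frame)
#' @param pixelSizeUm pixel size in micrometres per pixel
#' @param dtMin frame interval in minutes
#' @return speed in mm/h
#' @export
pxPerFrameToMmPerH <- function(px, pixelSizeUm = 1.4, dtMin = 15) {
  px * (pixelSizeUm / 1000) / (dtMin / 60)
}

#' @rdname pxPerFrameToMmPerH
#' @param rPx motion radius in pixels
#' @export
maxLinkableSpeed <- function(rPx, pixelSizeUm = 1.4, dtMin = 15) {
  pxPerFrameToMmPerH(rPx, pixelSizeUm, dtMin)
}

# mm per pixel
pxToMm <- function(px, pixelSizeUm) px * pixelSizeUm / 1000

# Min-max normalization of a frame to [0, 1]; constant frames map to 0.
normalizeFrame <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# Order file names by the first integer in their base name (natural sort).
naturalOrder <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(sub("^\\D*(\\d+).*$", "\\1", base)))
  order(is.na(num), num, base)
}

# Bilinear sampling of matrix S at fractional (row, col) positions (1-based),
# clamped to the matrix extent.
bilinearAt <- function(S, ri, ci) {
  n <- nrow(S); m <- ncol(S)
  ri <- pmin(pmax(ri, 1), n); ci <- pmin(pmax(ci, 1), m)
  r0 <- pmin(floor(ri), n - 1); c0 <- pmin(floor(ci), m - 1)
  fr <- ri - r0; fc <- ci - c0
  S[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    S[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    S[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    S[cbind(r0 + 1, c0 + 1)] * fr * fc
}
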