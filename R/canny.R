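#' Canny edge detection
#'
#' Classic Canny detector: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding (weak-edge components are kept only when they contain at
#' least one strong pixel). Thresholds are expressed as fractions of the
#' maximum gradient magnitude.
#'
#' @param frame 2-D numeric matrix in `[0, 1]`
#' @param low,high hysteresis thresholds in `(0, 1)`, `low < high`
#' @param sigma Gaussian smoothing standard deviation in pixels
#' @return binary integer matrix of edge pixels
#' @export
cannyEdges <- function(frame, low = 0.1, high = 0.3, sigma = 1.4) {
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix")
  if (low >= high) stop("low must be < high")
  g <- EBImage::gblur(frame, sigma)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (columns)
  ky <- t(kx)                                                # d/dy (rows)
  gx <- EBImage::filter2(g, kx, boundary = "replicate")
  gy <- EBImage::filter2(g, ky, boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # a (near-)constant frame has no edges; do not normalize float noise up
  if (mmax <= 1e-8) return(matrix(0L, nrow(frame), ncol(frame)))
  mag <- mag / mmax
  # quantize direction into 4 sectors (mod 180 deg)
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  # neighbour offsets (dy, dx) along the gradient for each sector:
  # 0: horizontal gradient -> compare left/right; 1: 45; 2: vertical; 3: 135
  n1 <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(0, nrow(mag), ncol(mag))
  for (s in 0:3) {
    o <- n1[[s + 1]]
    a <- shiftMat(mag, o[1], o[2])
    b <- shiftMat(mag, -o[1], -o[2])
    sel <- sector == s & mag >= a & mag >= b
    nms[sel] <- mag[sel]
  }
  weak <- nms >= low
  strong <- nms >= high
  if (!any(strong)) return(matrix(0L, nrow(frame), ncol(frame)))
  labs <- .cc_label(matrix(as.integer(weak), nrow(frame), ncol(frame)), 8L)
  keep <- unique(labs[strong])
  matrix(as.integer(labs %in% keep[keep > 0]), nrow(frame), ncol(frame))
}
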