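#' Configuration for adaptive local-mean threshold segmentation
#'
#' The conventional baseline segmentation: each pixel is compared against the
#' mean grey value of its neighbourhood. The default neighbourhood is
#' 161 x 121 pixels; sensitivities between 0.5 and 0.7 are suitable for
#' bright cells on a darker background.
#'
#' @param windowWPx,windowHPx neighbourhood width/height in px (odd, >= 3)
#' @param sensitivity in `[0, 1]`; a pixel is foreground iff its value
#'   exceeds `localMean * 2 * (1 - sensitivity)` (bright polarity), so the
#'   foreground grows monotonically with sensitivity
#' @param polarity `"bright_cells"` or `"dark_cells"`; dark polarity applies
#'   the bright rule to the inverted image
#' @param minCellAreaPx2 remove components smaller than this area
#' @param fillHoles close holes inside detected cells
#' @return a classed parameter list
#' @export
adaptiveConfig <- function(windowWPx = 161, windowHPx = 121, sensitivity = 0.6,
                           polarity = c("bright_cells", "dark_cells"),
                           minCellAreaPx2 = 50, fillHoles = TRUE) {
  polarity <- match.arg(polarity)
  if (windowWPx < 3 || windowHPx < 3 || windowWPx %% 2 == 0 || windowHPx %% 2 == 0)
    stop("window dimensions must be odd and >= 3")
  if (sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must be in [0, 1]")
  structure(list(windowWPx = as.integer(windowWPx),
                 windowHPx = as.integer(windowHPx),
                 sensitivity = sensitivity, polarity = polarity,
                 minCellAreaPx2 = minCellAreaPx2, fillHoles = fillHoles),
            class = "adaptiveConfig")
}

#' Local mean grey-value field
#'
#' Per-pixel mean over a `windowWPx` x `windowHPx` window centred at the
#' pixel; image borders are handled by mirror reflection, so a constant
#' image yields a constant field.
#'
#' @param frame 2-D numeric matrix with finite values
#' @param cfg an [adaptiveConfig()]
#' @return matrix of the same size
#' @export
localMean <- function(frame, cfg = adaptiveConfig()) {
  if (!is.matrix(frame) || !all(is.finite(frame)))
    stop("frame must be a finite 2-D matrix")
  H <- nrow(frame); W <- ncol(frame)
  wW <- cfg$windowWPx; wH <- cfg$windowHPx
  if (wW > W || wH > H)
    stop("window larger than the image")
  ry <- (wH - 1L) / 2L; rx <- (wW - 1L) / 2L
  p <- padSymmetric(frame, ry, ry, rx, rx)
  # integral image box sum
  S <- rbind(0, apply(p, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  i1 <- seq_len(H); j1 <- seq_len(W)
  box <- S[i1 + wH, j1 + wW, drop = FALSE] - S[i1, j1 + wW, drop = FALSE] -
    S[i1 + wH, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  box / (wW * wH)
}

#' Adaptive local-mean threshold segmentation
#'
#' Thresholds a frame against its local mean field (see [localMean()]), then
#' fills holes in detected cells and removes components smaller than the
#' minimum plausible cell size.
#'
#' @param frame 2-D numeric matrix with values in `[0, 1]`
#' @param cfg an [adaptiveConfig()]
#' @return binary integer matrix (1 = foreground)
#' @export
adaptiveThreshold <- function(frame, cfg = adaptiveConfig()) {
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix")
  work <- if (cfg$polarity == "dark_cells") 1 - frame else frame
  mu <- localMean(work, cfg)
  # strict comparison up to float rounding of the box-filter mean
  fg <- work - mu * (2 * (1 - cfg$sensitivity)) > 1e-9
  mask <- matrix(as.integer(fg), nrow(frame), ncol(frame))
  if (cfg$fillHoles)
    mask <- matrix(as.integer(EBImage::fillHull(mask) > 0), nrow(mask), ncol(mask))
  removeSmall(mask, cfg$minCellAreaPx2)
}

# Remove 8-connected components with area < minArea.
removeSmall <- function(mask, minArea) {
  if (minArea <= 1 || !any(mask > 0)) return(mask)
  labs <- .cc_label(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)), 8L)
  areas <- tabulate(labs[labs > 0])
  keep <- which(areas >= minArea)
  matrix(as.integer(labs %in% keep & labs > 0), nrow(mask), ncol(mask))
}

#' Extract cell detections from a binary mask
#'
#' Each 8-connected foreground component becomes one detection with its
#' centroid (mean of 0-based pixel coordinates, x = column, y = row) and
#' area. Ids are assigned deterministically in raster order of each
#' component's topmost-leftmost pixel.
#'
#' @param mask binary matrix
#' @param frameIdx frame index recorded in the output (1-based)
#' @return data.frame with columns `frame`, `id`, `x_px`, `y_px`, `area_px2`
#' @export
maskToDetections <- function(mask, frameIdx = 1) {
  labs <- .cc_label(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)), 8L)
  idx <- which(labs > 0)
  if (length(idx) == 0)
    return(data.frame(frame = integer(0), id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px2 = numeric(0)))
  H <- nrow(mask)
  l <- labs[idx]
  y <- (idx - 1) %% H          # 0-based row
  x <- (idx - 1) %/% H         # 0-based column
  n <- max(l)
  area <- tabulate(l, nbins = n)
  sx <- rowsum(x, l)[, 1]
  sy <- rowsum(y, l)[, 1]
  data.frame(frame = frameIdx, id = seq_len(n), x_px = sx / area,
             y_px = sy / area, area_px2 = as.numeric(area))
}
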