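# Leading-edge reconstruction and gap-closure metrics.

# Two largest 8-connected foreground components, each reduced to a mask;
# NULL if fewer than two components exist.
.twoLargest <- function(mask) {
  labs <- .cc_label(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)), 8L)
  if (max(labs) < 2) return(NULL)
  areas <- tabulate(labs[labs > 0])
  top <- order(areas, decreasing = TRUE)[1:2]
  list(matrix(as.integer(labs == top[1]), nrow(mask), ncol(mask)),
       matrix(as.integer(labs == top[2]), nrow(mask), ncol(mask)))
}

.largestComponent <- function(mask) {
  labs <- .cc_label(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)), 8L)
  if (max(labs) == 0) return(mask)
  areas <- tabulate(labs[labs > 0])
  matrix(as.integer(labs == which.max(areas)), nrow(mask), ncol(mask))
}

.meanX <- function(mask) {
  idx <- which(mask > 0)
  mean((idx - 1) %/% nrow(mask))
}

# Dilate a binary mask by one pixel with 4-connectivity.
.grow4 <- function(m) {
  (m | shiftMat(m, 1, 0) | shiftMat(m, -1, 0) |
     shiftMat(m, 0, 1) | shiftMat(m, 0, -1)) + 0L
}

# Trace the ordered gap-facing edge of one monolayer component.
.edgeContour <- function(mono, gap, side, pixelSizeUm, frame) {
  pts <- .trace_boundary(mono)                       # ordered (x, y), 0-based
  if (nrow(pts) == 0) return(NULL)
  gadj <- .grow4(gap) & !gap                         # pixels 4-adjacent to gap
  flag <- gadj[cbind(pts[, 2] + 1L, pts[, 1] + 1L)] & (mono[cbind(pts[, 2] + 1L, pts[, 1] + 1L)] > 0)
  if (!any(flag)) return(NULL)
  n <- nrow(pts)
  if (!all(flag)) {
    rot <- which(!flag)[1]
    ord <- c(rot:n, if (rot > 1) 1:(rot - 1))
    pts <- pts[ord, , drop = FALSE]
    flag <- flag[ord]
  }
  sel <- which(flag)
  # the trace doubles back over pixels where it turns around at a one-pixel
  # spur or corner; keep the first visit only
  sel <- sel[!duplicated(paste(pts[sel, 1], pts[sel, 2]))]
  coords <- pts[sel, , drop = FALSE]
  colnames(coords) <- c("x", "y")
  # chain length: steps between consecutive polyline pixels that are also
  # consecutive on the traced boundary, plus one pixel so a straight edge
  # spanning k rows measures exactly k pixels
  lenPx <- 1
  if (length(sel) > 1) {
    adjacent <- diff(sel) == 1
    d <- sqrt(diff(coords[, "x"])^2 + diff(coords[, "y"])^2)
    lenPx <- lenPx + sum(d[adjacent])
  }
  new("EdgeContour", side = side, coords = coords,
      lengthMm = pxToMm(lenPx, pixelSizeUm),
      meanXMm = pxToMm(mean(coords[, "x"]), pixelSizeUm),
      frame = frame)
}

# Shared tail of all edge detectors: two monolayer masks -> gap region ->
# ordered leading-edge contours.
.contoursFromMonolayers <- function(m1, m2, pixelSizeUm, frame) {
  if (.meanX(m1) > .meanX(m2)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  un <- (m1 | m2) + 0L
  bg <- matrix(as.integer(un == 0), nrow(un), ncol(un))
  bglabs <- .cc_label(bg, 4L)
  if (max(bglabs) == 0)
    return(list(closed = TRUE, left = NULL, right = NULL,
                monolayer = un, gap = NULL))
  adj1 <- unique(bglabs[.grow4(m1) & bg > 0])
  adj2 <- unique(bglabs[.grow4(m2) & bg > 0])
  cand <- setdiff(intersect(adj1, adj2), 0L)
  if (length(cand) == 0)
    return(list(closed = TRUE, left = NULL, right = NULL,
                monolayer = un, gap = NULL))
  areas <- tabulate(bglabs[bglabs > 0])
  gapId <- cand[which.max(areas[cand])]
  gap <- matrix(as.integer(bglabs == gapId), nrow(un), ncol(un))
  left <- .edgeContour(m1, gap, "left", pixelSizeUm, frame)
  right <- .edgeContour(m2, gap, "right", pixelSizeUm, frame)
  if (is.null(left) || is.null(right))
    return(list(closed = TRUE, left = NULL, right = NULL,
                monolayer = un, gap = gap))
  list(closed = FALSE, left = left, right = right, monolayer = un, gap = gap)
}

.edgePairFromMask <- function(fg, pixelSizeUm, frame) {
  two <- .twoLargest(fg)
  if (is.null(two))
    return(list(closed = TRUE, left = NULL, right = NULL,
                monolayer = (fg > 0) + 0L, gap = NULL))
  .contoursFromMonolayers(two[[1]], two[[2]], pixelSizeUm, frame)
}

#' Leading edges from a per-cell segmentation mask
#'
#' Upscales a cell-scale segmentation to population scale: the binary cell
#' mask is dilated with a disk so neighbouring cell boundaries overlap, the
#' two largest connected components (the two monolayers) are kept — which
#' discards debris and other artifacts — each is eroded back by the same
#' disk, and the gap region is identified as the largest background
#' component touching both monolayers. Each monolayer's leading edge is the
#' ordered polyline of its boundary pixels facing the gap.
#'
#' @param mask binary cell mask (1 = cell)
#' @param dilationRadiusPx disk radius for the dilation (default 15)
#' @param erosionRadiusPx disk radius for the erosion (defaults to the
#'   dilation radius)
#' @param pixelSizeUm pixel size in micrometres per pixel
#' @param frame frame index recorded in the contours
#' @return list with elements `closed` (logical; TRUE signals "gap closed or
#'   absent"), `left` and `right` ([EdgeContour-class] or NULL when closed),
#'   `monolayer` and `gap` (binary masks)
#' @export
edgeFromCells <- function(mask, dilationRadiusPx = 15,
                          erosionRadiusPx = dilationRadiusPx,
                          pixelSizeUm = 1.4, frame = 1) {
  brushD <- EBImage::makeBrush(2L * as.integer(dilationRadiusPx) + 1L, "disc")
  brushE <- EBImage::makeBrush(2L * as.integer(erosionRadiusPx) + 1L, "disc")
  d <- EBImage::dilate((mask > 0) + 0, brushD)
  two <- .twoLargest(d)
  if (is.null(two))
    return(list(closed = TRUE, left = NULL, right = NULL,
                monolayer = (mask > 0) + 0L, gap = NULL))
  m1 <- .largestComponent(matrix(as.integer(EBImage::erode(two[[1]] + 0, brushE) > 0),
                                 nrow(mask), ncol(mask)))
  m2 <- .largestComponent(matrix(as.integer(EBImage::erode(two[[2]] + 0, brushE) > 0),
                                 nrow(mask), ncol(mask)))
  .contoursFromMonolayers(m1, m2, pixelSizeUm, frame)
}

#' Leading edges by the Canny route
#'
#' Conventional population-scale detection on the raw image: Canny edge map,
#' dilation by a user-defined radius (typically 1-20 px), removal of small
#' components, erosion, then the same two-largest-component edge tracing as
#' [edgeFromCells()].
#'
#' @param frame 2-D numeric matrix in `[0, 1]`
#' @param low,high,sigma Canny parameters, see [cannyEdges()]
#' @param dilatePx dilation radius in pixels (1-20)
#' @param minAreaPx2 small-component removal threshold after dilation
#' @param erosionPx erosion radius (defaults to `dilatePx`)
#' @param pixelSizeUm pixel size in micrometres per pixel
#' @param frameIdx frame index recorded in the contours
#' @return as [edgeFromCells()], with an additional `edgeFound` element;
#'   `edgeFound = FALSE` signals that no edge was detected
#' @export
edgeFromCanny <- function(frame, low = 0.1, high = 0.3, sigma = 2,
                          dilatePx = 15, minAreaPx2 = 500,
                          erosionPx = dilatePx, pixelSizeUm = 1.4,
                          frameIdx = 1) {
  edges <- cannyEdges(frame, low, high, sigma)
  if (!any(edges > 0))
    return(list(edgeFound = FALSE, closed = NA, left = NULL, right = NULL,
                monolayer = NULL, gap = NULL))
  brushD <- EBImage::makeBrush(2L * as.integer(dilatePx) + 1L, "disc")
  brushE <- EBImage::makeBrush(2L * as.integer(erosionPx) + 1L, "disc")
  d <- EBImage::dilate(edges + 0, brushD)
  d <- removeSmall(matrix(as.integer(d > 0), nrow(frame), ncol(frame)),
                   minAreaPx2)
  e <- matrix(as.integer(EBImage::erode(d + 0, brushE) > 0),
              nrow(frame), ncol(frame))
  out <- .edgePairFromMask(e, pixelSizeUm, frameIdx)
  c(list(edgeFound = TRUE), out)
}

#' Leading edges from a direct monolayer/gap segmentation
#'
#' Applies the two-largest-component rule and boundary tracing directly to a
#' predicted 2-class monolayer mask (no dilation or erosion), as used with
#' the direct scratch-detection network.
#'
#' @param mask binary monolayer mask (1 = monolayer)
#' @param pixelSizeUm pixel size in micrometres per pixel
#' @param frame frame index recorded in the contours
#' @return as [edgeFromCells()]
#' @export
edgeFromIDSD <- function(mask, pixelSizeUm = 1.4, frame = 1) {
  .edgePairFromMask((mask > 0) + 0L, pixelSizeUm, frame)
}

#' Collate per-frame edge contours into a time series
#'
#' Collects edge protrusion lengths and spatially averaged edge positions
#' over time, derives the gap width (`mean_x(right) - mean_x(left)`) and the
#' closure time: the time of the first frame whose edge detection signalled
#' a closed gap. Frames are 1-based with frame 1 at time 0.
#'
#' @param pairs list of per-frame results from [edgeFromCells()],
#'   [edgeFromCanny()] or [edgeFromIDSD()]
#' @param dtMin frame interval in minutes
#' @return an [EdgeTimeSeries-class]
#' @export
edgeTimeSeries <- function(pairs, dtMin = 15) {
  if (length(pairs) == 0) stop("at least one frame required")
  rows <- list(); gaps <- list()
  closureTime <- NA_real_
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    timeH <- (k - 1) * dtMin / 60
    closed <- isTRUE(p$closed)
    if (closed && is.na(closureTime)) closureTime <- (k - 1) * dtMin
    if (!closed && !is.null(p$left) && !is.null(p$right)) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = c(k, k), time_h = timeH, side = c("left", "right"),
        length_mm = c(p$left@lengthMm, p$right@lengthMm),
        mean_x_mm = c(p$left@meanXMm, p$right@meanXMm))
      gaps[[length(gaps) + 1]] <- data.frame(
        frame = k, time_h = timeH,
        gap_width_mm = p$right@meanXMm - p$left@meanXMm, closed = FALSE)
    } else {
      gaps[[length(gaps) + 1]] <- data.frame(frame = k, time_h = timeH,
                                             gap_width_mm = 0, closed = TRUE)
    }
  }
  new("EdgeTimeSeries",
      edges = if (length(rows)) do.call(rbind, rows) else
        data.frame(frame = integer(0), time_h = numeric(0),
                   side = character(0), length_mm = numeric(0),
                   mean_x_mm = numeric(0)),
      gap = do.call(rbind, gaps), closureTimeMin = closureTime, dtMin = dtMin)
}

#' Relative errors of one edge time series against a reference
#'
#' Per frame and side, `|candidate - reference| / |reference|` for the edge
#' protrusion length and the spatially averaged edge position, plus their
#' means over frames. Frames whose reference value is zero are flagged
#' undefined (NA).
#'
#' @param candidate,reference [EdgeTimeSeries-class] objects on the same
#'   frames
#' @return list with `perFrame` (data.frame `frame`, `side`,
#'   `rel_err_length`, `rel_err_mean_x`) and the means
#'   `meanRelErrLength`, `meanRelErrMeanX`
#' @export
relativeErrorSeries <- function(candidate, reference) {
  a <- candidate@edges; b <- reference@edges
  key <- function(d) paste(d$frame, d$side)
  if (!identical(sort(key(a)), sort(key(b))))
    stop("candidate and reference cover different frames/sides")
  m <- merge(a, b, by = c("frame", "side"), suffixes = c("_c", "_r"))
  relErr <- function(c, r) ifelse(r == 0, NA_real_, abs(c - r) / abs(r))
  perFrame <- data.frame(
    frame = m$frame, side = m$side,
    rel_err_length = relErr(m$length_mm_c, m$length_mm_r),
    rel_err_mean_x = relErr(m$mean_x_mm_c, m$mean_x_mm_r))
  list(perFrame = perFrame,
       meanRelErrLength = mean(perFrame$rel_err_length, na.rm = TRUE),
       meanRelErrMeanX = mean(perFrame$rel_err_mean_x, na.rm = TRUE))
}
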