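#' Column-wise cell density profile
#'
#' Divides the image into `nColumns` vertical columns (half-open bins, the
#' last bin closed) and counts cell centroids per column. With
#' `normalize = "area"` (default) the count is divided by the column area in
#' mm^2 (cells/mm^2); with `"width"` by the column width in mm (cells/mm).
#'
#' @param dets detections for one frame (see [maskToDetections()])
#' @param widthPx,heightPx image size in pixels
#' @param pixelSizeUm pixel size in micrometres per pixel
#' @param nColumns number of columns (default 50)
#' @param normalize `"area"` or `"width"`
#' @return a [Profile-class]
#' @export
densityProfile <- function(dets, widthPx, heightPx, pixelSizeUm = 1.4,
                           nColumns = 50, normalize = c("area", "width")) {
  normalize <- match.arg(normalize)
  if (nColumns > widthPx) stop("more columns than pixels")
  if (nrow(dets) > 0 && (any(dets$x_px < 0) || any(dets$x_px > widthPx)))
    stop("centroids outside image bounds")
  colw <- widthPx / nColumns
  counts <- if (nrow(dets) == 0) rep(0, nColumns) else
    tabulate(pmin(floor(dets$x_px / colw) + 1L, nColumns), nbins = nColumns)
  colwMm <- pxToMm(colw, pixelSizeUm)
  hMm <- pxToMm(heightPx, pixelSizeUm)
  values <- if (normalize == "area") counts / (colwMm * hMm) else counts / colwMm
  edgesPx <- seq(0, widthPx, length.out = nColumns + 1)
  new("Profile", values = as.numeric(values), counts = as.numeric(counts),
      edgesPx = edgesPx,
      xCenterMm = pxToMm((edgesPx[-1] + edgesPx[-length(edgesPx)]) / 2,
                         pixelSizeUm),
      defined = rep(TRUE, nColumns),
      units = if (normalize == "area") "cells/mm^2" else "cells/mm")
}

#' Link detections between two consecutive frames
#'
#' Globally greedy one-to-one nearest-neighbour matching: all candidate
#' pairs with Euclidean centroid distance `<= rPx` are sorted by ascending
#' distance (ties broken by the smaller id in frame t, then in frame t+1)
#' and accepted whenever both endpoints are still unmatched. Unmatched
#' detections in t+1 start new tracks; unmatched detections in t terminate.
#'
#' @param detsT,detsT1 detections of frames t and t+1
#' @param rPx maximum length of cell motion per frame interval, in pixels
#' @return list with `matches` (data.frame `id_t`, `id_t1`, `dist_px`),
#'   `unmatchedT` and `unmatchedT1` (id vectors)
#' @export
linkFrames <- function(detsT, detsT1, rPx) {
  if (!is.finite(rPx) || rPx <= 0) stop("rPx must be > 0")
  empty <- data.frame(id_t = integer(0), id_t1 = integer(0),
                      dist_px = numeric(0))
  if (nrow(detsT) == 0 || nrow(detsT1) == 0)
    return(list(matches = empty, unmatchedT = detsT$id,
                unmatchedT1 = detsT1$id))
  D <- sqrt(outer(detsT$x_px, detsT1$x_px, "-")^2 +
              outer(detsT$y_px, detsT1$y_px, "-")^2)
  cand <- which(D <= rPx, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(matches = empty, unmatchedT = detsT$id,
                unmatchedT1 = detsT1$id))
  ord <- order(D[cand], detsT$id[cand[, 1]], detsT1$id[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  usedT <- logical(nrow(detsT)); usedT1 <- logical(nrow(detsT1))
  it <- integer(0); it1 <- integer(0); dd <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedT[i] && !usedT1[j]) {
      usedT[i] <- TRUE; usedT1[j] <- TRUE
      it <- c(it, i); it1 <- c(it1, j); dd <- c(dd, D[i, j])
    }
  }
  list(matches = data.frame(id_t = detsT$id[it], id_t1 = detsT1$id[it1],
                            dist_px = dd),
       unmatchedT = detsT$id[!usedT], unmatchedT1 = detsT1$id[!usedT1])
}

#' Track cells across an image sequence
#'
#' Repeated [linkFrames()] over consecutive frames with stable track ids.
#' A track terminates at its first miss (no gap closing); unmatched
#' detections found later start new tracks. Per-step speed is
#' `distance * pixelSize / dt` in mm/h, recorded on the step's start row.
#'
#' @param dets detections of all frames (columns `frame`, `id`, `x_px`,
#'   `y_px`, and optionally `area_px2`)
#' @param rPx maximum length of cell motion per frame interval, in pixels
#' @param pixelSizeUm,dtMin physical calibration
#' @return data.frame with columns `track_id`, `frame`, `id`, `x_px`,
#'   `y_px`, `step_dx_px`, `step_dy_px`, `speed_mm_h` (NA on each track's
#'   last row)
#' @export
trackSequence <- function(dets, rPx, pixelSizeUm = 1.4, dtMin = 15) {
  frames <- sort(unique(dets$frame))
  out <- NULL
  nextTrack <- 1L
  current <- NULL  # map id -> track for the previous frame
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    df <- dets[dets$frame == f, , drop = FALSE]
    if (fi == 1) {
      tr <- seq_len(nrow(df)) + nextTrack - 1L
      nextTrack <- nextTrack + nrow(df)
    } else {
      prev <- dets[dets$frame == frames[fi - 1], , drop = FALSE]
      lk <- linkFrames(prev, df, rPx)
      tr <- integer(nrow(df))
      m <- lk$matches
      for (k in seq_len(nrow(m))) {
        trk <- current[as.character(m$id_t[k])]
        row <- which(df$id == m$id_t1[k])
        tr[row] <- trk
        # record the step on the previous frame's row of that track
        prow <- which(out$track_id == trk & out$frame == frames[fi - 1])
        dxy <- c(df$x_px[row], df$y_px[row]) -
          c(out$x_px[prow], out$y_px[prow])
        out$step_dx_px[prow] <- dxy[1]
        out$step_dy_px[prow] <- dxy[2]
        out$speed_mm_h[prow] <- pxPerFrameToMmPerH(sqrt(sum(dxy^2)),
                                                   pixelSizeUm, dtMin)
      }
      newIdx <- which(tr == 0L)
      tr[newIdx] <- nextTrack + seq_along(newIdx) - 1L
      nextTrack <- nextTrack + length(newIdx)
    }
    block <- data.frame(track_id = tr, frame = f, id = df$id,
                        x_px = df$x_px, y_px = df$y_px,
                        step_dx_px = NA_real_, step_dy_px = NA_real_,
                        speed_mm_h = NA_real_)
    out <- if (is.null(out)) block else rbind(out, block)
    current <- stats::setNames(tr, as.character(df$id))
  }
  rownames(out) <- NULL
  out
}

#' Column-wise cell velocity profile
#'
#' Assigns each tracking step's speed magnitude to the column containing the
#' step's start centroid and averages per column (magnitude mean). Columns
#' without any step are flagged undefined (NA).
#'
#' @param tracks output of [trackSequence()]
#' @param widthPx image width in pixels
#' @param pixelSizeUm pixel size (for column centres in mm)
#' @param nColumns number of columns (default 50)
#' @return a [Profile-class] in mm/h
#' @export
velocityProfile <- function(tracks, widthPx, pixelSizeUm = 1.4,
                            nColumns = 50) {
  steps <- tracks[!is.na(tracks$speed_mm_h), , drop = FALSE]
  colw <- widthPx / nColumns
  values <- rep(NA_real_, nColumns)
  counts <- rep(0, nColumns)
  if (nrow(steps) > 0) {
    col <- pmin(floor(steps$x_px / colw) + 1L, nColumns)
    counts <- tabulate(col, nbins = nColumns)
    sums <- rep(0, nColumns)
    agg <- rowsum(steps$speed_mm_h, col)
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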