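#' Intersection over union (Jaccard index)
#'
#' Per-class and mean IoU between two label maps (or binary masks). For a
#' class absent from both maps the IoU is defined as 1 (prevents spurious
#' zeros on background-only tiles).
#'
#' @param pred,gt matrices of identical size with integer class labels
#' @param classes classes to evaluate; defaults to all labels present in
#'   either map
#' @return list with `perClass` (named numeric) and `mean`
#' @export
iou <- function(pred, gt, classes = NULL) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
  if (is.null(classes)) classes <- sort(unique(c(as.vector(pred), as.vector(gt))))
  per <- vapply(classes, function(cl) {
    i <- sum(pred == cl & gt == cl)
    u <- sum(pred == cl | gt == cl)
    if (u == 0) 1 else i / u
  }, numeric(1))
  names(per) <- as.character(classes)
  list(perClass = per, mean = mean(per))
}

# Boundary pixels: foreground pixels with a 4-neighbour background pixel or
# lying on the image border.
.boundaryPixels <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  inner <- shiftMat(m + 0, 1, 0, 1) & shiftMat(m + 0, -1, 0, 1) &
    shiftMat(m + 0, 0, 1, 1) & shiftMat(m + 0, 0, -1, 1)
  onBorder <- matrix(FALSE, H, W)
  onBorder[c(1, H), ] <- TRUE; onBorder[, c(1, W)] <- TRUE
  m & (!inner | onBorder)
}

#' Boundary F1 score
#'
#' Precision and recall of predicted versus reference boundary pixels,
#' matched within a Euclidean distance tolerance; `F1 = 2PR/(P+R)`. The
#' default tolerance is 0.75 % of the image diagonal. If both boundaries
#' are empty the score is 1; if exactly one is empty it is 0.
#'
#' @param pred,gt binary masks of identical size
#' @param tolerancePx matching tolerance in pixels
#' @return F1 score in `[0, 1]`
#' @export
boundaryF1 <- function(pred, gt, tolerancePx = NULL) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
  if (is.null(tolerancePx))
    tolerancePx <- 0.0075 * sqrt(nrow(pred)^2 + ncol(pred)^2)
  if (tolerancePx < 0) stop("tolerance must be >= 0")
  bp <- .boundaryPixels(pred)
  bg <- .boundaryPixels(gt)
  if (!any(bp) && !any(bg)) return(1)
  if (!any(bp) || !any(bg)) return(0)
  # distance of every pixel to the nearest boundary pixel of the other mask
  dToG <- EBImage::distmap(matrix(as.numeric(!bg), nrow(gt), ncol(gt)))
  dToP <- EBImage::distmap(matrix(as.numeric(!bp), nrow(pred), ncol(pred)))
  precision <- mean(dToG[bp] <= tolerancePx)
  recall <- mean(dToP[bg] <= tolerancePx)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Compare per-frame cell counts of two detection methods
#'
#' Means, per-frame differences, and the paired two-sided t-test p-value on
#' the per-frame counts. With fewer than two frames, or constant
#' differences, the p-value is NA and a note explains why.
#'
#' @param countsA,countsB numeric vectors of per-frame counts (same frames)
#' @return list with `meanA`, `meanB`, `meanDiff`, `diffs`, `pValue`, `note`
#' @export
countComparison <- function(countsA, countsB) {
  if (length(countsA) != length(countsB)) stop("count vectors differ in length")
  diffs <- countsA - countsB
  out <- list(meanA = mean(countsA), meanB = mean(countsB),
              meanDiff = mean(diffs), diffs = diffs, pValue = NA_real_,
              note = "")
  if (length(diffs) < 2) {
    out$note <- "p undefined: fewer than two frames"
  } else if (sd(diffs) == 0) {
    out$note <- "p undefined: constant differences"
  } else {
    out$pValue <- stats::t.test(countsA, countsB, paired = TRUE)$p.value
  }
  out
}

#' Relative error against a reference
#'
#' Elementwise `|candidate - reference| / |reference|`; elements with a zero
#' reference are flagged undefined (NA). For series the mean over defined
#' elements is also reported.
#'
#' @param candidate,reference numeric scalars or vectors of equal length
#' @return list with `values` (elementwise) and `mean`
#' @export
relativeError <- function(candidate, reference) {
  if (length(candidate) != length(reference)) stop("length mismatch")
  v <- ifelse(reference == 0, NA_real_,
              abs(candidate - reference) / abs(reference))
  list(values = v, mean = mean(v, na.rm = TRUE))
}

#' Bundle the segmentation evaluation metrics into one report
#'
#' Computes per-class and mean IoU, the boundary F1 score of the binarized
#' masks, the paired count comparison (when per-frame counts are supplied),
#' and the relative error of the total counts, and optionally writes the
#' report as JSON.
#'
#' @param pred,gt label maps (or binary masks) of identical size
#' @param predCounts,gtCounts optional per-frame detection counts
#' @param tolerancePx boundary F1 tolerance, see [boundaryF1()]
#' @param path if given, the report is written there as JSON
#' @return list with `mean_iou`, `per_class_iou`, `boundary_f1`, `counts`
#'   (means, p-value) and `relative_errors`
#' @export
evaluationReport <- function(pred, gt, predCounts = NULL, gtCounts = NULL,
                             tolerancePx = NULL, path = NULL) {
  ov <- iou(pred, gt)
  rep <- list(
    mean_iou = ov$mean,
    per_class_iou = as.list(ov$perClass),
    boundary_f1 = boundaryF1((pred > 0) + 0L, (gt > 0) + 0L, tolerancePx))
  if (!is.null(predCounts) && !is.null(gtCounts)) {
    cc <- countComparison(predCounts, gtCounts)
    rep$counts <- list(mean_pred = cc$meanA, mean_gt = cc$meanB,
                       mean_diff = cc$meanDiff, p_value = cc$pValue,
                       note = cc$note)
    rep$relative_errors <- list(
      total_count = relativeError(sum(predCounts), sum(gtCounts))$values)
  }
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  rep
}
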