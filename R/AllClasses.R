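#' Scene configuration for the synthetic wound-healing generator
#'
#' Describes a synthetic scratch-assay scene: two confluent monolayers of
#' textured elliptical cells separated by a vertical cell-free gap, imaged at
#' a fixed frame interval. Border cells migrate toward the gap centre at
#' `vEdgeMmH`; interior cells perform an isotropic random walk with mean step
#' speed `vInnerMmH`. `asymmetry` biases the upstream (left) edge speed by
#' `(1 + asymmetry)` and the downstream (right) edge by `(1 - asymmetry)`.
#'
#' @slot widthPx,heightPx image size in pixels
#' @slot pixelSizeUm pixel size, micrometres per pixel (default 1.4)
#' @slot dtMin frame interval in minutes (default 15)
#' @slot nFrames number of frames (>= 1)
#' @slot gapWidthUm initial gap width in micrometres (default 500)
#' @slot cellDensityPerMm2 monolayer cell density, cells per mm^2
#' @slot cellRadiusUmMean,cellRadiusUmSd cell radius distribution (um)
#' @slot vEdgeMmH directed speed of gap-border cells, mm/h
#' @slot vInnerMmH mean random-walk speed of interior cells, mm/h
#' @slot asymmetry upstream/downstream edge speed bias in `[-1, 1]`
#' @slot divisionRatePerH per-cell division rate per hour
#' @slot illuminationGradient peak-to-peak linear illumination ramp across x
#' @slot textureContrast multiplicative speckle contrast of the cell texture
#' @slot borderBandUm width of the gap-border band (um): cells whose centre
#'   lies within this distance of the monolayer front move with the directed
#'   edge speed; set it to the monolayer width for coherent sheet migration
#' @slot deformation per-frame fractional jitter of cell ellipse axes
#' @slot seed RNG seed fixing the whole sequence bit-exactly
#' @export
setClass("SceneConfig", representation(
  widthPx = "numeric", heightPx = "numeric", pixelSizeUm = "numeric",
  dtMin = "numeric", nFrames = "numeric", gapWidthUm = "numeric",
  cellDensityPerMm2 = "numeric", cellRadiusUmMean = "numeric",
  cellRadiusUmSd = "numeric", vEdgeMmH = "numeric", vInnerMmH = "numeric",
  asymmetry = "numeric", divisionRatePerH = "numeric",
  illuminationGradient = "numeric", textureContrast = "numeric",
  borderBandUm = "numeric", deformation = "numeric", seed = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  pos <- c(widthPx = object@widthPx, heightPx = object@heightPx,
           pixelSizeUm = object@pixelSizeUm, dtMin = object@dtMin,
           gapWidthUm = object@gapWidthUm,
           cellRadiusUmMean = object@cellRadiusUmMean)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be > 0:", paste(bad, collapse = ", ")))
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (object@gapWidthUm >= object@widthPx * object@pixelSizeUm)
    msg <- c(msg, "gap wider than the image")
  if (abs(object@asymmetry) > 1) msg <- c(msg, "asymmetry must be in [-1, 1]")
  if (object@vEdgeMmH < 0 || object@vInnerMmH < 0 || object@divisionRatePerH < 0)
    msg <- c(msg, "speeds and division rate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneConfig Constructor with the default study conditions.
#' @param widthPx,heightPx,pixelSizeUm,dtMin,nFrames,gapWidthUm,cellDensityPerMm2
#'   see slots
#' @param cellRadiusUmMean,cellRadiusUmSd,vEdgeMmH,vInnerMmH,asymmetry see slots
#' @param divisionRatePerH,illuminationGradient,textureContrast,borderBandUm
#'   see slots
#' @param deformation,seed see slots
#' @export
sceneConfig <- function(widthPx = 640, heightPx = 480, pixelSizeUm = 1.4,
                        dtMin = 15, nFrames = 5, gapWidthUm = 500,
                        cellDensityPerMm2 = 700, cellRadiusUmMean = 12,
                        cellRadiusUmSd = 2, vEdgeMmH = 0.03, vInnerMmH = 0.01,
                        asymmetry = 0, divisionRatePerH = 0,
                        illuminationGradient = 0.1, textureContrast = 0.3,
                        borderBandUm = 36, deformation = 0.1, seed = 1) {
  new("SceneConfig", widthPx = widthPx, heightPx = heightPx,
      pixelSizeUm = pixelSizeUm, dtMin = dtMin, nFrames = nFrames,
      gapWidthUm = gapWidthUm, cellDensityPerMm2 = cellDensityPerMm2,
      cellRadiusUmMean = cellRadiusUmMean, cellRadiusUmSd = cellRadiusUmSd,
      vEdgeMmH = vEdgeMmH, vInnerMmH = vInnerMmH, asymmetry = asymmetry,
      divisionRatePerH = divisionRatePerH,
      illuminationGradient = illuminationGradient,
      textureContrast = textureContrast, borderBandUm = borderBandUm,
      deformation = deformation, seed = seed)
}

#' Time-lapse grayscale image sequence
#'
#' Ordered grayscale frames (matrices indexed `[y + 1, x + 1]`, values in
#' `[0, 1]`) with the pixel size and frame interval needed to express
#' measurements in physical units.
#'
#' @slot frames list of numeric matrices, all the same size
#' @slot pixelSizeUm pixel size in micrometres per pixel
#' @slot dtMin frame interval in minutes
#' @export
setClass("ImageSequence", representation(
  frames = "list", pixelSizeUm = "numeric", dtMin = "numeric"
))

setValidity("ImageSequence", function(object) {
  if (length(object@frames) == 0) return("at least one frame required")
  d <- dim(object@frames[[1]])
  ok <- vapply(object@frames,
               function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) return("all frames must be matrices of identical size")
  if (object@pixelSizeUm <= 0 || object@dtMin <= 0)
    return("pixelSizeUm and dtMin must be > 0")
  TRUE
})

#' @describeIn ImageSequence Constructor.
#' @param frames list of numeric matrices
#' @param pixelSizeUm,dtMin metadata, see slots
#' @export
imageSequence <- function(frames, pixelSizeUm = 1.4, dtMin = 15) {
  new("ImageSequence", frames = frames, pixelSizeUm = pixelSizeUm,
      dtMin = dtMin)
}

#' Ground truth of a synthetic scene
#'
#' Per-frame cell records (id, centroid, area, instantaneous velocity),
#' per-frame cell-id label maps, the 2-class monolayer/gap masks, and the
#' true leading-edge x(y) samples for both monolayers.
#'
#' @slot cells data.frame with columns `frame`, `id`, `x_px`, `y_px`,
#'   `area_px2`, `vx_mm_h`, `vy_mm_h`, `border` (logical)
#' @slot labels list of integer matrices; pixel value = cell id (0 background)
#' @slot monolayer list of 0/1 matrices (1 = monolayer)
#' @slot edges list of data.frames with columns `y`, `xLeft`, `xRight`
#'   (0-based pixel coordinates; NA where a monolayer does not reach row y)
#' @slot config the generating [SceneConfig-class]
#' @export
setClass("GroundTruth", representation(
  cells = "data.frame", labels = "list", monolayer = "list",
  edges = "list", config = "SceneConfig"
))

#' Column profile of a scalar quantity versus x
#'
#' The image is partitioned into `nColumns` half-open vertical bins (the last
#' bin closed); each bin carries one scalar (cell density in cells/mm^2 or
#' mean speed in mm/h). Bins with no supporting data are flagged undefined.
#'
#' @slot values per-column values (NA where undefined)
#' @slot counts per-column number of contributing observations
#' @slot edgesPx bin edges in pixels, length `nColumns + 1`
#' @slot xCenterMm bin centres in millimetres
#' @slot defined logical, per-column
#' @slot units value units, e.g. `"cells/mm^2"` or `"mm/h"`
#' @export
setClass("Profile", representation(
  values = "numeric", counts = "numeric", edgesPx = "numeric",
  xCenterMm = "numeric", defined = "logical", units = "character"
))

#' Leading-edge contour of one monolayer
#'
#' Ordered 8-connected polyline of gap-facing boundary pixels of one
#' monolayer, with its protrusion length and spatially averaged position.
#'
#' @slot side `"left"` or `"right"` (map to upstream/downstream by flow
#'   orientation)
#' @slot coords integer matrix with columns `x`, `y` (0-based pixels)
#' @slot lengthMm protrusion (arc) length in mm: 8-connected chain length
#'   plus one pixel, so a straight edge spanning k rows measures k pixels
#' @slot meanXMm spatially averaged edge position in mm
#' @slot frame frame index (1-based)
#' @export
setClass("EdgeContour", representation(
  side = "character", coords = "matrix", lengthMm = "numeric",
  meanXMm = "numeric", frame = "numeric"
))

#' Leading-edge time series
#'
#' Edge protrusion length and spatially averaged position per frame and side,
#' the derived gap width, and the closure time (first frame where the two
#' monolayers meet), if reached.
#'
#' @slot edges data.frame: `frame`, `time_h`, `side`, `length_mm`, `mean_x_mm`
#' @slot gap data.frame: `frame`, `time_h`, `gap_width_mm`, `closed`
#' @slot closureTimeMin time of closure in minutes (NA if the gap stays open)
#' @slot dtMin frame interval in minutes
#' @export
setClass("EdgeTimeSeries", representation(
  edges = "data.frame", gap = "data.frame", closureTimeMin = "numeric",
  dtMin = "numeric"
))

#' Trained U-net model
#'
#' Weights and architecture of the small encoder-decoder segmentation
#' network, together with the per-epoch mean Tversky loss recorded during
#' training.
#'
#' @slot weights named list of layer parameter lists (`W`, `b`, `k`)
#' @slot config the [unetConfig()] list used to build the network
#' @slot lossHistory numeric, per-epoch mean training loss
#' @export
setClass("UNetModel", representation(
  weights = "list", config = "list", lossHistory = "numeric"
))

# ---- accessors and show methods ----

#' @describeIn ImageSequence Number of frames.
#' @param x an `ImageSequence`
#' @export
setMethod("length", "ImageSequence", function(x) length(x@frames))

#' Accessors for image sequences
#'
#' @param x an [ImageSequence-class]
#' @return `getFrames()` the list of frame matrices; `pixelSize()` the pixel
#'   size in um/px; `frameInterval()` the frame interval in minutes.
#' @export
getFrames <- function(x) x@frames

#' @rdname getFrames
#' @export
pixelSize <- function(x) x@pixelSizeUm

#' @rdname getFrames
#' @export
frameInterval <- function(x) x@dtMin

#' Accessors for ground truth
#'
#' @param gt a [GroundTruth-class]
#' @return `gtCells()` the cell record data.frame; `gtLabels()` the cell-id
#'   label maps; `gtMonolayer()` the 2-class monolayer masks; `gtEdges()` the
#'   true edge samples; `gtDetections()` detections (frame, id, x_px, y_px,
#'   area_px2) for one frame, in the format consumed by the tracker.
#' @export
gtCells <- function(gt) gt@cells

#' @rdname gtCells
#' @export
gtLabels <- function(gt) gt@labels

#' @rdname gtCells
#' @export
gtMonolayer <- function(gt) gt@monolayer

#' @rdname gtCells
#' @export
gtEdges <- function(gt) gt@edges

#' @rdname gtCells
#' @param frame 1-based frame index
#' @export
gtDetections <- function(gt, frame) {
  d <- gt@cells[gt@cells$frame == frame,
                c("frame", "id", "x_px", "y_px", "area_px2")]
  rownames(d) <- NULL
  d
}

#' @describeIn Profile Per-column values (NA where undefined).
#' @param object,x a `Profile`
#' @export
profileValues <- function(x) x@values

#' @rdname profileValues
#' @export
profileCenters <- function(x) x@xCenterMm

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d px @ %.2f um/px, %d frame(s) every %g min\n",
    object@widthPx, object@heightPx, object@pixelSizeUm,
    as.integer(object@nFrames), object@dtMin))
  cat(sprintf("  gap %g um | density %g cells/mm^2 | v_edge %g, v_inner %g mm/h\n",
              object@gapWidthUm, object@cellDensityPerMm2, object@vEdgeMmH,
              object@vInnerMmH))
})

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageSequence: %d frame(s) of %dx%d px, %.2f um/px, dt %g min\n",
              length(object@frames), d[2], d[1], object@pixelSizeUm,
              object@dtMin))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frame(s), %d cell record(s), %d unique cell(s)\n",
              length(object@labels), nrow(object@cells),
              length(unique(object@cells$id))))
})

setMethod("show", "Profile", function(object) {
  cat(sprintf("Profile: %d columns [%s]; %d defined; mean %.4g\n",
              length(object@values), object@units, sum(object@defined),
              mean(object@values[object@defined])))
})

setMethod("show", "EdgeContour", function(object) {
  cat(sprintf("EdgeContour (%s, frame %d): %d px, length %.4f mm, mean x %.4f mm\n",
              object@side, as.integer(object@frame), nrow(object@coords),
              object@lengthMm, object@meanXMm))
})

setMethod("show", "EdgeTimeSeries", function(object) {
  cat(sprintf("EdgeTimeSeries: %d frame(s); closure %s\n",
              length(unique(object@edges$frame)),
              if (is.na(object@closureTimeMin)) "not reached"
              else sprintf("at %g min", object@closureTimeMin)))
})

setMethod("show", "UNetModel", function(object) {
  cat(sprintf(
    "UNetModel: %d stages, %d base features, %d classes; %d training epoch(s)\n",
    object@config$nStages, object@config$baseFeatures, object@config$nClasses,
    length(object@lossHistory)))
})
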