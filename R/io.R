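#' Read a time-lapse image sequence
#'
#' Reads a multi-page TIFF stack, a list of files, or a directory of
#' numbered PNG/TIFF frames (ordered by the first number in each file name,
#' not lexicographically). Integer images are scaled to `[0, 1]` by the
#' reader; colour frames are averaged to grayscale. A JSON sidecar
#' (`<path>.json` or `metadata.json` in the directory) may provide
#' `pixel_size_um` and `dt_min`, which override the arguments.
#'
#' @param path TIFF file, directory, or character vector of files
#' @param pixelSizeUm,dtMin calibration used when no sidecar is present
#' @return an [ImageSequence-class]
#' @export
readSequence <- function(path, pixelSizeUm = 1.4, dtMin = 15) {
  files <- NULL
  sidecar <- NULL
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop("no image files found in ", path)
    files <- files[naturalOrder(files)]
    mj <- file.path(path, "metadata.json")
    if (file.exists(mj)) sidecar <- mj
  } else if (length(path) > 1) {
    files <- path[naturalOrder(path)]
  } else {
    if (!file.exists(path)) stop("cannot read file: ", path)
    if (file.exists(paste0(path, ".json"))) sidecar <- paste0(path, ".json")
  }
  toGray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                          drop = FALSE], c(1, 2), mean)
    if (!is.matrix(a)) a <- as.matrix(a)
    a
  }
  frames <- if (is.null(files)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, toGray)
  } else {
    lapply(files, function(f) {
      a <- tryCatch({
        if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
        else tiff::readTIFF(f)
      }, error = function(e) stop("unreadable file: ", f, " (",
                                  conditionMessage(e), ")"))
      toGray(a)
    })
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("mixed frame shapes in input")
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixelSizeUm <- meta$pixel_size_um
    if (!is.null(meta$dt_min)) dtMin <- meta$dt_min
  }
  imageSequence(frames, pixelSizeUm = pixelSizeUm, dtMin = dtMin)
}

#' Write an image sequence
#'
#' Writes either a multi-page 32-bit float TIFF stack (`format = "tiff"`;
#' lossless, so write/read round trips are exact) or numbered 8-bit PNG
#' frames in a directory (`format = "png"`), plus a JSON metadata sidecar
#' with the pixel size and frame interval.
#'
#' @param seq an [ImageSequence-class]
#' @param path output file (tiff) or directory (png)
#' @param format `"tiff"` or `"png"`
#' @return the path, invisibly
#' @export
writeSequence <- function(seq, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  meta <- list(pixel_size_um = seq@pixelSizeUm, dt_min = seq@dtMin,
               n_frames = length(seq@frames))
  if (format == "tiff") {
    tiff::writeTIFF(lapply(seq@frames, clamp01), path,
                    bits.per.sample = 32L)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(seq@frames))
      png::writePNG(clamp01(seq@frames[[i]]),
                    file.path(path, sprintf("frame%04d.png", i)))
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered frames as a TIFF stack, the 3-class label masks as
#' 8-bit PNGs, the ground-truth cell table as CSV (frame, cell_id, x_px,
#' y_px, area_px2, vx_mm_h, vy_mm_h) and the scene configuration as a JSON
#' sidecar. Coordinates are 0-based (x = column, y = row).
#'
#' @param scene result of [simulateScene()]
#' @param dir output directory (created if needed)
#' @param borderWidthPx border width for the rendered label masks
#' @return `dir`, invisibly
#' @export
writeScene <- function(scene, dir, borderWidthPx = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSequence(scene$sequence, file.path(dir, "frames.tiff"))
  labs <- renderLabels(scene$truth, borderWidthPx)
  for (i in seq_along(labs))
    png::writePNG(labs[[i]] / 255, file.path(dir, sprintf("labels%04d.png", i)))
  cells <- gtCells(scene$truth)
  write.csv(cells[, c("frame", "id", "x_px", "y_px", "area_px2",
                      "vx_mm_h", "vy_mm_h")],
            file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- scene$truth@config
  sl <- slotNames(cfg)
  jsonlite::write_json(stats::setNames(lapply(sl, function(s) slot(cfg, s)), sl),
                       file.path(dir, "scene_config.json"), auto_unbox = TRUE)
  invisible(dir)
}
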