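#' Calibrated grayscale frame sequence
#'
#' The universal input of the pipeline: an ordered list of equally sized
#' grayscale frames (numeric matrices on the 8-bit 0..255 scale) plus a
#' [Calibration-class]. Frame index is 0-based in all reported tables and the
#' time of frame i is i / fps seconds.
#'
#' Coordinates follow the raster convention: (row, col), 0-based, origin at
#' the top-left; centroids are real-valued (row, col) pairs.
#'
#' @slot frames list of numeric matrices, identical dimensions, values in
#'   [0, 255].
#' @slot calibration a [Calibration-class].
#' @name FrameSequence-class
#' @aliases FrameSequence-class
#' @exportClass FrameSequence
setClass("FrameSequence",
         representation(frames = "list", calibration = "Calibration"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) == 0) return("empty sequence")
  d <- dim(object@frames[[1]])
  for (f in object@frames) {
    if (!is.matrix(f) || !is.numeric(f)) return("frames must be numeric matrices")
    if (!identical(dim(f), d)) return("inconsistent frame sizes")
  }
  TRUE
})

#' Create a FrameSequence
#'
#' @param frames list of numeric matrices (grayscale, 0..255) with identical
#'   dimensions.
#' @param calibration a [Calibration-class] (default: platform defaults).
#' @return a [FrameSequence-class].
#' @export
FrameSequence <- function(frames, calibration = Calibration()) {
  if (is.matrix(frames)) frames <- list(frames)
  new("FrameSequence", frames = frames, calibration = calibration)
}

#' @describeIn FrameSequence list of frame matrices.
#' @param x a FrameSequence.
#' @export
frames <- function(x) x@frames

#' @describeIn FrameSequence number of frames.
#' @export
nframes <- function(x) length(x@frames)

#' @describeIn FrameSequence the calibration object.
#' @export
calibration <- function(x) x@calibration

#' @export
setMethod("dim", "FrameSequence", function(x) dim(x@frames[[1]]))

#' @export
setMethod("length", "FrameSequence", function(x) length(x@frames))

#' Extract a single frame (1-based list index)
#' @param x a FrameSequence.
#' @param i frame list index (1-based; frame 0 of the video is `x[[1]]`).
#' @export
setMethod("[[", "FrameSequence", function(x, i) x@frames[[i]])

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object)
  cat(sprintf("FrameSequence: %d frame(s) of %d x %d px\n",
              length(object@frames), d[1], d[2]))
  show(object@calibration)
})

#' Convert an image array to grayscale
#'
#' Color arrays (H x W x 3 or 4) are combined with the standard luma weights
#' 0.299 R + 0.587 G + 0.114 B and rounded to the nearest 8-bit level;
#' already-gray matrices pass through unchanged (idempotent).
#'
#' @param img numeric matrix or H x W x C array, values in [0, 255].
#' @return numeric matrix, values in [0, 255].
#' @export
#' @examples
#' toGrayscale(array(c(255, 0, 0), c(1, 1, 3)))  # pure red -> 76
toGrayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(round(g))
  }
  stop("unsupported image shape")
}

#' Load a frame sequence from a directory of numbered images
#'
#' Reads all PNG/TIFF files in a directory, ordered by the number embedded in
#' the file name (lexicographic fallback), converts color frames to grayscale
#' via luma weights, and attaches the calibration. Video containers (MP4/AVI)
#' must be exported to a frame directory first; this keeps test fixtures
#' bit-exact and the package free of codec dependencies.
#'
#' @param path directory containing the frames.
#' @param calibration a [Calibration-class].
#' @return a [FrameSequence-class].
#' @export
loadFrames <- function(path, calibration = Calibration()) {
  if (!file.exists(path)) stop("unreadable path: ", path)
  if (!dir.exists(path)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", path, ignore.case = TRUE))
      stop("video containers are not decoded; export the video to a ",
           "directory of numbered PNG/TIFF frames first")
    stop("path is neither a directory nor a supported input: ", path)
  }
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("empty sequence: no frames found in ", path)
  num <- suppressWarnings(
    as.numeric(sub(".*?(\\d+)\\D*$", "\\1", basename(files))))
  files <- if (anyNA(num)) files[order(basename(files))] else files[order(num)]
  fr <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(f)
    }
    toGrayscale(img * 255)
  })
  d <- lapply(fr, dim)
  if (length(unique(vapply(d, paste, "", collapse = "x"))) > 1)
    stop("inconsistent frame sizes")
  FrameSequence(fr, calibration)
}

#' Write a frame sequence as numbered PNG files
#'
#' Lossless 8-bit output; `loadFrames()` on the result reproduces the pixel
#' values exactly.
#'
#' @param x a [FrameSequence-class] or list of matrices.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
writeFrames <- function(x, dir, prefix = "frame") {
  fr <- if (is(x, "FrameSequence")) frames(x) else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(fr))
  for (i in seq_along(fr)) {
    paths[i] <- file.path(dir, sprintf("%s_%05d.png", prefix, i - 1))
    png::writePNG(clamp(round(fr[[i]]), 0, 255) / 255, paths[i])
  }
  invisible(paths)
}
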