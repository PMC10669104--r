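#' Spatial and temporal calibration of a recording
#'
#' Holds the two constants that turn pixel/frame measurements into physical
#' kinematics: micrometers per pixel and frames per second. Defaults match a
#' hand-held phone-microscope platform (0.074 um/px at roughly 38x
#' magnification, 29.80 fps video).
#'
#' @slot umPerPx micrometers per pixel, > 0.
#' @slot fps frames per second, > 0.
#' @name Calibration-class
#' @aliases Calibration-class
#' @exportClass Calibration
setClass("Calibration", representation(umPerPx = "numeric", fps = "numeric"))

setValidity("Calibration", function(object) {
  if (length(object@umPerPx) != 1 || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    return("umPerPx must be a single positive number")
  if (length(object@fps) != 1 || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' Create a Calibration
#'
#' @param umPerPx micrometers per pixel (default 0.074).
#' @param fps frames per second (default 29.80).
#' @return a [Calibration-class] object.
#' @export
#' @examples
#' Calibration()            # platform defaults
#' Calibration(0.5, 30)     # desk-scale synthetic default
Calibration <- function(umPerPx = 0.074, fps = 29.80) {
  new("Calibration", umPerPx = as.numeric(umPerPx), fps = as.numeric(fps))
}

#' @describeIn Calibration micrometers per pixel.
#' @param x a Calibration.
#' @export
umPerPx <- function(x) x@umPerPx

#' @describeIn Calibration frames per second.
#' @export
fps <- function(x) x@fps

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g um/px, %.4g fps\n",
              object@umPerPx, object@fps))
})

# area thresholds published at 0.074 um/px are physical sizes: rescale by the
# squared pixel-pitch ratio, floored at 2 px (single-pixel components are
# never meaningful objects)
scaleArea <- function(areaPxRef, umPerPx, umPerPxRef = 0.074) {
  max(2, round(areaPxRef * (umPerPxRef / umPerPx)^2))
}

# linear rescale for distances (e.g. assignment gates)
scaleDistance <- function(distPxRef, umPerPx, umPerPxRef = 0.074) {
  distPxRef * umPerPxRef / umPerPx
}
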