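#' Otsu threshold of a grayscale image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the 8-bit
#' image. If several thresholds tie for the maximum (a plateau), the plateau
#' midpoint is returned — a symmetric, deterministic tie-break. The value is
#' reported as a normalized level in [0, 1] (threshold / 255).
#'
#' @param gray numeric matrix, values in [0, 255].
#' @return normalized threshold level in [0, 1].
#' @export
#' @examples
#' img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
#' otsuThreshold(img)  # plateau midpoint: 127/255
otsuThreshold <- function(gray) {
  v <- clamp(floor(as.vector(gray)), 0, 255)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) stop("degenerate histogram: constant image")
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)                      # class {<= t}
  m0 <- cumsum(p * lev)
  mT <- m0[256]
  # sigma^2_B(t) = (mT*w0 - m0)^2 / (w0*(1-w0)) for t = 0..254
  w <- w0[1:255]
  m <- m0[1:255]
  denom <- w * (1 - w)
  sb <- ifelse(denom > 0, (mT * w - m)^2 / denom, 0)
  mx <- max(sb)
  plateau <- which(sb >= mx - 1e-10 * max(mx, 1)) - 1L   # thresholds t
  t_mid <- (min(plateau) + max(plateau)) / 2
  t_mid / 255
}

#' Binarize a grayscale image at a normalized level
#'
#' Bright-object convention: a pixel is foreground iff intensity > level*255.
#'
#' @param gray numeric matrix in [0, 255].
#' @param level normalized threshold in [0, 1].
#' @return binary 0/1 matrix of the same shape.
#' @export
binarize <- function(gray, level) {
  stopifnot(level >= 0, level <= 1)
  (gray > level * 255) + 0
}

#' Fill enclosed holes in a binary mask
#'
#' @param mask binary 0/1 matrix.
#' @return binary matrix with enclosed background regions set to 1.
#' @export
fillHoles <- function(mask) {
  out <- EBImage::fillHull(mask)
  matrix(as.numeric(out > 0), nrow(mask), ncol(mask))
}

#' Morphological opening with a disc element
#'
#' Erosion then dilation with a disc structuring element of the given radius
#' (width 2*radius + 1); separates weakly adhered objects and removes thin
#' bridges. `radius = 0` is the identity.
#'
#' @param mask binary 0/1 matrix.
#' @param radius disc radius in pixels.
#' @return opened binary matrix.
#' @export
morphOpen <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- EBImage::opening(mask, brush)
  matrix(as.numeric(out > 0), nrow(mask), ncol(mask))
}

#' Label 8-connected components
#'
#' EBImage's labeller is 4-connected; diagonally touching labels are merged
#' with a union-find pass so that components follow the 8-connectivity
#' convention used throughout the package.
#'
#' @param mask binary 0/1 matrix.
#' @return integer matrix of component labels (0 = background), relabelled
#'   densely from 1.
#' @export
labelComponents <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  n <- max(L)
  if (n <= 1) return(L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(L); nc <- ncol(L)
  if (nr > 1 && nc > 1) {
    a <- L[-nr, -nc]; b <- L[-1, -1]     # down-right diagonal pairs
    idx <- which(a > 0 & b > 0 & a != b)
    for (k in idx) unite(a[k], b[k])
    a <- L[-1, -nc]; b <- L[-nr, -1]     # up-right diagonal pairs
    idx <- which(a > 0 & b > 0 & a != b)
    for (k in idx) unite(a[k], b[k])
  }
  roots <- vapply(seq_len(n), find, 0L)
  dense <- match(roots, sort(unique(roots)))
  out <- L
  out[L > 0] <- dense[L[L > 0]]
  out
}

#' Remove connected components below a minimum area
#'
#' @param mask binary 0/1 matrix.
#' @param minArea minimum component area in pixels (components with area <
#'   `minArea` are removed); 0 is the identity.
#' @return filtered binary matrix.
#' @export
removeSmall <- function(mask, minArea) {
  stopifnot(minArea >= 0)
  if (minArea <= 1 || !any(mask > 0)) return(mask)
  L <- labelComponents(mask)
  areas <- tabulate(L[L > 0])
  keep <- which(areas >= minArea)
  matrix(as.numeric(L %in% keep & L > 0), nrow(mask), ncol(mask))
}

#' Count total sperm in a single frame
#'
#' The static counting chain: grayscale frame -> Otsu (or fixed-level)
#' binarization -> hole filling -> morphological opening -> impurity removal
#' (area < `minArea`) -> 8-connected component count. Counts moving and
#' stationary cells alike; sub-threshold debris (white blood cells, dust) is
#' removed by the area filter.
#'
#' @param frame numeric matrix in [0, 255] (or a [FrameSequence-class], whose
#'   first frame is used).
#' @param level fixed normalized threshold in [0, 1], or `NULL` to use Otsu.
#' @param openRadius disc radius of the opening (default 1 px).
#' @param minArea minimum object area in px; default is 70 px at the
#'   reference pitch of 0.074 um/px, rescaled by the squared pixel-pitch
#'   ratio for other calibrations.
#' @param polarity `"bright"` for bright objects on a dark background
#'   (default), `"dark"` to invert the frame first.
#' @param calibration a [Calibration-class] used only for the default
#'   `minArea` scaling.
#' @return a list of class `CountResult`: `count`, `detections` (data.frame
#'   with 0-based real-valued centroids), `otsuLevel`, `mask` (final binary
#'   mask).
#' @export
countSperm <- function(frame, level = NULL, openRadius = 1, minArea = NULL,
                       polarity = c("bright", "dark"),
                       calibration = Calibration()) {
  polarity <- match.arg(polarity)
  if (is(frame, "FrameSequence")) {
    calibration <- calibration(frame)
    frame <- frame[[1]]
  }
  if (is.null(minArea)) minArea <- scaleArea(70, umPerPx(calibration))
  g <- if (polarity == "dark") 255 - frame else frame
  lev <- if (is.null(level)) otsuThreshold(g) else level
  mask <- binarize(g, lev)
  mask <- fillHoles(mask)
  mask <- morphOpen(mask, openRadius)
  mask <- removeSmall(mask, minArea)
  det <- extractDetections(mask, frameIndex = 0L, minBlobArea = minArea)
  structure(list(count = nrow(det), detections = det,
                 otsuLevel = lev, mask = mask),
            class = "CountResult")
}

#' @export
print.CountResult <- function(x, ...) {
  cat(sprintf("CountResult: %d object(s), Otsu level %.4f\n",
              x$count, x$otsuLevel))
  invisible(x)
}

#' Per-frame sperm counts for a sequence
#'
#' @param x a [FrameSequence-class].
#' @param ... passed to [countSperm()].
#' @return data.frame with columns `frame` (0-based) and `count`.
#' @export
countFrames <- function(x, ...) {
  counts <- vapply(seq_len(nframes(x)), function(i) {
    countSperm(x[[i]], calibration = calibration(x), ...)$count
  }, 0L)
  data.frame(frame = seq_len(nframes(x)) - 1L, count = counts)
}
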