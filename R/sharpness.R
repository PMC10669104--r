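#' SMD-based sharpness (sum of grayscale difference modulus)
#'
#' Mean absolute difference between each pixel and its left and lower
#' neighbours, summed over in-bounds pairs and divided by the total pixel
#' count M x N. Zero iff the image is constant; invariant to a constant
#' intensity offset.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return non-negative sharpness value.
#' @export
#' @examples
#' sdf(matrix(c(0, 1, 1, 0), 2, 2))  # checkerboard: 1
sdf <- function(img) {
  img <- as.matrix(img)
  if (nrow(img) < 2 || ncol(img) < 2)
    stop("image must be at least 2 x 2")
  dcol <- abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE])
  drow <- abs(img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE])
  (sum(dcol) + sum(drow)) / length(img)
}

# valid (interior) 3 x 3 correlation without padding
conv3 <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr - 2, nc - 2)
  for (i in 1:3) for (j in 1:3) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * img[i:(nr - 3 + i), j:(nc - 3 + j)]
  }
  out
}

#' Tenengrad-based sharpness
#'
#' Squared Sobel gradient magnitude averaged over the image: the two 3 x 3
#' Sobel responses Gx * I and Gy * I give S = sqrt((Gx*I)^2 + (Gy*I)^2) at
#' each interior pixel; TDF = sum(S^2) / (M x N). Border pixels, where the
#' kernel does not fit, are excluded rather than padded (padding choices
#' change values; exclusion is reproducible). `combine = "sum"` selects the
#' plain-sum variant S = Gx*I + Gy*I instead of the gradient magnitude.
#'
#' @param img numeric matrix, at least 3 x 3.
#' @param combine `"magnitude"` (default, Tenengrad) or `"sum"`.
#' @return non-negative sharpness value.
#' @export
tdf <- function(img, combine = c("magnitude", "sum")) {
  combine <- match.arg(combine)
  img <- as.matrix(img)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("image smaller than the 3 x 3 Sobel kernel")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- conv3(img, kx)
  gy <- conv3(img, ky)
  s2 <- if (combine == "magnitude") gx^2 + gy^2 else (gx + gy)^2
  sum(s2) / length(img)
}

#' Sharpness series of a frame sequence
#'
#' Raw SDF and TDF per frame plus max-normalized series in [0, 1] (an
#' all-zero raw series normalizes to all zeros).
#'
#' @param x a [FrameSequence-class] or list of matrices.
#' @param combine passed to [tdf()].
#' @return data.frame: `frame` (0-based), `sdf`, `tdf`, `sdf_norm`,
#'   `tdf_norm`.
#' @export
scoreSharpness <- function(x, combine = "magnitude") {
  fr <- if (is(x, "FrameSequence")) frames(x) else x
  if (length(fr) == 0) stop("empty sequence")
  s <- vapply(fr, sdf, 0)
  t <- vapply(fr, tdf, 0, combine = combine)
  norm <- function(v) if (max(v) > 0) v / max(v) else v * 0
  data.frame(frame = seq_along(fr) - 1L, sdf = s, tdf = t,
             sdf_norm = norm(s), tdf_norm = norm(t))
}
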