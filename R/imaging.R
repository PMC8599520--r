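# Pixel-level primitives: grayscale conversion, fixed thresholding, binary
# morphology (via the compiled kernels in src/) and connected components.
# Images are plain matrices, m[y + 1, x + 1] = pixel (x, y).

#' Convert an RGB image to grayscale
#'
#' Per-pixel weighted sum `0.299 R + 0.589 G + 0.114 B`, kept unrounded.
#' Note the G coefficient: the weights sum to 1.002, so a uniform white
#' image maps to 255.51, slightly above 255.
#'
#' @param rgb Numeric array `height x width x 3`, channels in `[0, 255]`.
#' @return Numeric matrix of gray levels.
#' @export
rgb_to_gray <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a height x width x 3 array", call. = FALSE)
  g <- 0.299 * rgb[, , 1] + 0.589 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(g, nrow = dim(rgb)[1], ncol = dim(rgb)[2])
}

#' Threshold a gray image to binary
#'
#' A pixel becomes 1 when its gray level is strictly greater than
#' `threshold`, 0 otherwise. Under infrared illumination the rat's body is
#' the bright region, so the default 127 separates it from the dark
#' background.
#'
#' @param g Numeric gray matrix.
#' @param threshold Gray-level cut in `[0, 255]`.
#' @return Integer 0/1 matrix of the same size.
#' @export
binarize <- function(g, threshold = 127) {
  stopifnot(is.matrix(g), threshold >= 0, threshold <= 255)
  matrix(as.integer(g > threshold), nrow = nrow(g), ncol = ncol(g))
}

#' Square all-ones structuring element
#'
#' @param size Odd side length; the anchor is the geometric center.
#' @return Integer matrix of ones with an `anchor` attribute `c(x, y)`
#'   (0-based column/row within the element).
#' @export
structuring_element <- function(size = 5) {
  stopifnot(size >= 1)
  se <- matrix(1L, nrow = size, ncol = size)
  attr(se, "anchor") <- c((size - 1) %/% 2, (size - 1) %/% 2)
  se
}

.se_anchor <- function(se) {
  a <- attr(se, "anchor")
  if (is.null(a)) a <- c((ncol(se) - 1) %/% 2, (nrow(se) - 1) %/% 2)
  a
}

.check_binary <- function(a) {
  if (!is.matrix(a)) stop("expected a matrix", call. = FALSE)
  storage.mode(a) <- "integer"
  a
}

#' Binary erosion
#'
#' Set-theoretic erosion with the reflected structuring element: output
#' pixel z is 1 when every element position translated to z (through the
#' reflection of `se` about its anchor) lands on a 1 of `a`. Pixels outside
#' the image count as 0, so foreground touching the border is eroded away.
#'
#' @param a Integer 0/1 matrix.
#' @param se Structuring element (0/1 matrix, see [structuring_element()]);
#'   must contain at least one 1.
#' @return Integer 0/1 matrix.
#' @export
img_erode <- function(a, se = structuring_element(5)) {
  a <- .check_binary(a); se <- .check_binary(se)
  if (sum(se) < 1) stop("structuring element must contain a 1", call. = FALSE)
  an <- .se_anchor(se)
  cpp_erode(a, se, an[1], an[2])
}

#' Binary dilation
#'
#' Output pixel z is 1 when the reflected structuring element translated to
#' z hits at least one 1 of `a`.
#'
#' @inheritParams img_erode
#' @return Integer 0/1 matrix.
#' @export
img_dilate <- function(a, se = structuring_element(5)) {
  a <- .check_binary(a); se <- .check_binary(se)
  if (sum(se) < 1) stop("structuring element must contain a 1", call. = FALSE)
  an <- .se_anchor(se)
  cpp_dilate(a, se, an[1], an[2])
}

#' Binary opening
#'
#' Erosion followed by dilation with the same element. Removes bright
#' components too small to contain a translate of the element (for the
#' default 5x5 square: dropping-sized noise spots) while restoring the
#' extent of the survivors.
#'
#' @inheritParams img_erode
#' @return Integer 0/1 matrix.
#' @export
img_open <- function(a, se = structuring_element(5)) {
  img_dilate(img_erode(a, se), se)
}

#' Pixelwise AND of two binary images
#'
#' @param a,b Integer 0/1 matrices of identical size.
#' @return Integer 0/1 matrix.
#' @export
intersect_images <- function(a, b) {
  a <- .check_binary(a); b <- .check_binary(b)
  if (!all(dim(a) == dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  a * b
}

#' Extract 8-connected white components
#'
#' Finds all maximal 8-connected components of 1-pixels with their areas
#' and centroids, ordered by descending area; ties broken by the smaller
#' (y, then x) of each component's topmost-leftmost pixel.
#'
#' @param a Integer 0/1 matrix.
#' @return A tibble with one row per component: `label` (index into the
#'   label matrix), `area` (pixel count), `x`, `y` (real-valued centroid,
#'   0-based pixel coordinates), `top_y`, `top_x` (topmost-leftmost pixel).
#'   The label matrix (0 = background) is attached as attribute `labels`.
#' @export
extract_components <- function(a) {
  a <- .check_binary(a)
  lab <- cpp_label8(a)
  n <- max(lab)
  if (n == 0) {
    out <- tibble::tibble(label = integer(), area = integer(),
                          x = double(), y = double(),
                          top_y = integer(), top_x = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  ys <- (idx - 1L) %% nrow(a)        # 0-based row = y
  xs <- (idx - 1L) %/% nrow(a)       # 0-based col = x
  area <- tabulate(lv, nbins = n)
  cx <- as.vector(tapply(xs, lv, mean))
  cy <- as.vector(tapply(ys, lv, mean))
  # first pixel in raster-scan (row-major) order
  ord_first <- order(ys, xs)
  first <- !duplicated(lv[ord_first])
  top_y <- ys[ord_first][first][order(lv[ord_first][first])]
  top_x <- xs[ord_first][first][order(lv[ord_first][first])]
  out <- tibble::tibble(label = seq_len(n), area = area,
                        x = cx, y = cy,
                        top_y = as.integer(top_y), top_x = as.integer(top_x))
  out <- out[order(-out$area, out$top_y, out$top_x), ]
  attr(out, "labels") <- lab
  out
}
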