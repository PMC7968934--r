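#' Raster containers
#'
#' Images are plain numeric arrays on the 8-bit intensity scale: a
#' `ColorImage` is a `height x width x 3` array with channels R, G, B in
#' `[0, 255]`; a `GrayImage` is a `height x width` matrix in `[0, 255]`
#' (real-valued); a `LabImage` is a `height x width x 3` array of CIELAB
#' coordinates (`L` in `[0, 100]` for valid sRGB input, `a`/`b` unbounded).
#' `color_image()` validates and tags an array; validation is cheap and
#' every pipeline entry point applies it.
#'
#' @param x numeric array, `height x width x 3`, values in `[0, 255]`.
#' @return `x`, validated, with class `"color_image"`.
#' @examples
#' img <- color_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
#' @export
color_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("a ColorImage must be a height x width x 3 array (channels R,G,B)")
  if (!is.numeric(x) || anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("ColorImage values must be numeric in [0, 255]")
  structure(x, class = c("color_image", class(unclass(x))))
}

assert_color_image <- function(x) {
  if (inherits(x, "color_image")) return(x)
  color_image(x)
}

# sRGB (D65) -> XYZ matrix, IEC 61966-2-1 primaries
.srgb2xyz <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227), nrow = 3, byrow = TRUE)
.d65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)  # 2-degree observer

#' Convert an RGB image to CIELAB
#'
#' Standard closed-form chain: 8-bit sRGB values are linearized (inverse
#' sRGB companding), mapped to CIE XYZ with the D65 white point, and then to
#' L*a*b*.  The camera encoding is assumed to be sRGB/D65; the conversion is
#' a fixed, documented embedding — pixel clustering only requires that it be
#' consistent, not radiometrically exact.
#'
#' @param img a [color_image()] (or coercible array).
#' @return `height x width x 3` array of (L, a, b), class `"lab_image"`.
#' @examples
#' rgb_to_lab(color_image(array(c(0, 255), dim = c(1, 2, 3))))[1, , 1]
#' @export
rgb_to_lab <- function(img) {
  img <- assert_color_image(img)
  d <- dim(img)
  v <- matrix(as.numeric(img), ncol = 3L) / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  xyz <- sweep(xyz, 2L, .d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3]))
  out <- array(lab, dim = d)
  class(out) <- c("lab_image", class(unclass(out)))
  out
}

# Rec. 709 luminance weights (match common grayscale conversions of
# camera output; recorded in the pipeline config for reproducibility)
.gray_weights <- c(r = 0.2125, g = 0.7154, b = 0.0721)

#' Convert an RGB image to grayscale luminance
#'
#' Weighted luminance `Y = 0.2125 R + 0.7154 G + 0.0721 B` (Rec. 709
#' weights), kept real-valued on the `[0, 255]` scale.
#'
#' @inheritParams rgb_to_lab
#' @return `height x width` numeric matrix in `[0, 255]`.
#' @examples
#' rgb_to_gray(color_image(array(255, dim = c(1, 1, 3))))
#' @export
rgb_to_gray <- function(img) {
  img <- assert_color_image(img)
  w <- .gray_weights
  d <- dim(img)
  matrix(img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3],
         d[1], d[2])
}
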