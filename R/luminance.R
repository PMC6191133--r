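## sRGB (D65) -> CIE XYZ -> CIELAB L*. Only the lightness channel is
## needed downstream, so the a*/b* chroma axes are never computed.

## Rec. 709 / IEC 61966-2-1 luminance weights for linear sRGB
.SRGB_Y <- c(0.2126729, 0.7151522, 0.0721750)

.srgbToLinear <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.linearToSrgb <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.labF <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.labFinv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

#' Perceptual lightness (CIELAB L*) of an RGB image
#'
#' Converts an 8-bit sRGB image (D65 white point) to its CIELAB L*
#' channel, the representation on which uncapped-cell segmentation is most
#' reliable: L* tracks human-perceived brightness, and uncapped lumens are
#' the darkest structures on a comb under all common lighting conditions.
#'
#' @param image an \code{EBImage::Image} in colour mode, a width x height
#'   x 3 array with values in \[0, 1\], or an integer array with values in
#'   0..255.
#' @return numeric width x height matrix of L* values in \[0, 100\].
#' @examples
#' img <- array(1, dim = c(4, 4, 3))  # white
#' range(toLuminance(img))            # 100 100
#' @export
toLuminance <- function(image) {
  a <- if (is(image, "Image")) EBImage::imageData(image) else image
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    invalidImage("expected an RGB image with exactly 3 channels")
  a <- a * 1.0
  if (max(a) > 1 + 1e-9) a <- a / 255   # 8-bit integer encoding
  if (min(a) < -1e-9 || max(a) > 1 + 1e-9)
    invalidImage("channel values must be in [0, 1] or 0..255")
  lin <- .srgbToLinear(a)
  Y <- .SRGB_Y[1] * lin[, , 1] + .SRGB_Y[2] * lin[, , 2] + .SRGB_Y[3] * lin[, , 3]
  Y <- Y / sum(.SRGB_Y)   # normalise to the white point (L*(white) = 100 exactly)
  116 * .labF(Y) - 16
}

## Inverse map used by the synthetic renderer: desired L* -> the grey
## sRGB value v (in [0, 1]) with R=G=B=v whose lightness is L*.
.srgbGreyFromL <- function(L) {
  Y <- .labFinv((L + 16) / 116)
  pmin(1, pmax(0, .linearToSrgb(Y)))
}
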