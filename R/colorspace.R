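# Colour-space conversions used throughout the pipeline.
#
# All conversions assume the sRGB primaries and companding of IEC 61966-2-1
# with a D65/2-degree white point, the de-facto standard for consumer digital
# cameras. They are defined pixelwise and accept a single triplet (length-3
# vector), a set of triplets (n x 3 matrix), or a raster (H x W x 3 array),
# returning the same shape.

# sRGB (linear) -> XYZ, IEC 61966-2-1 / Rec. 709 primaries, D65
.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# D65 reference white in XYZ, taken as the image of sRGB white under the
# matrix above so that achromatic sRGB maps exactly onto the achromatic axis
.white_d65 <- rowSums(.srgb_to_xyz_mat)
names(.white_d65) <- c("X", "Y", "Z")

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

# Coerce triplet/matrix/raster input to an n x 3 matrix, remembering shape.
.as_triplets <- function(x, what = "colour input") {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] != 3L) stop(what, " raster must have 3 channels")
    list(m = matrix(x, ncol = 3L), dim = dim(x))
  } else if (is.matrix(x)) {
    if (ncol(x) != 3L) stop(what, " matrix must have 3 columns")
    list(m = x, dim = NULL)
  } else if (is.numeric(x) && length(x) == 3L) {
    list(m = matrix(x, nrow = 1L), dim = -1L)
  } else {
    stop(what, " must be a length-3 vector, an n x 3 matrix or an H x W x 3 array")
  }
}

.restore_shape <- function(m, shape) {
  if (is.null(shape$dim)) {
    dimnames(m) <- NULL
    m
  } else if (identical(shape$dim, -1L)) {
    as.vector(m)
  } else {
    array(m, dim = shape$dim)
  }
}

.check_srgb8 <- function(m) {
  if (anyNA(m)) stop("sRGB input contains missing values")
  if (min(m) < -1e-8 || max(m) > 255 + 1e-8) {
    stop("sRGB channel values must lie in [0, 255]; got range [",
         signif(min(m), 4), ", ", signif(max(m), 4), "]")
  }
}

# sRGB electro-optical transfer: 8-bit encoded -> linear [0,1]
.srgb_decompand <- function(v) {
  s <- v / 255
  ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
}

.srgb_compand <- function(lin) {
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  v * 255
}

.srgb8_to_xyz <- function(m) {
  .srgb_decompand(m) %*% t(.srgb_to_xyz_mat)
}

# CIE 1976 f() with the linear toe below (6/29)^3
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert sRGB colours to CIELAB
#'
#' Standard sRGB (IEC 61966-2-1) to CIE 1976 L*a*b* conversion via XYZ with a
#' D65/2-degree white point. This is the working space in which the
#' colour-correction model is fitted.
#'
#' @param x Colours in 8-bit sRGB, channels in `[0, 255]`: a length-3 vector,
#'   an `n x 3` matrix (one colour per row), or an `H x W x 3` array. Values
#'   need not be integers.
#' @return The converted colours in the same shape as `x`. L* lies in
#'   `[0, 100]`; a* and b* are unbounded opponent axes.
#' @examples
#' srgb_to_lab(c(255, 255, 255))  # reference white: (100, 0, 0)
#' srgb_to_lab(c(128, 128, 128))  # mid grey, achromatic: a* = b* = 0
#' @seealso [lab_to_srgb()], [srgb_to_luv()], [srgb_to_hsv()]
#' @export
srgb_to_lab <- function(x) {
  shape <- .as_triplets(x, "sRGB")
  .check_srgb8(shape$m)
  xyz <- .srgb8_to_xyz(shape$m)
  fx <- .lab_f(xyz[, 1] / .white_d65[1])
  fy <- .lab_f(xyz[, 2] / .white_d65[2])
  fz <- .lab_f(xyz[, 3] / .white_d65[3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  .restore_shape(lab, shape)
}

#' Convert CIELAB colours to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut results are clipped to
#' `[0, 255]` per channel; whether any clipping occurred is recorded in the
#' `"clipped"` attribute of the result (clipping is defined behaviour, not an
#' error).
#'
#' @param x Colours in CIELAB, same accepted shapes as [srgb_to_lab()].
#' @return 8-bit sRGB colours in the shape of `x`, with a logical
#'   `"clipped"` attribute.
#' @export
lab_to_srgb <- function(x) {
  shape <- .as_triplets(x, "Lab")
  m <- shape$m
  if (anyNA(m)) stop("Lab input contains missing values")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx) * .white_d65[1],
               .lab_f_inv(fy) * .white_d65[2],
               .lab_f_inv(fz) * .white_d65[3])
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  clipped <- any(lin < -1e-9 | lin > 1 + 1e-9)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- .restore_shape(.srgb_compand(lin), shape)
  attr(out, "clipped") <- clipped
  out
}

#' Convert sRGB colours to CIELUV
#'
#' Standard sRGB to CIE 1976 L*u*v* with a D65/2-degree white. The (u, v)
#' chromaticity pair is the feature space used for plant/background
#' segmentation.
#'
#' @inheritParams srgb_to_lab
#' @return Converted colours in the shape of `x` (L*, u*, v*).
#' @export
srgb_to_luv <- function(x) {
  shape <- .as_triplets(x, "sRGB")
  .check_srgb8(shape$m)
  xyz <- .srgb8_to_xyz(shape$m)
  denom <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  up <- ifelse(denom > 0, 4 * xyz[, 1] / denom, 0)
  vp <- ifelse(denom > 0, 9 * xyz[, 2] / denom, 0)
  wd <- .white_d65[1] + 15 * .white_d65[2] + 3 * .white_d65[3]
  upn <- 4 * .white_d65[1] / wd
  vpn <- 9 * .white_d65[2] / wd
  L <- 116 * .lab_f(xyz[, 2] / .white_d65[2]) - 16
  luv <- cbind(L, 13 * L * (up - upn), 13 * L * (vp - vpn))
  .restore_shape(luv, shape)
}

#' Convert sRGB colours to HSV
#'
#' Hue, saturation and value, each scaled to `[0, 1]` (hue wraps). Used as an
#' optional feature space for NDVI prediction from mean canopy colour.
#'
#' @inheritParams srgb_to_lab
#' @return Converted colours in the shape of `x`.
#' @export
srgb_to_hsv <- function(x) {
  shape <- .as_triplets(x, "sRGB")
  .check_srgb8(shape$m)
  m <- shape$m / 255
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  d <- mx - mn
  h <- numeric(nrow(m))
  nz <- d > 0
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  .restore_shape(cbind(h, s, mx), shape)
}
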