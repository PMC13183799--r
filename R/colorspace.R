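# Color representations and perceptual difference metrics.
#
# All color operations accept either a length-3 vector or an N x 3 matrix and
# are fully vectorized. Everything is computed in double precision.

#' D65 2-degree reference white
#'
#' Tristimulus values of the CIE standard illuminant D65 for the 2-degree
#' observer, normalized so that Y = 100. This is the default adapting white
#' for all CIELAB conversions in the package; the display characterization of
#' a particular apparatus can be substituted through the `white` arguments.
#'
#' @return Named numeric vector with components `X`, `Y`, `Z`.
#' @export
white_d65 <- function() {
  c(X = 95.047, Y = 100, Z = 108.883)
}

# Coerce colors to an N x 3 matrix; remembers whether input was a bare vector.
as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(what, " must be a length-3 vector or an N x 3 matrix", call. = FALSE)
    }
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
    storage.mode(x) <- "double"
  }
  if (!all(is.finite(x))) {
    stop("non-finite values in ", what, call. = FALSE)
  }
  x
}

drop_if_vector <- function(m, template) {
  if (is.null(dim(template))) drop(m[1L, ]) else m
}

check_white <- function(white) {
  white <- as.numeric(white)
  if (length(white) != 3L || !all(is.finite(white)) || any(white <= 0)) {
    stop("white point must be three strictly positive finite values",
         call. = FALSE)
  }
  white
}

# CIE 1976 cube-root companding and its inverse.
lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_f_inv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert XYZ tristimulus values to CIELAB
#'
#' Standard CIE 1976 L*a*b* forward transform relative to an adapting white.
#' The reference white maps to (L = 100, a = 0, b = 0) and zero maps to
#' (0, 0, 0).
#'
#' @param xyz Length-3 vector or N x 3 matrix of tristimulus values, on the
#'   scale where the reference white has Y = 100.
#' @param white Adapting white point (XYZ), strictly positive.
#' @return Lab values in the same shape as the input.
#' @export
xyz_to_lab <- function(xyz, white = white_d65()) {
  white <- check_white(white)
  m <- as_color_matrix(xyz, "xyz")
  fx <- lab_f(m[, 1] / white[1])
  fy <- lab_f(m[, 2] / white[2])
  fz <- lab_f(m[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  drop_if_vector(out, xyz)
}

#' Convert CIELAB to XYZ tristimulus values
#'
#' Inverse of [xyz_to_lab()]; exact on the gamut interior.
#'
#' @param lab Length-3 vector or N x 3 matrix of Lab values.
#' @param white Adapting white point (XYZ), strictly positive.
#' @return XYZ values in the same shape as the input.
#' @export
lab_to_xyz <- function(lab, white = white_d65()) {
  white <- check_white(white)
  m <- as_color_matrix(lab, "lab")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(X = white[1] * lab_f_inv(fx),
               Y = white[2] * lab_f_inv(fy),
               Z = white[3] * lab_f_inv(fz))
  drop_if_vector(out, lab)
}

#' Default linear RGB to XYZ primaries matrix
#'
#' The sRGB/BT.709 primaries with a D65 white, scaled so that RGB (1, 1, 1)
#' maps to the D65 white with Y = 100. Any invertible 3 x 3 matrix may be
#' used in its place to model a different (e.g. measured) display.
#'
#' @return 3 x 3 matrix mapping linear RGB column vectors to XYZ.
#' @export
srgb_primaries <- function() {
  100 * matrix(c(0.4124564, 0.3575761, 0.1804375,
                 0.2126729, 0.7151522, 0.0721750,
                 0.0193339, 0.1191920, 0.9503041),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Convert linear RGB to XYZ
#'
#' Applies a linear primaries matrix; no transfer function is assumed, so the
#' input must be linear-light RGB. (1, 1, 1) maps to the row sums of the
#' matrix, i.e. the display white.
#'
#' @param rgb Length-3 vector or N x 3 matrix of linear RGB values.
#' @param primaries Invertible 3 x 3 RGB-to-XYZ matrix.
#' @return XYZ values in the same shape as the input.
#' @export
linear_rgb_to_xyz <- function(rgb, primaries = srgb_primaries()) {
  primaries <- as.matrix(primaries)
  if (!all(dim(primaries) == c(3L, 3L)) || !all(is.finite(primaries))) {
    stop("primaries must be a finite 3 x 3 matrix", call. = FALSE)
  }
  if (abs(det(primaries)) < 1e-12) {
    stop("primaries matrix is singular", call. = FALSE)
  }
  m <- as_color_matrix(rgb, "rgb")
  out <- m %*% t(primaries)
  colnames(out) <- c("X", "Y", "Z")
  drop_if_vector(out, rgb)
}

#' Convert XYZ to linear RGB
#'
#' Inverse of [linear_rgb_to_xyz()] under the same primaries matrix.
#'
#' @inheritParams linear_rgb_to_xyz
#' @param xyz Length-3 vector or N x 3 matrix of tristimulus values.
#' @return Linear RGB values in the same shape as the input.
#' @export
xyz_to_linear_rgb <- function(xyz, primaries = srgb_primaries()) {
  primaries <- as.matrix(primaries)
  if (abs(det(primaries)) < 1e-12) {
    stop("primaries matrix is singular", call. = FALSE)
  }
  m <- as_color_matrix(xyz, "xyz")
  out <- m %*% t(solve(primaries))
  colnames(out) <- c("R", "G", "B")
  drop_if_vector(out, xyz)
}

#' Convert linear RGB directly to CIELAB
#'
#' Convenience composition of [linear_rgb_to_xyz()] and [xyz_to_lab()].
#'
#' @inheritParams linear_rgb_to_xyz
#' @param white Adapting white point (XYZ).
#' @return Lab values in the same shape as the input.
#' @export
linear_rgb_to_lab <- function(rgb, white = white_d65(),
                              primaries = srgb_primaries()) {
  xyz_to_lab(linear_rgb_to_xyz(rgb, primaries), white)
}

#' Convert CIELAB to linear RGB
#'
#' Convenience composition of [lab_to_xyz()] and [xyz_to_linear_rgb()].
#'
#' @inheritParams xyz_to_linear_rgb
#' @param lab Length-3 vector or N x 3 matrix of Lab values.
#' @param white Adapting white point (XYZ).
#' @return Linear RGB values in the same shape as the input.
#' @export
lab_to_linear_rgb <- function(lab, white = white_d65(),
                              primaries = srgb_primaries()) {
  xyz_to_linear_rgb(lab_to_xyz(lab, white), primaries)
}

#' CIELAB chroma
#'
#' C* = sqrt(a^2 + b^2); independent of L and invariant to a simultaneous
#' sign flip of (a, b).
#'
#' @param lab Length-3 vector or N x 3 matrix of Lab values.
#' @return Numeric vector of chroma values, one per color.
#' @export
chroma <- function(lab) {
  m <- as_color_matrix(lab, "lab")
  sqrt(m[, 2]^2 + m[, 3]^2)
}

#' CIEDE2000 color difference
#'
#' The full CIEDE2000 formula, including the lightness/chroma/hue weighting
#' functions and the rotation term that couples the chroma and hue
#' differences in the blue region. Parametric factors kL = kC = kH = 1.
#' Vectorized over rows; the two inputs are recycled to a common length.
#'
#' @param lab1,lab2 Length-3 vectors or N x 3 matrices of Lab values.
#' @return Numeric vector of color differences (>= 0, zero iff the inputs
#'   are identical).
#' @export
ciede2000 <- function(lab1, lab2) {
  m1 <- as_color_matrix(lab1, "lab1")
  m2 <- as_color_matrix(lab2, "lab2")
  n <- max(nrow(m1), nrow(m2))
  if (nrow(m1) != n) m1 <- m1[rep_len(seq_len(nrow(m1)), n), , drop = FALSE]
  if (nrow(m2) != n) m2 <- m2[rep_len(seq_len(nrow(m2)), n), , drop = FALSE]

  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hp <- function(a, b) {
    h <- atan2(b, a) * 180 / pi
    h[h < 0] <- h[h < 0] + 360
    h[a == 0 & b == 0] <- 0
    h
  }
  h1p <- hp(a1p, b1)
  h2p <- hp(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p

  # hue difference with wrap-around; undefined (zero) when either chroma is 0
  dhp <- h2p - h1p
  dhp[dhp > 180] <- dhp[dhp > 180] - 360
  dhp[dhp < -180] <- dhp[dhp < -180] + 360
  zeroC <- C1p * C2p == 0
  dhp[zeroC] <- 0
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2

  hsum <- h1p + h2p
  hbp <- hsum / 2
  big <- abs(h1p - h2p) > 180
  hbp[big & hsum < 360] <- hbp[big & hsum < 360] + 180
  hbp[big & hsum >= 360] <- hbp[big & hsum >= 360] - 180
  hbp[zeroC] <- hsum[zeroC]

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)

  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}
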