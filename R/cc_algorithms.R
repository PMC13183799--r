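# Classical statistics-based illuminant estimation and diagonal white
# balancing: gray world, white patch, shades of gray, (weighted) gray edge.
#
# All estimators return a unit-L2 illuminant direction; pixels at the clip
# ceiling are excluded from the statistics because clipping corrupts both
# mean- and max-based estimates.

#' Construct an illuminant estimate
#'
#' @param rgb Length-3 direction; normalized to unit L2 norm unless
#'   degenerate.
#' @param method Name of the estimator.
#' @param params Parameter list used.
#' @param degenerate Logical; `TRUE` when the image carried no usable signal
#'   for the estimator (e.g. all-zero image, edgeless image for gray edge).
#' @return Object of class `illuminant_estimate`.
#' @export
illuminant_estimate <- function(rgb, method, params = list(),
                                degenerate = FALSE) {
  if (!degenerate) {
    rgb <- as.numeric(rgb)
    nrm <- sqrt(sum(rgb^2))
    if (!is.finite(nrm) || nrm <= 0) {
      degenerate <- TRUE
      rgb <- rep(NA_real_, 3)
    } else {
      rgb <- rgb / nrm
    }
  } else {
    rgb <- rep(NA_real_, 3)
  }
  structure(list(rgb = rgb, method = method, params = params,
                 degenerate = degenerate),
            class = "illuminant_estimate")
}

#' @export
print.illuminant_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<illuminant_estimate %s: degenerate>\n", x$method))
  } else {
    cat(sprintf("<illuminant_estimate %s: (%.4f, %.4f, %.4f)>\n",
                x$method, x$rgb[1], x$rgb[2], x$rgb[3]))
  }
  invisible(x)
}

check_image <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  if (!all(is.finite(image)) || any(image < 0)) {
    stop("image must be finite and non-negative", call. = FALSE)
  }
  image
}

# logical matrix of pixels to keep (below the clip ceiling in all channels)
unsaturated_mask <- function(image, ceiling = 1) {
  !apply(image >= ceiling - 1e-6, c(1, 2), any)
}

channel_vectors <- function(image, keep) {
  lapply(1:3, function(k) image[, , k][keep])
}

#' Gray world illuminant estimate
#'
#' Assumes the average scene reflectance is achromatic: the illuminant
#' direction is the per-channel spatial mean of the image.
#'
#' @param image H x W x 3 linear RGB array, non-negative.
#' @param exclude_saturated Drop pixels at the clip ceiling from the
#'   statistics.
#' @return An `illuminant_estimate`.
#' @export
gray_world <- function(image, exclude_saturated = TRUE) {
  image <- check_image(image)
  keep <- if (exclude_saturated) unsaturated_mask(image) else
    matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(keep)) keep[] <- TRUE
  est <- vapply(channel_vectors(image, keep), mean, numeric(1))
  illuminant_estimate(est, "gray_world",
                      degenerate = all(est == 0))
}

#' White patch (max-RGB) illuminant estimate
#'
#' Assumes the brightest patch is a perfect white reflector: the illuminant
#' direction is the per-channel maximum.
#'
#' @inheritParams gray_world
#' @return An `illuminant_estimate`.
#' @export
white_patch <- function(image, exclude_saturated = TRUE) {
  image <- check_image(image)
  keep <- if (exclude_saturated) unsaturated_mask(image) else
    matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(keep)) keep[] <- TRUE
  est <- vapply(channel_vectors(image, keep), max, numeric(1))
  illuminant_estimate(est, "white_patch",
                      degenerate = all(est == 0))
}

#' Shades-of-gray illuminant estimate
#'
#' Minkowski p-norm generalization bridging gray world (p = 1) and white
#' patch (p -> infinity): the illuminant direction is the per-channel
#' p-norm mean `mean(x^p)^(1/p)`.
#'
#' @inheritParams gray_world
#' @param p Minkowski order, >= 1. Default 6, the usual literature choice.
#' @return An `illuminant_estimate`.
#' @export
shades_of_gray <- function(image, p = 6, exclude_saturated = TRUE) {
  image <- check_image(image)
  if (!is.finite(p) || p < 1) stop("p must be >= 1", call. = FALSE)
  keep <- if (exclude_saturated) unsaturated_mask(image) else
    matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(keep)) keep[] <- TRUE
  chans <- channel_vectors(image, keep)
  # normalize by the max first for numerical stability at large p
  m <- max(vapply(chans, max, numeric(1)))
  if (m == 0) {
    return(illuminant_estimate(NULL, "shades_of_gray", list(p = p),
                               degenerate = TRUE))
  }
  est <- vapply(chans, function(x) m * mean((x / m)^p)^(1 / p), numeric(1))
  illuminant_estimate(est, "shades_of_gray", list(p = p))
}

# --- Gaussian (derivative) filtering ---------------------------------------

gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(-x / sigma^2 * g)
  if (order == 2) return((x^2 - sigma^2) / sigma^4 * g)
  stop("derivative order must be 0, 1 or 2", call. = FALSE)
}

# Separable convolution of a matrix with 1-D kernels along rows (ky) and
# columns (kx), with replicate padding. Implemented as shift-and-accumulate.
convolve_sep <- function(m, ky, kx) {
  conv_dim <- function(m, k, along) {
    r <- (length(k) - 1L) %/% 2L
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate padding
      shifted <- if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      out <- out + k[j] * shifted
    }
    out
  }
  conv_dim(conv_dim(m, ky, 1), kx, 2)
}

# Per-channel Gaussian-derivative gradient magnitude of an image.
gradient_magnitude <- function(image, sigma = 1, order = 1) {
  g0 <- gauss_kernel(sigma, 0)
  g1 <- gauss_kernel(sigma, order)
  lapply(1:3, function(k) {
    dx <- convolve_sep(image[, , k], g0, g1)
    dy <- convolve_sep(image[, , k], g1, g0)
    sqrt(dx^2 + dy^2)
  })
}

#' Gray edge illuminant estimate
#'
#' Assumes the average color difference at edges is achromatic: the
#' illuminant direction is the per-channel Minkowski mean of
#' Gaussian-derivative gradient magnitudes. A spatially constant image has
#' no edges and yields a flagged degenerate estimate.
#'
#' @inheritParams gray_world
#' @param p Minkowski order (default 1).
#' @param sigma Gaussian smoothing scale in pixels (default 1).
#' @param order Derivative order, 1 or 2.
#' @return An `illuminant_estimate`.
#' @export
gray_edge <- function(image, p = 1, sigma = 1, order = 1,
                      exclude_saturated = TRUE) {
  image <- check_image(image)
  if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
  if (!is.finite(p) || p < 1) stop("p must be >= 1", call. = FALSE)
  if (min(dim(image)[1:2]) <= 2 * ceiling(3 * sigma) + 1) {
    stop("image smaller than the smoothing kernel", call. = FALSE)
  }
  grads <- gradient_magnitude(image, sigma, order)
  keep <- if (exclude_saturated) unsaturated_mask(image) else
    matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(keep)) keep[] <- TRUE
  vals <- lapply(grads, function(g) g[keep])
  m <- max(vapply(vals, max, numeric(1)))
  if (m <= 1e-12) {
    return(illuminant_estimate(NULL, "gray_edge",
                               list(p = p, sigma = sigma, order = order),
                               degenerate = TRUE))
  }
  est <- vapply(vals, function(x) m * mean((x / m)^p)^(1 / p), numeric(1))
  illuminant_estimate(est, "gray_edge",
                      list(p = p, sigma = sigma, order = order))
}

#' Weighted gray edge illuminant estimate
#'
#' As [gray_edge()], but each pixel's contribution is scaled by a monotone
#' power of its overall gradient magnitude, emphasizing prominent edges over
#' noise and minor texture. `weight_exponent = 0` reduces exactly to the
#' unweighted gray edge.
#'
#' @inheritParams gray_edge
#' @param weight_exponent Non-negative exponent on the normalized total
#'   gradient magnitude (default 2).
#' @return An `illuminant_estimate`.
#' @export
weighted_gray_edge <- function(image, p = 1, sigma = 1, weight_exponent = 2,
                               order = 1, exclude_saturated = TRUE) {
  image <- check_image(image)
  if (weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  if (min(dim(image)[1:2]) <= 2 * ceiling(3 * sigma) + 1) {
    stop("image smaller than the smoothing kernel", call. = FALSE)
  }
  grads <- gradient_magnitude(image, sigma, order)
  keep <- if (exclude_saturated) unsaturated_mask(image) else
    matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(keep)) keep[] <- TRUE
  total <- sqrt(grads[[1]]^2 + grads[[2]]^2 + grads[[3]]^2)
  tmax <- max(total[keep])
  if (tmax <= 1e-12) {
    return(illuminant_estimate(NULL, "weighted_gray_edge",
                               list(p = p, sigma = sigma,
                                    weight_exponent = weight_exponent,
                                    order = order),
                               degenerate = TRUE))
  }
  w <- (total / tmax)^weight_exponent
  vals <- lapply(grads, function(g) (w * g)[keep])
  m <- max(vapply(vals, max, numeric(1)))
  est <- vapply(vals, function(x) m * mean((x / m)^p)^(1 / p), numeric(1))
  illuminant_estimate(est, "weighted_gray_edge",
                      list(p = p, sigma = sigma,
                           weight_exponent = weight_exponent, order = order))
}

#' Diagonal white balance correction
#'
#' Divides each channel by the estimated illuminant direction, then rescales
#' globally so the image's mean luminance (channel average) is preserved. A
#' surface whose color equals the estimate maps to neutral (equal channels).
#'
#' @param image H x W x 3 linear RGB array.
#' @param est An `illuminant_estimate` (must not be degenerate).
#' @return Corrected H x W x 3 array.
#' @export
white_balance <- function(image, est) {
  image <- check_image(image)
  stopifnot(inherits(est, "illuminant_estimate"))
  if (est$degenerate) {
    stop("cannot white balance with a degenerate estimate", call. = FALSE)
  }
  out <- image
  for (k in 1:3) out[, , k] <- image[, , k] / est$rgb[k]
  lum_in <- mean(image)
  lum_out <- mean(out)
  if (lum_out > 0) out <- out * (lum_in / lum_out)
  out
}

#' Angular error between two chromatic directions
#'
#' The angle, in degrees, between two RGB vectors; the standard accuracy
#' measure for illuminant estimation.
#'
#' @param u,v Length-3 non-zero vectors.
#' @return Angle in degrees.
#' @export
angular_error <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}
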