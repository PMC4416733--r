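erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfinv <- function(p) stats::qnorm((1 + p) / 2) / sqrt(2)

#' Integrated-Gaussian sampling kernel
#'
#' Builds the separable 1-D filter that sizes the LBP sampling support to the
#' adapted radius \eqn{\lambda}. The filter radius is
#' \eqn{g_r = \lambda\pi/n} (the half-distance between adjacent neighbors on
#' the sampling circle) and the Gaussian standard deviation is chosen so
#' that a fraction \code{P} of the Gaussian mass falls inside
#' \eqn{[-g_r, g_r]}: \eqn{\sigma_g = g_r / (\sqrt{2}\,\mathrm{erf}^{-1}(P))}.
#' Because \eqn{\sigma_g} is often well below one pixel, coefficients are
#' obtained by integrating the Gaussian over unit pixel bins via the error
#' function rather than by point sampling.
#'
#' @param lambda adapted LBP radius, pixels.
#' @param n number of LBP neighbors.
#' @param P Gaussian mass captured inside the filter radius (default 0.99).
#' @return list with \code{gr}, \code{sigmaG} and the normalized symmetric
#'   \code{weights} (length \code{2*ceiling(gr) + 1}).
#' @export
samplingKernel <- function(lambda, n = 8L, P = 0.99) {
  stopifnot(lambda > 0, n >= 4L, P > 0, P < 1)
  gr <- lambda * pi / n
  sigmaG <- gr / (sqrt(2) * erfinv(P))
  h <- as.integer(ceiling(gr))
  x <- (-h):h
  w <- erf((x + 0.5) / (sqrt(2) * sigmaG)) - erf((x - 0.5) / (sqrt(2) * sigmaG))
  list(gr = gr, sigmaG = sigmaG, weights = w / sum(w))
}

applySamplingKernel <- function(image, kernel) {
  .sep_convolve(image, kernel$weights)
}

#' Adaptive sign threshold
#'
#' The threshold used by the orientation-compensated LBP sign function: the
#' square root of the population standard deviation of all pixel values of
#' the Gaussian-filtered image. Stabilizes bits against interpolation
#' artifacts when patterns are accumulated over multiple orientations.
#'
#' @param image numeric matrix (normally the filtered image \eqn{I_g}).
#' @return single non-negative number (8-bit intensity units).
#' @export
adaptiveThreshold <- function(image) {
  v <- as.vector(image)
  sqrt(sqrt(mean((v - mean(v))^2)))
}

lbpMargin <- function(radius) as.integer(ceiling(radius)) + 1L

newPatternHistogram <- function(counts, classRef, baseRadius, adaptedRadius,
                                fallback) {
  total <- sum(counts)
  if (total <= 0) stop("no LBP patterns computed")
  new("PatternHistogram", bins = counts / total,
      classRef = as.character(classRef), baseRadius = baseRadius,
      adaptedRadius = adaptedRadius, fallback = fallback)
}

#' Standard local binary patterns
#'
#' Classic fixed-radius LBP: for every interior pixel, each of the \eqn{n}
#' neighbors on a circle of radius \code{radius} (bilinear interpolation)
#' contributes bit \eqn{2^k} when its intensity exceeds the center by at
#' least \code{threshold}. Pixels closer than \code{ceiling(radius) + 1} to
#' the border are skipped. The normalized pattern histogram is returned.
#'
#' @param image numeric matrix.
#' @param radius circle radius, pixels (>= 1 for discriminative patterns).
#' @param n neighbor count; the histogram has \eqn{2^n} bins.
#' @param threshold sign threshold \eqn{T} (intensity units, default 0; the
#'   classic sgn with equality mapping to 1).
#' @param orientationOffsets angular offsets (radians) of the first neighbor;
#'   pattern counts are accumulated over all offsets.
#' @return A [PatternHistogram].
#' @examples
#' img <- matrix(0, 5, 5); img[3, 3] <- 10
#' standardLBP(img, radius = 1, n = 8)
#' @export
standardLBP <- function(image, radius, n = 8L, threshold = 0,
                        orientationOffsets = 0) {
  stopifnot(is.matrix(image), radius > 0, n >= 4L)
  m <- lbpMargin(radius)
  if (nrow(image) <= 2 * m || ncol(image) <= 2 * m) stop("image too small")
  counts <- .lbp_hist(image, radius, as.integer(n), threshold,
                      as.numeric(orientationOffsets), m)
  newPatternHistogram(counts, NA_character_, radius, radius, FALSE)
}

#' Scale-adapted local binary patterns
#'
#' Computes LBP at the intrinsic-scale-adapted radius
#' \eqn{\lambda(s, l, \rho) = \rho\,s/\bar{s}_l}, on the image low-pass
#' filtered with the matching [samplingKernel()], so neighbors are sampled
#' with a support sized to the adapted scale.
#'
#' @param image numeric matrix.
#' @param class class label \eqn{l} whose trained base scale is referenced.
#' @param scale a valid [ScaleEstimate] or a positive number (pixels).
#' @param rho base radius \eqn{\rho}.
#' @param baseScales a [TrainedBaseScales].
#' @param n neighbor count.
#' @param threshold sign threshold (default 0 in scale-only mode).
#' @param orientationOffsets angular offsets, radians (default 0).
#' @param filtered optional precomputed filtered image for this \eqn{\lambda}
#'   (cache used by [buildDescriptor()]).
#' @return A [PatternHistogram] tagged with class, base and adapted radius.
#' @export
extractSaLBP <- function(image, class, scale, rho, baseScales, n = 8L,
                         threshold = 0, orientationOffsets = 0,
                         filtered = NULL) {
  s <- if (is(scale, "ScaleEstimate")) {
    if (!isValid(scale)) stop("scale estimate invalid; use the fixed-radius fallback")
    scale@s
  } else scale
  lambda <- adaptedRadius(s, class, rho, baseScales)
  if (is.null(filtered)) {
    filtered <- applySamplingKernel(image, samplingKernel(lambda, n))
  }
  m <- lbpMargin(lambda)
  if (nrow(image) <= 2 * m || ncol(image) <= 2 * m)
    stop("image too small for adapted radius ", format(lambda))
  counts <- .lbp_hist(filtered, lambda, as.integer(n), threshold,
                      as.numeric(orientationOffsets), m)
  newPatternHistogram(counts, class, rho, lambda, FALSE)
}

#' Scale- and orientation-adaptive local binary patterns
#'
#' SOA-LBP: scale-adapted patterns whose sampling circle is aligned with the
#' estimated global orientation \eqn{o}. To compensate estimation errors,
#' pattern counts are accumulated over orientation offsets
#' \eqn{\{o-\Delta o, \dots, o+\Delta o\}} in steps of \code{stepO}, and --
#' because the second-moment-matrix orientation is ambiguous by \eqn{\pi} --
#' over both initial orientations \eqn{o} and \eqn{o+\pi}
#' (\code{dualOrientation}). The sign threshold defaults to
#' [adaptiveThreshold()] of the filtered image.
#'
#' @inheritParams extractSaLBP
#' @param orientation an [OrientationEstimate] or an angle in radians.
#' @param deltaO one-sided compensation interval, degrees (default 20).
#' @param stepO accumulation step, degrees (default 5).
#' @param dualOrientation accumulate at \eqn{o} and \eqn{o + \pi} (default
#'   TRUE, matching the ambiguity of the orientation estimate).
#' @param threshold sign threshold; \code{NULL} (default) selects
#'   [adaptiveThreshold()] of the filtered image.
#' @return A [PatternHistogram].
#' @export
extractSoaLBP <- function(image, class, scale, orientation, rho, baseScales,
                          n = 8L, deltaO = 20, stepO = 5,
                          dualOrientation = TRUE, threshold = NULL,
                          filtered = NULL) {
  o <- if (is(orientation, "OrientationEstimate")) orientation@o else orientation
  s <- if (is(scale, "ScaleEstimate")) {
    if (!isValid(scale)) stop("scale estimate invalid; use the fixed-radius fallback")
    scale@s
  } else scale
  lambda <- adaptedRadius(s, class, rho, baseScales)
  if (is.null(filtered)) {
    filtered <- applySamplingKernel(image, samplingKernel(lambda, n))
  }
  if (is.null(threshold)) threshold <- adaptiveThreshold(filtered)
  offs <- if (deltaO > 0) seq(-deltaO, deltaO, by = stepO) * pi / 180 else 0
  offs <- o + offs
  if (dualOrientation) offs <- c(offs, offs + pi)
  m <- lbpMargin(lambda)
  if (nrow(image) <= 2 * m || ncol(image) <= 2 * m)
    stop("image too small for adapted radius ", format(lambda))
  counts <- .lbp_hist(filtered, lambda, as.integer(n), threshold, offs, m)
  newPatternHistogram(counts, class, rho, lambda, FALSE)
}

#' @describeIn standardLBP histogram bin accessor.
#' @param h a \code{PatternHistogram}.
#' @export
histBins <- function(h) h@bins

setMethod("show", "PatternHistogram", function(object) {
  cat(sprintf(
    "PatternHistogram: %d bins, class %s, rho %.2f, adapted radius %.3f%s\n",
    length(object@bins), object@classRef, object@baseRadius,
    object@adaptedRadius, if (object@fallback) " [fallback]" else ""))
})
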