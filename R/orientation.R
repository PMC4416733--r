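# Central-difference gradient of a smoothed image. gy is returned in the
# "y up" convention used by all angle computations in this package (rows
# grow downward, so gy = -d/drow).
imageGradient <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  left  <- image[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- image[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up    <- image[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- image[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (up - down) / 2)
}

#' Local orientations from multi-scale second-moment matrices
#'
#' Computes, per pixel, the 2x2 second-moment matrix (structure tensor)
#' \eqn{\mu = g(\cdot;i) * (\nabla L)(\nabla L)^T}, with gradients taken on
#' the scale-space representation at the local (derivative) scale and
#' integrated with a Gaussian at twice that scale. The local orientation is
#' the angle between the major eigen-axis (the dominant gradient direction)
#' and the vertical image axis, reduced modulo \eqn{\pi}, counted
#' counter-clockwise. Pixels whose gradient energy is negligible relative to
#' the image variance carry no orientation and are set to \code{NA}.
#'
#' @param image numeric matrix.
#' @param localScale derivative scale in pixels, typically the estimated
#'   global image scale.
#' @param stride sample every \code{stride}-th pixel (1 = dense grid).
#' @return An [OrientationField].
#' @export
smmOrientationField <- function(image, localScale, stride = 1L) {
  stopifnot(is.matrix(image), localScale > 0)
  L <- gaussianSmooth(image, localScale)
  g <- imageGradient(L)
  intScale <- 2 * localScale
  m11 <- gaussianSmooth(g$gx * g$gx, intScale)
  m22 <- gaussianSmooth(g$gy * g$gy, intScale)
  m12 <- gaussianSmooth(g$gx * g$gy, intScale)
  if (stride > 1L) {
    ri <- seq(1L, nrow(image), by = stride)
    ci <- seq(1L, ncol(image), by = stride)
    m11 <- m11[ri, ci, drop = FALSE]
    m22 <- m22[ri, ci, drop = FALSE]
    m12 <- m12[ri, ci, drop = FALSE]
  }
  # Major eigenvector angle from the x axis: phi = atan2(2*m12, m11-m22)/2.
  # Orientation from the vertical axis, CCW, modulo pi.
  phi <- 0.5 * atan2(2 * m12, m11 - m22)
  ang <- (phi - pi / 2) %% pi
  ang[ang >= pi] <- 0  # guard against %% returning pi at rounding limits
  lmax <- (m11 + m22 + sqrt((m11 - m22)^2 + 4 * m12^2)) / 2
  degenerate <- lmax <= 1e-12 * max(stats::var(as.vector(image)), .Machine$double.eps)
  ang[degenerate] <- NA_real_
  new("OrientationField", angles = ang, localScale = localScale,
      integrationScale = intScale)
}

# Second-moment matrices at given pixel indices, for cross-checking the
# vectorized angle computation against an explicit eigen-decomposition.
smmAt <- function(image, localScale, rows, cols) {
  L <- gaussianSmooth(image, localScale)
  g <- imageGradient(L)
  intScale <- 2 * localScale
  m11 <- gaussianSmooth(g$gx * g$gx, intScale)
  m22 <- gaussianSmooth(g$gy * g$gy, intScale)
  m12 <- gaussianSmooth(g$gx * g$gy, intScale)
  mapply(function(r, c) matrix(c(m11[r, c], m12[r, c], m12[r, c], m22[r, c]), 2L),
         rows, cols, SIMPLIFY = FALSE)
}

#' Estimate the global image orientation
#'
#' Histograms the defined local orientations over \eqn{[0,\pi)}, circularly
#' recenters the histogram on its mode, discards bins offset by more than
#' \code{trim} degrees from the mode, and fits a three-parameter Gaussian to
#' the remaining bin counts by nonlinear least squares. The fitted mean,
#' wrapped back to \eqn{[0,\pi)}, is the global orientation. If the fit does
#' not converge the histogram mode is returned with \code{fitStd = NA}.
#'
#' @param field an [OrientationField].
#' @param trim one-sided trim around the mode, degrees (default 15).
#' @param binWidth histogram bin width, degrees (default 1).
#' @return An [OrientationEstimate].
#' @export
estimateGlobalOrientation <- function(field, trim = 15, binWidth = 1) {
  ang <- field@angles[!is.na(field@angles)]
  if (length(ang) == 0L) stop("no orientation signal")
  nbins <- as.integer(round(180 / binWidth))
  deg <- ang * 180 / pi
  bin <- pmin(nbins - 1L, floor(deg / binWidth))        # 0-based bin index
  counts <- tabulate(bin + 1L, nbins)
  centers <- (seq_len(nbins) - 0.5) * binWidth          # degrees

  mode <- which.max(counts)
  # rotate circularly so the mode sits at 90 degrees
  shift <- as.integer(round((90 - centers[mode]) / binWidth))
  rot <- counts[((seq_len(nbins) - 1L - shift) %% nbins) + 1L]
  keep <- abs(centers - 90) <= trim
  x <- centers[keep]; y <- rot[keep]

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(a = max(y), mu = 90, w = 5),
      fn = function(p) y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4 || !is.finite(fit$par[2])) {
    o <- (centers[mode] %% 180) * pi / 180
    return(new("OrientationEstimate", o = o %% pi, fitStd = NA_real_))
  }
  muDeg <- (unname(fit$par[2]) - 90 + centers[mode]) %% 180
  new("OrientationEstimate", o = (muDeg * pi / 180) %% pi,
      fitStd = abs(unname(fit$par[3])) * pi / 180)
}

#' One-call global orientation estimation
#'
#' Estimates the global scale (unless a numeric scale is supplied) and
#' derives the global orientation from the second-moment-matrix field at
#' that scale. When the scale estimate is invalid, the default local scale
#' \eqn{\sigma = c} (grid level \eqn{k = 0}) is used.
#'
#' @param image numeric matrix.
#' @param scale \code{NULL} (estimate it), a [ScaleEstimate], or a positive
#'   number of pixels.
#' @param grid [ScaleGrid] used when estimating the scale.
#' @param stride pixel stride of the orientation field.
#' @return An [OrientationEstimate].
#' @export
estimateOrientation <- function(image, scale = NULL, grid = scaleGrid(),
                                stride = 1L) {
  if (is.null(scale)) scale <- estimateScale(image, grid)
  if (is(scale, "ScaleEstimate")) {
    scale <- if (isValid(scale)) scale@s else grid@c
  }
  estimateGlobalOrientation(smmOrientationField(image, scale, stride))
}

#' @describeIn estimateGlobalOrientation orientation accessor (radians).
#' @param est an \code{OrientationEstimate}.
#' @export
globalOrientation <- function(est) est@o

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %dx%d, local scale %.3f px (%d undefined)\n",
              nrow(object@angles), ncol(object@angles), object@localScale,
              sum(is.na(object@angles))))
})

setMethod("show", "OrientationEstimate", function(object) {
  cat(sprintf("OrientationEstimate: o = %.2f deg (fit std %.2f deg)\n",
              object@o * 180 / pi, object@fitStd * 180 / pi))
})

# Smallest absolute angular difference modulo pi, in radians.
angleDiffModPi <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}
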