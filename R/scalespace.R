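#' Construct an exponential scale grid
#'
#' Builds the grid of scale-space standard deviations
#' \eqn{\sigma_i = c\,2^{k_i}} with exponents \eqn{k_i} running from
#' \code{kmin} to \code{kmax} in steps of \code{kstep}. The defaults give the
#' 49-level grid used throughout the package; \code{c} is chosen so that the
#' spatial extent \eqn{\sigma\sqrt{2}} of the level at \eqn{k = 0}
#' corresponds to an LBP radius of 3.
#'
#' @param c positive scaling factor, pixels.
#' @param kmin,kmax,kstep exponent range and step.
#' @return A [ScaleGrid].
#' @examples
#' g <- scaleGrid()
#' length(sigmas(g))  # 49
#' @export
scaleGrid <- function(c = 2.1214, kmin = -4, kmax = 8, kstep = 0.25) {
  if (kmax <= kmin || kstep <= 0) stop("exponents must be strictly increasing")
  k <- seq(kmin, kmax, by = kstep)
  new("ScaleGrid", c = c, exponents = k, sigmas = c * 2^k)
}

#' @describeIn scaleGrid the sigma values of a grid.
#' @param x a \code{ScaleGrid}.
#' @export
sigmas <- function(x) x@sigmas

gaussianKernel1d <- function(sigma, truncate = 3.5) {
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-h):h
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Gaussian smoothing with symmetric-reflection boundaries. Small sigmas use
# a truncated separable spatial kernel; large sigmas use an exact
# frequency-domain product on the mirror-extended image (periodic extension
# of the reflected image is identical to reflective-boundary convolution,
# without kernel truncation), which keeps the cost independent of sigma.
gaussianSmooth <- function(image, sigma, truncate = 3.5) {
  if (sigma <= 8) {
    .sep_convolve(image, gaussianKernel1d(sigma, truncate))
  } else {
    gaussianSmoothFFT(image, sigma)
  }
}

gaussianSmoothFFT <- function(image, sigma) {
  nr <- nrow(image); nc <- ncol(image)
  m <- rbind(image, image[nr:1, , drop = FALSE])
  m <- cbind(m, m[, nc:1, drop = FALSE])
  wr <- 2 * pi * c(seq(0, floor((2 * nr - 1) / 2)), seq(-floor(2 * nr / 2), -1)) / (2 * nr)
  wc <- 2 * pi * c(seq(0, floor((2 * nc - 1) / 2)), seq(-floor(2 * nc / 2), -1)) / (2 * nc)
  H <- exp(-sigma^2 * outer(wr^2, wc^2, `+`) / 2)
  sm <- Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (4 * nr * nc)
  sm[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Build a Gaussian scale-space
#'
#' Convolves the image with a separable 2-D Gaussian at every standard
#' deviation of the grid, using reflective boundary handling. The smallest
#' default level (\eqn{\sigma \approx 0.13}) leaves the image essentially
#' unchanged, approximating the initial condition \eqn{L(\cdot;0) = f}.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param grid a [ScaleGrid].
#' @return A [ScaleSpace].
#' @export
buildScaleSpace <- function(image, grid = scaleGrid()) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 16L || ncol(image) < 16L) stop("image too small")
  levels <- lapply(grid@sigmas, function(s) gaussianSmooth(image, s))
  new("ScaleSpace", grid = grid, levels = levels)
}

#' Scale-normalized Laplacian responses
#'
#' For every level \eqn{L(\cdot;\sigma_i)} of a scale-space, computes the
#' pointwise scale-normalized Laplacian magnitude
#' \eqn{\bar\Delta I(\cdot;\sigma_i) = \sigma_i^2\,|\Delta L(\cdot;\sigma_i)|}
#' using a 5-point finite-difference stencil. Responses are non-negative and
#' attain their maximum over scales at the characteristic scale of blob-like
#' structure.
#'
#' @param ss a [ScaleSpace].
#' @return list of non-negative matrices, one per level.
#' @export
normalizedLaplacian <- function(ss) {
  stopifnot(is(ss, "ScaleSpace"))
  mapply(function(level, sigma) sigma^2 * abs(.laplacian5(level)),
         ss@levels, ss@grid@sigmas, SIMPLIFY = FALSE)
}

#' Scale response function
#'
#' Sums the scale-normalized Laplacian magnitude over all pixels at every
#' level, giving the scale response \eqn{\xi(\sigma_i)} whose first local
#' maximum marks the dominant global scale of the image.
#'
#' @param lapStack list of matrices as returned by [normalizedLaplacian()].
#' @return numeric vector, one non-negative entry per scale level.
#' @export
scaleResponse <- function(lapStack) {
  stopifnot(is.list(lapStack), length(lapStack) > 0L)
  vapply(lapStack, sum, numeric(1))
}

firstLocalMaximum <- function(xi) {
  n <- length(xi)
  if (n < 3L) return(NA_integer_)
  for (i in 2:(n - 1L)) {
    if (xi[i - 1L] < xi[i] && xi[i] >= xi[i + 1L]) return(i)
  }
  NA_integer_
}

# Map a fractional (1-based) level index to a spatial scale by linear
# interpolation on the exponent grid: sigma = c * 2^k(sTilde).
levelToSigma <- function(sTilde, grid) {
  k <- grid@exponents
  step <- k[2L] - k[1L]
  grid@c * 2^(k[1L] + (sTilde - 1) * step)
}

#' Estimate the global image scale from a scale response
#'
#' Scans \eqn{\xi} from the smallest scale for its first local maximum
#' (plateaus resolve to their leftmost index; the endpoints never seed), then
#' fits a three-parameter Gaussian \eqn{a\,e^{-(i-\mu)^2/(2u^2)}} by nonlinear
#' least squares to the data points within \eqn{\pm}\code{round(offsetFraction
#' * n)} levels of the seed. The fitted mean is the fractional dominant level
#' \code{sTilde}, the fitted standard deviation the uncertainty \code{u}. The
#' estimate is valid when the fit converged and \eqn{u/n \le t}; otherwise
#' callers fall back to fixed-radius standard LBP.
#'
#' @param xi numeric vector from [scaleResponse()], one entry per grid level.
#' @param grid the [ScaleGrid] the response was computed on.
#' @param offsetFraction fraction of the level count used as one-sided fit
#'   window (default 0.10, i.e. \eqn{\pm 5} levels on the 49-level grid).
#' @param threshold validity threshold \eqn{t} on \eqn{u/n}; default
#'   \eqn{20/n} (0.4082 on the default grid).
#' @return A [ScaleEstimate].
#' @export
estimateGlobalScale <- function(xi, grid = scaleGrid(),
                                offsetFraction = 0.10,
                                threshold = 20 / length(xi)) {
  n <- length(xi)
  stopifnot(n == length(grid@sigmas))
  invalid <- new("ScaleEstimate", sTilde = NA_real_, s = NA_real_,
                 u = NA_real_, valid = FALSE)
  if (all(xi == 0)) return(invalid)
  seed <- firstLocalMaximum(xi)
  if (is.na(seed)) return(invalid)

  w <- max(1L, as.integer(round(offsetFraction * n)))
  idx <- max(1L, seed - w):min(n, seed + w)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(a = xi[seed], mu = as.numeric(seed), u = 2),
      fn = function(p) xi[idx] - p[1] * exp(-(idx - p[2])^2 / (2 * p[3]^2)))),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(invalid)

  sTilde <- unname(fit$par[2])
  u <- abs(unname(fit$par[3]))
  s <- levelToSigma(sTilde, grid)
  valid <- is.finite(s) && s > 0 && is.finite(u) && (u / n) <= threshold
  if (!valid) return(new("ScaleEstimate", sTilde = sTilde, s = s, u = u, valid = FALSE))
  new("ScaleEstimate", sTilde = sTilde, s = s, u = u, valid = TRUE)
}

#' One-call global scale estimation
#'
#' Convenience wrapper chaining [buildScaleSpace()], [normalizedLaplacian()],
#' [scaleResponse()] and [estimateGlobalScale()].
#'
#' @inheritParams buildScaleSpace
#' @inheritParams estimateGlobalScale
#' @return A [ScaleEstimate].
#' @examples
#' img <- makeTexture(textureSpec("blobs", dominantScale = 4, seed = 1))
#' estimateScale(img)
#' @export
estimateScale <- function(image, grid = scaleGrid(), offsetFraction = 0.10,
                          threshold = 20 / length(grid@sigmas)) {
  xi <- scaleResponse(normalizedLaplacian(buildScaleSpace(image, grid)))
  estimateGlobalScale(xi, grid, offsetFraction, threshold)
}

#' @describeIn estimateGlobalScale dominant spatial scale accessor.
#' @param est a \code{ScaleEstimate}.
#' @export
dominantScale <- function(est) est@s

#' @describeIn estimateGlobalScale uncertainty accessor.
#' @export
uncertainty <- function(est) est@u

#' @describeIn estimateGlobalScale validity accessor.
#' @export
isValid <- function(est) isTRUE(est@valid)

setMethod("show", "ScaleGrid", function(object) {
  cat(sprintf("ScaleGrid: %d levels, c = %.4f, sigma in [%.4g, %.4g] px\n",
              length(object@sigmas), object@c,
              min(object@sigmas), max(object@sigmas)))
})

setMethod("show", "ScaleSpace", function(object) {
  d <- dim(object@levels[[1]])
  cat(sprintf("ScaleSpace: %d levels of a %dx%d image\n",
              length(object@levels), d[1], d[2]))
})

setMethod("show", "ScaleEstimate", function(object) {
  if (isTRUE(object@valid)) {
    cat(sprintf("ScaleEstimate: s = %.3f px (level %.2f, u = %.2f) [valid]\n",
                object@s, object@sTilde, object@u))
  } else {
    cat("ScaleEstimate: invalid (fallback to fixed-radius LBP)\n")
  }
})
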