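#' Specification of a synthetic texture
#'
#' Parameters of the synthetic textures used for testing the pipeline:
#' \code{"blobs"} (isotropic blob field with controllable dominant scale),
#' \code{"grating"} (sinusoid with controllable scale and orientation) and
#' \code{"oriented-noise"} (band-pass filtered noise with controllable scale
#' and orientation). \code{dominantScale} is the characteristic scale the
#' scale-normalized-Laplacian machinery measures, in sigma units;
#' \code{dominantOrientation} is the value the orientation estimator should
#' recover (radians, modulo pi). Generation is deterministic given
#' \code{seed}.
#'
#' @slot kind one of "blobs", "grating", "oriented-noise".
#' @slot dominantScale pixels.
#' @slot dominantOrientation radians in \eqn{[0,\pi)} (ignored for blobs).
#' @slot size image side length, pixels.
#' @slot density blob density (blobs per dominantScale^2 area; blobs only).
#' @slot contrast amplitude as a fraction of the 8-bit range.
#' @slot seed integer RNG seed.
#' @export
setClass("TextureSpec",
  representation(kind = "character", dominantScale = "numeric",
                 dominantOrientation = "numeric", size = "integer",
                 density = "numeric", contrast = "numeric", seed = "integer"))

setValidity("TextureSpec", function(object) {
  if (!object@kind %in% c("blobs", "grating", "oriented-noise"))
    return("unknown texture kind")
  if (object@dominantScale <= 0) return("dominantScale must be positive")
  if (object@size < 32L) return("size must be at least 32")
  if (object@density <= 0 || object@contrast <= 0) return("density and contrast must be positive")
  TRUE
})

#' @describeIn TextureSpec constructor.
#' @param kind,dominantScale,dominantOrientation,size,density,contrast,seed
#'   see the class slots.
#' @export
textureSpec <- function(kind = c("blobs", "grating", "oriented-noise"),
                        dominantScale = 4, dominantOrientation = 0,
                        size = 128L, density = 1, contrast = 1, seed = 1L) {
  kind <- match.arg(kind)
  new("TextureSpec", kind = kind, dominantScale = dominantScale,
      dominantOrientation = dominantOrientation %% pi, size = as.integer(size),
      density = density, contrast = contrast, seed = as.integer(seed))
}

toByteRange <- function(x, contrast = 1) {
  s <- stats::sd(as.vector(x))
  if (s == 0) return(matrix(127.5, nrow(x), ncol(x)))
  y <- (x - mean(x)) / (3 * s) * contrast
  y <- pmin(1, pmax(-1, y))
  matrix(127.5 + 127.5 * y, nrow(x), ncol(x))
}

# Dense field of Gaussian blobs: Poisson-distributed signed impulses
# convolved with a Gaussian. For such a field the summed scale-normalized
# Laplacian response peaks at sqrt(2) times the blob standard deviation, so
# the kernel uses dominantScale/sqrt(2) to make the generated dominant
# (characteristic) scale equal to the requested one.
makeBlobs <- function(spec) {
  n <- spec@size
  sigmaB <- spec@dominantScale / sqrt(2)
  count <- stats::rpois(1, spec@density * n^2 / spec@dominantScale^2)
  count <- max(count, 8L)
  field <- matrix(0, n, n)
  r <- sample.int(n, count, replace = TRUE)
  c <- sample.int(n, count, replace = TRUE)
  amp <- sample(c(-1, 1), count, replace = TRUE) * stats::rgamma(count, 2, 2)
  for (i in seq_len(count)) field[r[i], c[i]] <- field[r[i], c[i]] + amp[i]
  toByteRange(gaussianSmooth(field, sigmaB), spec@contrast)
}

# Sinusoidal grating. The wave vector sits perpendicular to the requested
# orientation (the second-moment-matrix major axis is the gradient
# direction); angular frequency sqrt(2)/dominantScale puts the peak of the
# scale response at dominantScale.
makeGrating <- function(spec) {
  n <- spec@size
  omega <- sqrt(2) / spec@dominantScale
  beta <- spec@dominantOrientation + pi / 2
  phase <- stats::runif(1, 0, 2 * pi)
  x <- matrix(rep(seq_len(n), each = n), n)        # column index
  yUp <- matrix(rep(n - seq_len(n), times = n), n) # row index, y up
  wave <- sin(omega * (x * cos(beta) + yUp * sin(beta)) + phase)
  toByteRange(wave, spec@contrast)
}

fftFreq <- function(n) {
  f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  2 * pi * f
}

# White noise filtered in the frequency domain with a Gaussian ring at
# radial frequency sqrt(2)/dominantScale and a Gaussian angular window
# (sd 10 degrees, modulo pi) around the gradient direction.
makeOrientedNoise <- function(spec) {
  n <- spec@size
  omega0 <- sqrt(2) / spec@dominantScale
  beta <- spec@dominantOrientation + pi / 2
  noise <- matrix(stats::rnorm(n * n), n)
  kx <- matrix(rep(fftFreq(n), each = n), n)
  kyRow <- matrix(rep(fftFreq(n), times = n), n)
  kyUp <- -kyRow
  kr <- sqrt(kx^2 + kyUp^2)
  ka <- atan2(kyUp, kx)
  radial <- exp(-(kr - omega0)^2 / (2 * (0.25 * omega0)^2))
  dAng <- (ka - beta) %% pi
  dAng <- pmin(dAng, pi - dAng)
  angular <- exp(-dAng^2 / (2 * (10 * pi / 180)^2))
  spec2 <- stats::fft(noise) * radial * angular
  img <- Re(stats::fft(spec2, inverse = TRUE)) / n^2
  toByteRange(img, spec@contrast)
}

#' Generate a synthetic texture
#'
#' Deterministic given the seed in the spec; returns a numeric matrix with
#' intensities in \eqn{[0, 255]}.
#'
#' @param spec a [textureSpec()].
#' @return numeric matrix \code{size x size}.
#' @examples
#' img <- makeTexture(textureSpec("grating", dominantScale = 4,
#'                                dominantOrientation = pi / 6, seed = 7))
#' @export
makeTexture <- function(spec) {
  stopifnot(is(spec, "TextureSpec"))
  validObject(spec)
  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(spec@seed)
  switch(spec@kind,
         "blobs" = makeBlobs(spec),
         "grating" = makeGrating(spec),
         "oriented-noise" = makeOrientedNoise(spec))
}

bilinearWarp <- function(image, rows, cols) {
  matrix(.bilinear_grid(image, as.numeric(rows) - 1, as.numeric(cols) - 1),
         nrow(rows), ncol(rows))
}

resampleBilinear <- function(image, q) {
  nr <- max(2L, as.integer(round(nrow(image) * q)))
  nc <- max(2L, as.integer(round(ncol(image) * q)))
  # map output pixel centers back onto the input grid
  rows <- (seq_len(nr) - 0.5) / q + 0.5
  cols <- (seq_len(nc) - 0.5) / q + 0.5
  bilinearWarp(image, matrix(rep(rows, times = nc), nr),
               matrix(rep(cols, each = nr), nr))
}

rotateBilinear <- function(image, thetaDeg) {
  th <- thetaDeg * pi / 180
  nr <- nrow(image); nc <- ncol(image)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  col <- matrix(rep(seq_len(nc), each = nr), nr)
  row <- matrix(rep(seq_len(nr), times = nc), nr)
  x <- col - cc
  yUp <- cr - row
  # counter-clockwise rotation (y up): sample source at R(-theta) * target
  sx <- cos(th) * x + sin(th) * yUp
  sy <- -sin(th) * x + cos(th) * yUp
  bilinearWarp(image, cr - sy, cc + sx)
}

centerCrop <- function(image, crop) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < crop || nc < crop) stop("image smaller than crop")
  r0 <- floor((nr - crop) / 2)
  c0 <- floor((nc - crop) / 2)
  image[r0 + seq_len(crop), c0 + seq_len(crop)]
}

#' Rescale, rotate and crop a texture
#'
#' Emulates the construction of evaluation images at probe scales and
#' rotations: resamples the image by \code{scaleFactor} (with Gaussian
#' anti-alias pre-filtering when shrinking), rotates counter-clockwise by
#' \code{rotation} degrees about the center, and center-crops to
#' \code{crop} pixels. A counter-clockwise rotation by \eqn{\theta} shifts
#' the estimated global orientation by \eqn{+\theta} modulo \eqn{\pi}.
#'
#' @param image numeric matrix.
#' @param scaleFactor magnification \eqn{q > 0} (content scales by q).
#' @param rotation degrees counter-clockwise.
#' @param crop output side length (default 128).
#' @return \code{crop x crop} numeric matrix.
#' @export
transformTexture <- function(image, scaleFactor = 1, rotation = 0, crop = 128L) {
  stopifnot(scaleFactor > 0)
  out <- image
  if (scaleFactor < 1) {
    aa <- 0.5 * sqrt(1 / scaleFactor^2 - 1)
    if (aa > 0.1) out <- gaussianSmooth(out, aa)
    out <- resampleBilinear(out, scaleFactor)
  } else if (scaleFactor > 1) {
    out <- resampleBilinear(out, scaleFactor)
  }
  if (rotation %% 360 != 0) out <- rotateBilinear(out, rotation)
  centerCrop(out, crop)
}

setMethod("show", "TextureSpec", function(object) {
  cat(sprintf(
    "TextureSpec: %s, scale %.2f px, orientation %.1f deg, %dx%d, seed %d\n",
    object@kind, object@dominantScale,
    object@dominantOrientation * 180 / pi, object@size, object@size,
    object@seed))
})
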