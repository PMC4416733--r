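test_that("standard LBP matches hand-traced toy cases", {
  # constant image, T = 0: sgn(0) = 1 for every neighbor -> all-ones pattern
  h <- standardLBP(matrix(7, 16, 16), radius = 1.5, n = 8)
  expect_equal(h@bins[256], 1)
  # constant image, T > 0: no neighbor clears the threshold
  h0 <- standardLBP(matrix(7, 16, 16), radius = 1.5, n = 8, threshold = 1)
  expect_equal(h0@bins[1], 1)
  # single bright center: its 8 neighbors are all darker -> pattern 0
  img <- matrix(0, 5, 5); img[3, 3] <- 10
  hc <- standardLBP(img, radius = 1, n = 8)
  expect_equal(hc@bins[1], 1)
  expect_error(standardLBP(matrix(0, 4, 4), radius = 2), "too small")
})

test_that("every histogram is normalized with 2^n bins", {
  set.seed(2)
  img <- matrix(stats::runif(32^2, 0, 255), 32)
  for (n in c(4L, 8L)) {
    h <- standardLBP(img, radius = 2, n = n)
    expect_length(h@bins, 2^n)
    expect_equal(sum(h@bins), 1, tolerance = 1e-9)
    expect_true(all(h@bins >= 0))
  }
})

test_that("the sampling kernel follows the integrated-Gaussian construction", {
  k <- samplingKernel(3, 8)
  # gr = 3*pi/8; sigma_g = gr / (sqrt(2) * erfinv(0.99)), erfinv(0.99) = 1.8214
  expect_equal(k$gr, 3 * pi / 8, tolerance = 1e-12)
  expect_equal(k$gr, 1.1781, tolerance = 1e-4)
  expect_equal(k$sigmaG, 0.4574, tolerance = 1e-4)
  for (lambda in c(0.7, 2, 5.3)) {
    kk <- samplingKernel(lambda, 8)
    expect_equal(sum(kk$weights), 1, tolerance = 1e-12)
    expect_equal(kk$weights, rev(kk$weights))
    expect_true(all(kk$weights > 0))
    expect_length(kk$weights, 2 * ceiling(kk$gr) + 1)
  }
})

test_that("for large radii the kernel moments approach the truncated Gaussian", {
  k <- samplingKernel(60, 8)
  x <- seq(-ceiling(k$gr), ceiling(k$gr))
  emp <- sqrt(sum(k$weights * x^2))
  # the kernel is truncated at gr = 2.576 sigma_g by construction (99% mass);
  # oracle: variance of the truncated Gaussian plus the unit-bin term
  cc <- k$gr / k$sigmaG
  vTrunc <- k$sigmaG^2 * (1 - 2 * cc * stats::dnorm(cc) / (2 * stats::pnorm(cc) - 1))
  expect_equal(emp, sqrt(vTrunc + 1 / 12), tolerance = 0.02)
})

test_that("kernel size scales linearly with the adapted radius", {
  k1 <- samplingKernel(2.5, 8)
  k2 <- samplingKernel(5, 8)
  expect_equal(k2$gr, 2 * k1$gr)
  expect_equal(k2$sigmaG, 2 * k1$sigmaG)
})

test_that("the adaptive threshold is the square root of the population standard deviation", {
  expect_equal(adaptiveThreshold(matrix(5, 10, 10)), 0)
  img <- matrix(c(rep(0, 50), rep(16, 50)), 10)
  expect_equal(adaptiveThreshold(img), sqrt(8), tolerance = 1e-12)
  # intensity scaling by a^2 scales T by a
  expect_equal(adaptiveThreshold(img * 9), 3 * adaptiveThreshold(img), tolerance = 1e-12)
})

test_that("scale-adapted LBP reduces exactly to standard LBP at the base scale", {
  img <- makeTexture(textureSpec("oriented-noise", dominantScale = 4,
                                 dominantOrientation = 1, seed = 11))
  b <- baseScales(c(A = 4))
  for (rho in c(1.5, 3)) {
    filt <- soalbp:::applySamplingKernel(img, samplingKernel(rho, 8))
    hStd <- standardLBP(filt, rho, 8)
    hSa <- extractSaLBP(img, "A", 4, rho, b)  # s = sbar -> lambda = rho
    expect_identical(hSa@bins, hStd@bins)
    expect_equal(hSa@adaptedRadius, rho)
  }
})

test_that("identical base scales give identical histograms across classes", {
  img <- makeTexture(textureSpec("blobs", dominantScale = 3, seed = 6))
  b <- baseScales(c(A = 3.5, B = 3.5))
  hA <- extractSaLBP(img, "A", 5, 3, b)
  hB <- extractSaLBP(img, "B", 5, 3, b)
  expect_identical(hA@bins, hB@bins)
})

test_that("SOA-LBP reduces to SA-LBP and standard LBP when alignment is disabled", {
  img <- makeTexture(textureSpec("oriented-noise", dominantScale = 4,
                                 dominantOrientation = 1, seed = 11))
  b <- baseScales(c(A = 4))
  hSa <- extractSaLBP(img, "A", 4, 3, b)
  hSingle <- extractSoaLBP(img, "A", 4, 0, 3, b, deltaO = 0,
                           dualOrientation = FALSE, threshold = 0)
  expect_identical(hSingle@bins, hSa@bins)
  # with the pi-ambiguous dual start, the reduction is to SA-LBP accumulated
  # at initial orientations {0, pi}
  hDual <- extractSoaLBP(img, "A", 4, 0, 3, b, deltaO = 0,
                         dualOrientation = TRUE, threshold = 0)
  hSaDual <- extractSaLBP(img, "A", 4, 3, b, orientationOffsets = c(0, pi))
  expect_identical(hDual@bins, hSaDual@bins)
})

test_that("SOA-LBP of an isotropic image is orientation-independent", {
  img <- blobImage(4, 65) * 255
  b <- baseScales(c(A = 4))
  h1 <- extractSoaLBP(img, "A", 4, 0.3, 3, b)
  h2 <- extractSoaLBP(img, "A", 4, 1.8, 3, b)
  # rotational symmetry of the blob: histograms nearly identical
  expect_lt(sum(abs(h1@bins - h2@bins)), 0.02)
})

test_that("doubling the estimated scale doubles the adapted radius and filter radius", {
  b <- baseScales(c(A = 2))
  l1 <- adaptedRadius(3, "A", 1.5, b)
  l2 <- adaptedRadius(6, "A", 1.5, b)
  expect_identical(l2, 2 * l1)
  expect_identical(samplingKernel(l2, 8)$gr, 2 * samplingKernel(l1, 8)$gr)
})

test_that("an invalid scale estimate is refused by the adaptive extractors", {
  bad <- new("ScaleEstimate", sTilde = NA_real_, s = NA_real_, u = NA_real_, valid = FALSE)
  b <- baseScales(c(A = 3))
  img <- matrix(stats::runif(32^2), 32)
  expect_error(extractSaLBP(img, "A", bad, 3, b), "invalid")
  expect_error(extractSoaLBP(img, "A", bad, 0, 3, b), "invalid")
})

test_that("orientation errors up to 20 degrees are compensated at the descriptor level", {
  set.seed(31)
  b <- baseScales(c(A = 3, B = 3, C = 3))
  mk <- function(cl, seed) transformTexture(makeTexture(threeClassSpec(cl, seed)), 1)
  classes <- c("A", "B", "C")
  train <- lapply(stats::setNames(classes, classes), function(cl)
    buildDescriptor(mk(cl, match(cl, classes)), b, "training", ownClass = cl))
  for (cl in c("B", "C")) {  # the anisotropic classes
    img <- mk(cl, 100 + match(cl, classes))
    est <- estimateScale(img)
    o <- globalOrientation(estimateGlobalOrientation(smmOrientationField(img, est@s)))
    for (err in c(10, 20)) {
      feats <- list()
      for (l in classes) for (r in c(1.5, 3, 4.5)) {
        feats[[paste(l, format(r), sep = "|")]] <-
          extractSoaLBP(img, l, est, o + err * pi / 180, r, b)
      }
      q <- new("MetaDescriptor", features = feats, scale = est,
               orientation = list(), fallback = FALSE, mode = "evaluation",
               id = "", label = cl)
      d <- vapply(train, function(t) descriptorDistance(q, t, b), numeric(1))
      # the misaligned query is still nearest to its own class
      expect_identical(names(d)[which.min(d)], cl)
    }
  }
})
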