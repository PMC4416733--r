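test_that("the default grid spans 49 exponentially spaced levels", {
  g <- scaleGrid()
  expect_length(sigmas(g), 49L)
  expect_true(all(diff(sigmas(g)) > 0))
  # exponential spacing: constant ratio between adjacent levels
  expect_equal(sigmas(g)[-1] / sigmas(g)[-49], rep(2^0.25, 48))
  expect_error(scaleGrid(kmin = 2, kmax = 1), "increasing")
})

test_that("Gaussian filtering preserves constants and reproduces the impulse response", {
  g <- scaleGrid(kmin = 0, kmax = 1, kstep = 0.5)
  ss <- buildScaleSpace(matrix(42, 32, 32), g)
  for (lvl in ss@levels) expect_equal(lvl, matrix(42, 32, 32))

  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  lvl <- buildScaleSpace(imp, scaleGrid(kmin = -0.0855, kmax = 0, kstep = 0.0855))@levels[[1]]
  # first level has sigma = 2.1214 * 2^-0.0855 ~= 2; compare against the
  # sampled 2-D Gaussian
  sg <- 2.1214 * 2^-0.0855
  x <- outer((-16):16, (-16):16, function(i, j) exp(-(i^2 + j^2) / (2 * sg^2)))
  x <- x / sum(x)
  expect_equal(sum(lvl), 1, tolerance = 1e-6)
  # small residual from the 3.5-sigma kernel truncation
  expect_lt(max(abs(lvl - x)), 5e-5)
})

test_that("images below the minimum support are rejected", {
  expect_error(buildScaleSpace(matrix(0, 8, 8)), "too small")
})

test_that("the normalized Laplacian vanishes on constants and linear ramps", {
  g <- scaleGrid(kmin = -1, kmax = 1, kstep = 1)
  lap <- normalizedLaplacian(buildScaleSpace(matrix(3, 24, 24), g))
  for (m in lap) expect_equal(m, matrix(0, 24, 24))
  expect_equal(scaleResponse(lap), c(0, 0, 0))

  ramp <- matrix(rep(1:40, each = 40), 40)
  lapR <- normalizedLaplacian(buildScaleSpace(ramp, scaleGrid(kmin = 0, kmax = 0.25, kstep = 0.25)))
  # interior pixels far enough from the reflective border see a pure linear
  # function, whose Laplacian is zero
  interior <- lapR[[1]][15:26, 15:26]
  expect_lt(max(abs(interior)), 1e-8)
  expect_true(all(vapply(lapR, function(m) all(m >= 0), logical(1))))
})

test_that("the center response of a Gaussian blob peaks at the blob scale", {
  g <- scaleGrid()
  for (sigma0 in c(3, 5)) {
    img <- blobImage(sigma0)
    lap <- normalizedLaplacian(buildScaleSpace(img, g))
    resp <- vapply(lap, function(m) m[65, 65], numeric(1))
    # closed-form oracle: sigma^2 * |lap of G(sqrt(sigma0^2+sigma^2))| at the
    # origin is proportional to sigma^2 / (sigma0^2 + sigma^2)^2, maximized
    # over the discrete grid by brute force
    oracle <- sigmas(g)^2 / (sigma0^2 + sigmas(g)^2)^2
    expect_equal(which.max(resp), which.max(oracle))
    expect_lt(abs(log2(sigmas(g)[which.max(resp)] / sigma0)), 0.25 + 1e-9)
  }
})

test_that("the scale response of a blob texture shifts by four levels under 2x magnification", {
  img <- makeTexture(textureSpec("blobs", dominantScale = 4, size = 256L, seed = 21))
  base <- transformTexture(img, 1)
  big <- transformTexture(img, 2)
  g <- scaleGrid()
  xi1 <- scaleResponse(normalizedLaplacian(buildScaleSpace(base, g)))
  xi2 <- scaleResponse(normalizedLaplacian(buildScaleSpace(big, g)))
  # 2 = 2^(4 * 0.25): the argmax moves by ~4 grid steps
  shift <- which.max(xi2) - which.max(xi1)
  expect_true(abs(shift - 4) <= 1)
})

test_that("the Gaussian fit recovers a synthetic scale response exactly", {
  g <- scaleGrid()
  xi <- 7 * exp(-((1:49) - 20)^2 / (2 * 3^2))
  est <- estimateGlobalScale(xi, g)
  expect_true(isValid(est))
  expect_equal(est@sTilde, 20, tolerance = 1e-3)
  expect_equal(uncertainty(est), 3, tolerance = 1e-3)
  # exponential interpolation of the grid at the fitted mean
  expect_equal(dominantScale(est), 2.1214 * 2^(-4 + 19 * 0.25), tolerance = 1e-4)
})

test_that("flat responses and missing maxima yield invalid estimates", {
  g <- scaleGrid()
  expect_false(isValid(estimateGlobalScale(rep(0, 49), g)))
  # monotone decreasing response: no interior first local maximum
  expect_false(isValid(estimateGlobalScale(seq(49, 1), g)))
  expect_false(isValid(estimateScale(matrix(5, 64, 64), g)))
})

test_that("an overly wide fitted Gaussian trips the uncertainty fallback", {
  g <- scaleGrid()
  xi <- exp(-((1:49) - 25)^2 / (2 * 25^2))  # u = 25 > 20 levels
  est <- estimateGlobalScale(xi, g)
  expect_false(isValid(est))
  expect_gt(uncertainty(est) / 49, 20 / 49)
})

test_that("estimated scale tracks the generated dominant scale", {
  for (sigma0 in c(3, 6)) {
    img <- makeTexture(textureSpec("blobs", dominantScale = sigma0, seed = 5))
    est <- estimateScale(img)
    expect_true(isValid(est))
    # within one grid step of the requested characteristic scale
    expect_lt(abs(log2(dominantScale(est) / sigma0)), 0.25)
  }
})
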