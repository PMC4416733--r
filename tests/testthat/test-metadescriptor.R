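test_that("descriptor structure follows the training/evaluation contract", {
  img <- makeTexture(textureSpec("oriented-noise", dominantScale = 3,
                                 dominantOrientation = 0.4, seed = 41))
  b <- baseScales(c(A = 3, B = 4, C = 5))
  dTr <- buildDescriptor(img, b, "training", ownClass = "A")
  expect_length(dTr@features, 3L)
  expect_setequal(names(dTr@features), c("A|1.5", "A|3", "A|4.5"))
  expect_false(dTr@fallback)
  dEv <- buildDescriptor(img, b, "evaluation")
  expect_length(dEv@features, 9L)
  expect_setequal(unique(vapply(dEv@features, function(h) h@classRef, character(1))),
                  c("A", "B", "C"))
  expect_error(buildDescriptor(img, b, "training"), "ownClass")
})

test_that("a constant image routes to the fixed-radius fallback", {
  b <- baseScales(c(A = 3, B = 4))
  d <- buildDescriptor(matrix(128, 64, 64), b, "evaluation")
  expect_true(d@fallback)
  expect_length(d@features, 6L)  # 2 classes x 3 radii
  radii <- vapply(d@features, function(h) h@adaptedRadius, numeric(1))
  expect_setequal(unique(radii), c(1.5, 3, 4.5))
  expect_true(all(vapply(d@features, function(h) h@fallback, logical(1))))
})

test_that("valid subsets reproduce the worked selection cases", {
  b <- baseScales(c(A = 4))
  H <- lapply(c(1.5, 3, 4.5), function(r) mockHistogram(1, "A", r))
  # equal scales at the base scale: radii {1.5, 3, 4.5} within [1, 5.44]
  expect_equal(validSubsets(H, H, 4, 4, b, "A")$keep, c(TRUE, TRUE, TRUE))
  # 2.5x: (1.5, 3.75) survives; (3, 7.5) and (4.5, 11.25) exceed 5.44
  expect_equal(validSubsets(H, H, 4, 10, b, "A")$keep, c(TRUE, FALSE, FALSE))
  # 4x: the ratio rule removes everything
  expect_equal(validSubsets(H, H, 4, 16, b, "A")$keep, c(FALSE, FALSE, FALSE))
})

test_that("subset selection matches a brute-force re-check of the three rules", {
  set.seed(77)
  for (i in 1:10000) {
    sbar <- stats::runif(1, 0.5, 10)
    s1 <- stats::runif(1, 0.2, 30)
    s2 <- stats::runif(1, 0.2, 30)
    rho <- stats::runif(1, 0.5, 6)
    r1 <- rho * s1 / sbar
    r2 <- rho * s2 / sbar
    expect_identical(soalbp:::radiusPairValid(r1, r2), naiveValidPair(r1, r2))
  }
})

test_that("increasing the scale ratio never revalidates a removed radius pair", {
  b <- baseScales(c(A = 3))
  H <- lapply(c(1.5, 3, 4.5), function(r) mockHistogram(1, "A", r))
  prev <- c(TRUE, TRUE, TRUE)
  for (q in seq(1, 6, by = 0.05)) {
    keep <- validSubsets(H, H, 3, 3 * q, b, "A")$keep
    expect_true(all(keep <= prev))  # monotone: once invalid, stays invalid
    prev <- keep
  }
})

test_that("the descriptor distance evaluates histogram intersection over valid subsets", {
  b <- baseScales(c(A = 3, B = 3))
  m1 <- mockDescriptor("A", centerBin = 2, jitter = 0)
  expect_equal(descriptorDistance(m1, m1, b), 0)
  # single surviving rho, flat toy histograms: d = 1 - sum(min)
  h1 <- new("PatternHistogram", bins = c(0.5, 0.5, rep(0, 14)), classRef = "A",
            baseRadius = 3, adaptedRadius = 3, fallback = FALSE)
  h2 <- new("PatternHistogram", bins = c(0, 0.5, 0.5, rep(0, 13)), classRef = "A",
            baseRadius = 3, adaptedRadius = 3, fallback = FALSE)
  mk <- function(h, lab) new("MetaDescriptor", features = stats::setNames(list(h), "A|3"),
    scale = new("ScaleEstimate", sTilde = 20, s = 3, u = 1, valid = TRUE),
    orientation = list(), fallback = FALSE, mode = "training", id = "", label = lab)
  expect_equal(descriptorDistance(mk(h1, "A"), mk(h2, "A"), b), 0.5)
  # different classes only: incomparable
  mB <- mockDescriptor("B", centerBin = 2)
  expect_equal(descriptorDistance(m1, mB, b), Inf)
})

test_that("the distance is symmetric and bounded for same-class pairs", {
  b <- baseScales(c(A = 3, B = 3))
  set.seed(9)
  for (i in 1:10) {
    d1 <- mockDescriptor("A", centerBin = sample(16, 1), jitter = stats::runif(1, 0, 0.5))
    d2 <- mockDescriptor("A", centerBin = sample(16, 1), jitter = stats::runif(1, 0, 0.5))
    d12 <- descriptorDistance(d1, d2, b)
    expect_identical(d12, descriptorDistance(d2, d1, b))
    expect_gte(d12, 0); expect_lte(d12, 1)
  }
})

test_that("widely separated scales make descriptors incomparable", {
  b <- baseScales(c(A = 3))
  d1 <- mockDescriptor("A", centerBin = 1, s = 3)
  d2 <- mockDescriptor("A", centerBin = 1, s = 13)
  # adapted radii stored in the features decide comparability
  for (k in names(d2@features)) {
    h <- d2@features[[k]]
    h@adaptedRadius <- h@baseRadius * 13 / 3
    d2@features[[k]] <- h
  }
  expect_identical(descriptorDistance(d1, d2, b), Inf)
})

test_that("fallback descriptors compare through their fixed radii", {
  b <- baseScales(c(A = 3, B = 4))
  img1 <- makeTexture(textureSpec("grating", dominantScale = 3,
                                  dominantOrientation = 0.3, seed = 51))
  img2 <- makeTexture(textureSpec("grating", dominantScale = 3,
                                  dominantOrientation = 0.3, seed = 52))
  d1 <- buildDescriptor(img1, b, "evaluation", adapt = FALSE)
  d2 <- buildDescriptor(img2, b, "evaluation", adapt = FALSE)
  d <- descriptorDistance(d1, d2, b)
  expect_true(is.finite(d))
  expect_gte(d, 0); expect_lte(d, 1)
})
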