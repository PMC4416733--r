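# Shared fixtures and independent oracles, built in code at test time.

# Gaussian blob image with unit peak, centered on an odd-sized grid.
blobImage <- function(sigma0, n = 129L) {
  ctr <- (n + 1) / 2
  r <- matrix(rep(seq_len(n), times = n), n)
  c <- matrix(rep(seq_len(n), each = n), n)
  matrix(exp(-((r - ctr)^2 + (c - ctr)^2) / (2 * sigma0^2)), n, n)
}

# Point-mass-with-noise pattern histogram, for cheap descriptor fixtures.
mockHistogram <- function(centerBin, classRef, rho, lambda = rho,
                          nbins = 16L, jitter = 0.02) {
  b <- rep(jitter / nbins, nbins)
  b[centerBin] <- b[centerBin] + (1 - jitter)
  new("PatternHistogram", bins = b / sum(b), classRef = classRef,
      baseRadius = rho, adaptedRadius = lambda, fallback = FALSE)
}

mockDescriptor <- function(label, centerBin, classes = label, s = 3,
                           rho = c(1.5, 3, 4.5), mode = "training",
                           jitter = 0.02) {
  feats <- list()
  for (l in classes) {
    for (r in rho) {
      feats[[paste(l, format(r), sep = "|")]] <-
        mockHistogram(centerBin, l, r, lambda = r, jitter = jitter)
    }
  }
  new("MetaDescriptor", features = feats,
      scale = new("ScaleEstimate", sTilde = 20, s = s, u = 2, valid = TRUE),
      orientation = list(), fallback = FALSE, mode = mode, id = "",
      label = label)
}

# Three structurally distinct texture classes at a common dominant scale;
# class identity is carried by the kind of structure, not by scale or
# orientation, so it survives intrinsic-scale adaption and alignment.
threeClassSpec <- function(cl, seed, size = 256L) {
  ori <- switch(cl, A = 0, B = 15 * pi / 180, C = 105 * pi / 180)
  kind <- switch(cl, A = "blobs", B = "grating", C = "oriented-noise")
  textureSpec(kind, dominantScale = 3, dominantOrientation = ori,
              size = size, seed = seed)
}

# Labeled image sets for the classification experiments: training images at
# the reference scale without rotation, evaluation images rescaled by q and
# (optionally) rotated.
threeClassImages <- function(nTrain, nEval, q = 1, rotations = 0,
                             seedOffset = 0) {
  classes <- c("A", "B", "C")
  train <- list(); evalg <- list()
  trainLab <- character(0); evalLab <- character(0)
  sd <- seedOffset
  for (cl in classes) {
    for (i in seq_len(nTrain)) {
      sd <- sd + 1
      train[[length(train) + 1]] <- transformTexture(
        makeTexture(threeClassSpec(cl, sd)), 1)
      trainLab <- c(trainLab, cl)
    }
  }
  for (cl in classes) {
    for (i in seq_len(nEval)) {
      sd <- sd + 1
      rot <- rotations[((sd - 1) %% length(rotations)) + 1]
      evalg[[length(evalg) + 1]] <- transformTexture(
        makeTexture(threeClassSpec(cl, sd + 5000)), q, rot)
      evalLab <- c(evalLab, cl)
    }
  }
  list(train = train, trainLabels = trainLab,
       eval = evalg, evalLabels = evalLab)
}

buildAll <- function(images, labels, base, mode, adapt = TRUE) {
  mapply(function(im, l) {
    d <- buildDescriptor(im, base, mode,
                         ownClass = if (mode == "training") l else NULL,
                         adapt = adapt)
    d@label <- l
    d
  }, images, labels)
}

# Independent re-statement of the three feature-validity rules, used as the
# brute-force oracle for the subset-selection implementation.
naiveValidPair <- function(r1, r2) {
  if (min(r1, r2) < 1) return(FALSE)
  if (max(r1, r2) > 5.44) return(FALSE)
  if (max(r1, r2) / min(r1, r2) > 3) return(FALSE)
  TRUE
}

# Exhaustive kNN recount: enumerate the k nearest finite-distance
# neighbors and their votes without reusing the package's ranking code.
naiveVote <- function(d, labels, k) {
  if (!any(is.finite(d))) return("unclassifiable")
  ord <- order(d)[seq_len(min(k, length(d)))]
  ord <- ord[is.finite(d[ord])]
  if (length(ord) == 0L) return("unclassifiable")
  votes <- table(labels[ord])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1L) return(winners)
  md <- sapply(winners, function(l) mean(d[ord][labels[ord] == l]))
  winners[which.min(md)]
}

absAngleErrDeg <- function(a, b) {
  d <- (a - b) %% pi
  min(d, pi - d) * 180 / pi
}
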