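DEFAULT_RHO <- c(1.5, 3, 4.5)
RADIUS_BOUNDS <- c(1, 5.44)
MAX_RADIUS_RATIO <- 3

featureKey <- function(class, rho) paste(class, format(rho), sep = "|")

#' Build a multi-resolution SOA-LBP meta-descriptor
#'
#' Estimates the global scale and orientation of an image once, then
#' computes SOA-LBP histograms for every (class, base radius) pair in scope:
#' in training mode only the image's own class is referenced (its label is
#' known), in evaluation mode every trained class is (the label is not). One
#' filtered image is computed and cached per distinct adapted radius. When
#' the scale estimate is invalid -- or \code{adapt = FALSE} -- the
#' descriptor falls back to standard multi-resolution LBP at the fixed radii
#' \code{rho} and is flagged \code{fallback}.
#'
#' @param image numeric matrix.
#' @param base a [TrainedBaseScales].
#' @param mode \code{"training"} or \code{"evaluation"}.
#' @param ownClass the image's class (required in training mode).
#' @param rho base radii (default \code{c(1.5, 3, 4.5)}).
#' @param n LBP neighbor count.
#' @param adapt set \code{FALSE} to force the fixed-radius standard-LBP
#'   path (baseline features).
#' @param grid [ScaleGrid] for scale estimation.
#' @param deltaO,stepO orientation error-compensation interval and step,
#'   degrees.
#' @param id image identifier stored in the descriptor.
#' @return A [MetaDescriptor].
#' @export
buildDescriptor <- function(image, base, mode = c("evaluation", "training"),
                            ownClass = NULL, rho = DEFAULT_RHO, n = 8L,
                            adapt = TRUE, grid = scaleGrid(),
                            deltaO = 20, stepO = 5, id = "") {
  mode <- match.arg(mode)
  if (mode == "training" && is.null(ownClass))
    stop("training mode requires ownClass")
  classes <- if (mode == "training") ownClass else trainedClasses(base)

  est <- if (adapt) estimateScale(image, grid) else
    new("ScaleEstimate", sTilde = NA_real_, s = NA_real_, u = NA_real_, valid = FALSE)

  if (!isValid(est)) {
    # fixed-radius standard LBP, duplicated across referenced classes so the
    # descriptor keeps the (class, rho) structure of the adaptive path
    feats <- list()
    for (r in rho) {
      h <- standardLBP(image, r, n)
      for (l in classes) {
        feats[[featureKey(l, r)]] <- new("PatternHistogram", bins = h@bins,
          classRef = l, baseRadius = r, adaptedRadius = r, fallback = TRUE)
      }
    }
    return(new("MetaDescriptor", features = feats, scale = est,
               orientation = list(), fallback = TRUE, mode = mode,
               id = id, label = if (is.null(ownClass)) "" else ownClass))
  }

  ori <- estimateGlobalOrientation(smmOrientationField(image, est@s))
  filteredCache <- new.env(parent = emptyenv())
  feats <- list()
  for (l in classes) {
    for (r in rho) {
      lambda <- adaptedRadius(est@s, l, r, base)
      key <- format(lambda, digits = 12)
      if (is.null(filteredCache[[key]])) {
        filteredCache[[key]] <- applySamplingKernel(image, samplingKernel(lambda, n))
      }
      feats[[featureKey(l, r)]] <- extractSoaLBP(
        image, l, est, ori, r, base, n = n, deltaO = deltaO, stepO = stepO,
        filtered = filteredCache[[key]])
    }
  }
  new("MetaDescriptor", features = feats, scale = est, orientation = list(ori),
      fallback = FALSE, mode = mode, id = id,
      label = if (is.null(ownClass)) "" else ownClass)
}

# The three removal rules of the valid-subset selection, on a pair of
# adapted radii.
radiusPairValid <- function(r1, r2,
                            bounds = RADIUS_BOUNDS, maxRatio = MAX_RADIUS_RATIO) {
  !(pmin(r1, r2) < bounds[1] | pmax(r1, r2) > bounds[2] |
      pmax(r1, r2) / pmin(r1, r2) > maxRatio)
}

#' Select valid multi-resolution feature subsets
#'
#' For two same-class multi-resolution feature sets with estimated scales
#' \eqn{s_1}, \eqn{s_2}, drops every base radius \eqn{\rho_i} whose pair of
#' adapted radii \eqn{(\lambda(s_1,l,\rho_i), \lambda(s_2,l,\rho_i))}
#' violates any of: minimum below 1 pixel, maximum above 5.44 pixels, or
#' ratio above 3. The bounds delimit the radii found discriminative for LBP;
#' the ratio caps the compensable scale difference. The surviving pairs (and
#' their indices in \code{rho}) are returned; an empty result is legal and
#' marks the pair of descriptors as incomparable for this class.
#'
#' @param H1,H2 lists of [PatternHistogram] computed in reference to the
#'   same class, ordered as \code{rho}.
#' @param s1,s2 estimated scales of the two images.
#' @param base a [TrainedBaseScales].
#' @param class the referenced class.
#' @param rho the base radii of the features.
#' @return list with \code{V1}, \code{V2} (surviving histograms) and
#'   \code{keep} (logical over \code{rho}).
#' @export
validSubsets <- function(H1, H2, s1, s2, base, class, rho = DEFAULT_RHO) {
  stopifnot(length(H1) == length(rho), length(H2) == length(rho))
  r1 <- vapply(rho, function(r) adaptedRadius(s1, class, r, base), numeric(1))
  r2 <- vapply(rho, function(r) adaptedRadius(s2, class, r, base), numeric(1))
  keep <- radiusPairValid(r1, r2)
  list(V1 = H1[keep], V2 = H2[keep], keep = keep)
}

# Histogram-intersection distance between two equal-length sets of
# normalized histograms, concatenated and renormalized to total mass 1.
intersectionDistance <- function(H1, H2) {
  m <- length(H1)
  b1 <- unlist(lapply(H1, function(h) h@bins)) / m
  b2 <- unlist(lapply(H2, function(h) h@bins)) / m
  1 - sum(pmin(b1, b2))
}

#' Distance between two meta-descriptors
#'
#' For every class referenced by both descriptors, applies [validSubsets()]
#' to the per-radius features (fallback features take their fixed radii as
#' adapted radii), concatenates the surviving normalized histograms
#' (renormalized to total mass 1) and computes the histogram-intersection
#' distance \eqn{d = 1 - \sum_i \min(H_1(i), H_2(i))}. Features referencing
#' different classes are incomparable (distance \eqn{\infty}); the
#' descriptor distance is the minimum over classes, or \eqn{\infty} when
#' every class yields an empty valid subset.
#'
#' @param M1,M2 [MetaDescriptor] objects built against the same
#'   [TrainedBaseScales].
#' @param base the [TrainedBaseScales] both descriptors were built against.
#' @return a number in \eqn{[0, 1]}, or \code{Inf}.
#' @export
descriptorDistance <- function(M1, M2, base) {
  f1 <- M1@features; f2 <- M2@features
  cls1 <- unique(vapply(f1, function(h) h@classRef, character(1)))
  cls2 <- unique(vapply(f2, function(h) h@classRef, character(1)))
  common <- intersect(cls1, cls2)
  best <- Inf
  for (l in common) {
    h1 <- f1[vapply(f1, function(h) identical(h@classRef, l), logical(1))]
    h2 <- f2[vapply(f2, function(h) identical(h@classRef, l), logical(1))]
    rho1 <- vapply(h1, function(h) h@baseRadius, numeric(1))
    rho2 <- vapply(h2, function(h) h@baseRadius, numeric(1))
    rhos <- sort(intersect(rho1, rho2))
    if (length(rhos) == 0L) next
    h1 <- h1[match(rhos, rho1)]
    h2 <- h2[match(rhos, rho2)]
    r1 <- vapply(h1, function(h) h@adaptedRadius, numeric(1))
    r2 <- vapply(h2, function(h) h@adaptedRadius, numeric(1))
    keep <- radiusPairValid(r1, r2)
    if (!any(keep)) next
    d <- intersectionDistance(h1[keep], h2[keep])
    if (d < best) best <- d
  }
  best
}

setMethod("show", "MetaDescriptor", function(object) {
  cat(sprintf("MetaDescriptor (%s%s): %d features%s%s\n",
              object@mode, if (object@fallback) ", fallback" else "",
              length(object@features),
              if (nzchar(object@label)) paste0(", label ", object@label) else "",
              if (nzchar(object@id)) paste0(", id ", object@id) else ""))
  show(object@scale)
  if (length(object@orientation)) show(object@orientation[[1]])
})
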