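#' Learn per-class trained base scales
#'
#' Estimates the global scale of every training image and takes, per class,
#' the median of the valid estimates as that class's trained base scale
#' \eqn{\bar{s}_l}. Images whose scale estimation fails (invalid estimate)
#' are excluded from the median; a class with no valid estimate is an error.
#'
#' @param images list of numeric matrices, or of [ScaleEstimate] objects
#'   (already-estimated scales are accepted to avoid recomputation).
#' @param labels character vector of class labels, one per image.
#' @param grid [ScaleGrid] used for estimation.
#' @return A [TrainedBaseScales].
#' @export
trainBaseScales <- function(images, labels, grid = scaleGrid()) {
  stopifnot(length(images) == length(labels), length(images) > 0L)
  labels <- as.character(labels)
  ests <- lapply(images, function(x) {
    if (is(x, "ScaleEstimate")) x else estimateScale(x, grid)
  })
  scales <- vapply(split(ests, labels), function(e) {
    s <- vapply(e, function(x) if (isValid(x)) x@s else NA_real_, numeric(1))
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(NA_real_)
    stats::median(s)
  }, numeric(1))
  bad <- names(scales)[is.na(scales)]
  if (length(bad) > 0L)
    stop("no valid scale estimate for class: ", paste(bad, collapse = ", "))
  new("TrainedBaseScales", scales = scales)
}

#' Trained base scales from known values
#'
#' @param scales named positive numeric vector (class -> scale in pixels).
#' @return A [TrainedBaseScales].
#' @export
baseScales <- function(scales) new("TrainedBaseScales", scales = scales)

#' @describeIn baseScales the reference scale of one class.
#' @param base a \code{TrainedBaseScales}.
#' @param class class label.
#' @export
baseScaleOf <- function(base, class) {
  if (!class %in% names(base@scales)) stop("unknown class: ", class)
  unname(base@scales[class])
}

#' @describeIn baseScales the trained class names.
#' @export
trainedClasses <- function(base) names(base@scales)

#' Intrinsic-scale-adapted LBP radius
#'
#' \eqn{\lambda(s, l, \rho) = \rho\,s/\bar{s}_l}: the radius used for an
#' image with estimated scale \eqn{s} in reference to the trained base scale
#' of class \eqn{l}, with base radius \eqn{\rho} the radius used at the
#' trained base scale itself. Linearity in \eqn{s} is what makes the adapted
#' representation scale-invariant; the intrinsic texture scale cancels in
#' the ratio.
#'
#' @param s estimated spatial scale, pixels.
#' @param class class label \eqn{l}.
#' @param rho base radius.
#' @param base a [TrainedBaseScales].
#' @return adapted radius, pixels.
#' @examples
#' b <- baseScales(c(wood = 4))
#' adaptedRadius(8, "wood", 3, b)  # 6
#' @export
adaptedRadius <- function(s, class, rho, base) {
  stopifnot(s > 0, rho > 0)
  rho * s / baseScaleOf(base, class)
}

setMethod("show", "TrainedBaseScales", function(object) {
  cat("TrainedBaseScales:\n")
  for (l in names(object@scales))
    cat(sprintf("  %s: %.3f px\n", l, object@scales[l]))
})
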