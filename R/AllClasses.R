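#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib soalbp, .registration = TRUE
NULL

#' Exponential grid of scale-space levels
#'
#' A \code{ScaleGrid} holds the standard deviations \eqn{\sigma_i = c\,2^{k_i}}
#' of the Gaussian scale-space levels, parametrized by a scaling factor
#' \eqn{c} and an ordered sequence of exponents \eqn{k_i}. The default
#' parametrization (\eqn{c = 2.1214}, \eqn{k_i \in \{-4, -3.75, \dots, 8\}})
#' spans 49 levels; the center scale corresponds to an LBP radius of 3
#' (the spatial extent of a structure at scale \eqn{\sigma} is taken as
#' \eqn{\sigma\sqrt{2}}).
#'
#' @slot c positive scaling factor in pixels.
#' @slot exponents ordered numeric vector of exponents \eqn{k_i}.
#' @slot sigmas numeric vector \eqn{c\,2^{k_i}}, strictly increasing.
#' @seealso [scaleGrid()], [buildScaleSpace()]
#' @export
setClass("ScaleGrid",
  representation(c = "numeric", exponents = "numeric", sigmas = "numeric"))

setValidity("ScaleGrid", function(object) {
  if (length(object@c) != 1L || object@c <= 0) return("c must be a single positive number")
  if (length(object@exponents) < 2L) return("need at least two scale levels")
  if (is.unsorted(object@exponents, strictly = TRUE)) return("exponents must be strictly increasing")
  if (!isTRUE(all.equal(object@sigmas, object@c * 2^object@exponents)))
    return("sigmas inconsistent with c and exponents")
  TRUE
})

#' Gaussian scale-space of an image
#'
#' Stack of progressively Gaussian-smoothed versions \eqn{L(\cdot;\sigma_i)}
#' of an image, one per level of a [ScaleGrid].
#'
#' @slot grid the [ScaleGrid] used.
#' @slot levels list of numeric matrices, one per \eqn{\sigma_i}, all with
#'   the dimensions of the input image.
#' @seealso [buildScaleSpace()], [normalizedLaplacian()]
#' @export
setClass("ScaleSpace", representation(grid = "ScaleGrid", levels = "list"))

setValidity("ScaleSpace", function(object) {
  if (length(object@levels) != length(object@grid@sigmas))
    return("number of levels must equal grid length")
  d <- dim(object@levels[[1]])
  ok <- vapply(object@levels, function(l) is.matrix(l) && identical(dim(l), d), logical(1))
  if (!all(ok)) return("all levels must be matrices of identical dimension")
  TRUE
})

#' Global scale estimate of an image
#'
#' Result of fitting a Gaussian to the scale response function \eqn{\xi}
#' around its first local maximum. \code{sTilde} is the fitted mean
#' (fractional scale-level index, 1-based), \code{u} the fitted standard
#' deviation in scale-level units used as estimation uncertainty, and
#' \code{s} the dominant spatial scale in pixels obtained by exponential
#' interpolation of the grid at \code{sTilde}. The estimate is flagged
#' invalid when \code{u} normalized by the number of levels exceeds the
#' fallback threshold (default \eqn{20/n}).
#'
#' @slot sTilde fractional dominant scale-level index.
#' @slot s dominant spatial scale, pixels (sigma units).
#' @slot u uncertainty, scale-level units.
#' @slot valid logical validity flag.
#' @seealso [estimateGlobalScale()], [estimateScale()]
#' @export
setClass("ScaleEstimate",
  representation(sTilde = "numeric", s = "numeric", u = "numeric", valid = "logical"))

setValidity("ScaleEstimate", function(object) {
  if (isTRUE(object@valid) && (!is.finite(object@s) || object@s <= 0))
    return("a valid estimate requires s > 0")
  TRUE
})

#' Field of local orientations
#'
#' Per-pixel local orientations (radians in \eqn{[0,\pi)}) derived from the
#' eigen-structure of multi-scale second-moment matrices; undefined pixels
#' (degenerate, near-zero gradient energy) are \code{NA}.
#'
#' @slot angles numeric matrix of orientations in \eqn{[0,\pi)}, \code{NA}
#'   where undefined.
#' @slot localScale derivative scale, pixels.
#' @slot integrationScale integration scale, pixels (twice the local scale).
#' @seealso [smmOrientationField()], [estimateGlobalOrientation()]
#' @export
setClass("OrientationField",
  representation(angles = "matrix", localScale = "numeric", integrationScale = "numeric"))

setValidity("OrientationField", function(object) {
  a <- object@angles
  if (any(!is.na(a) & (a < 0 | a >= pi))) return("angles must lie in [0, pi)")
  if (object@localScale <= 0) return("localScale must be positive")
  TRUE
})

#' Global orientation estimate
#'
#' @slot o global orientation, radians in \eqn{[0,\pi)}.
#' @slot fitStd standard deviation of the Gaussian fitted to the local
#'   orientation distribution, radians (\code{NA} if the fit did not
#'   converge and the histogram mode was used instead).
#' @seealso [estimateGlobalOrientation()]
#' @export
setClass("OrientationEstimate", representation(o = "numeric", fitStd = "numeric"))

setValidity("OrientationEstimate", function(object) {
  if (object@o < 0 || object@o >= pi) return("o must lie in [0, pi)")
  TRUE
})

#' Normalized histogram of local binary patterns
#'
#' @slot bins numeric vector of \eqn{2^n} non-negative bin masses summing
#'   to 1.
#' @slot classRef character, the texture class whose trained base scale the
#'   feature was computed against (\code{NA} for plain LBP).
#' @slot baseRadius base radius \eqn{\rho} (the radius used at the trained
#'   base scale).
#' @slot adaptedRadius the radius actually used, \eqn{\lambda = \rho s/\bar{s}_l}.
#' @slot fallback TRUE when the histogram comes from the fixed-radius
#'   standard-LBP fallback path.
#' @export
setClass("PatternHistogram",
  representation(bins = "numeric", classRef = "character", baseRadius = "numeric",
                 adaptedRadius = "numeric", fallback = "logical"))

setValidity("PatternHistogram", function(object) {
  nb <- length(object@bins)
  if (nb < 16L || bitwAnd(nb, nb - 1L) != 0L) return("bin count must be a power of two >= 16")
  if (any(object@bins < 0)) return("bins must be non-negative")
  if (abs(sum(object@bins) - 1) > 1e-9) return("bins must sum to 1")
  TRUE
})

#' Per-class trained base scales
#'
#' One reference scale \eqn{\bar{s}_l} per texture class: the median of the
#' valid global scale estimates over that class's training images. Adapted
#' LBP radii are computed relative to these references, which cancels the
#' intrinsic scale of a texture out of the radius computation.
#'
#' @slot scales named numeric vector, one positive entry per class.
#' @seealso [trainBaseScales()], [adaptedRadius()]
#' @export
setClass("TrainedBaseScales", representation(scales = "numeric"))

setValidity("TrainedBaseScales", function(object) {
  if (is.null(names(object@scales)) || any(!nzchar(names(object@scales))))
    return("scales must be named by class")
  if (anyDuplicated(names(object@scales))) return("duplicate class names")
  if (any(!is.finite(object@scales) | object@scales <= 0)) return("scales must be positive")
  TRUE
})

#' Multi-resolution SOA-LBP meta-descriptor
#'
#' The set of [PatternHistogram] features of one image: in training mode one
#' histogram per base radius against the image's own class; in evaluation
#' mode one per (class, base radius) pair over every trained class. When the
#' global scale estimate is invalid the features revert to fixed-radius
#' standard LBP and \code{fallback} is set.
#'
#' @slot features list of [PatternHistogram] objects.
#' @slot scale the image's [ScaleEstimate].
#' @slot orientation the image's [OrientationEstimate] (may be absent for
#'   scale-only features; stored as a list of length 0 or 1).
#' @slot fallback logical.
#' @slot mode "training" or "evaluation".
#' @slot id image identifier.
#' @slot label class label ("" when unknown).
#' @seealso [buildDescriptor()], [descriptorDistance()]
#' @export
setClass("MetaDescriptor",
  representation(features = "list", scale = "ScaleEstimate", orientation = "list",
                 fallback = "logical", mode = "character", id = "character",
                 label = "character"))

setValidity("MetaDescriptor", function(object) {
  if (!object@mode %in% c("training", "evaluation")) return("mode must be training or evaluation")
  ok <- vapply(object@features, is, logical(1), class2 = "PatternHistogram")
  if (!all(ok)) return("features must be PatternHistogram objects")
  if (object@mode == "training") {
    cls <- unique(vapply(object@features, function(h) h@classRef, character(1)))
    cls <- cls[!is.na(cls)]
    if (length(cls) > 1L) return("training descriptors must reference a single class")
  }
  TRUE
})

#' Descriptor store
#'
#' Serializable container pairing [TrainedBaseScales] with a list of
#' [MetaDescriptor] records; written and read as JSON lines.
#'
#' @slot version store format version string.
#' @slot baseScales a [TrainedBaseScales].
#' @slot descriptors list of [MetaDescriptor].
#' @seealso [saveStore()], [loadStore()]
#' @export
setClass("DescriptorStore",
  representation(version = "character", baseScales = "TrainedBaseScales",
                 descriptors = "list"))
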