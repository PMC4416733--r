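STORE_VERSION <- "1.0"

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF image as a numeric matrix with
#' intensities in \eqn{[0, 255]}. Multi-channel images are converted to
#' grayscale by the channel mean; an alpha channel, if present, is dropped.
#'
#' @param path file path (.png, .tif or .tiff).
#' @return numeric matrix.
#' @export
readTextureImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                "png" = png::readPNG(path),
                "tif" = ,
                "tiff" = tiff::readTIFF(path),
                stop("unsupported image format: ", path))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 2L || nch == 4L) nch <- nch - 1L  # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  arr * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image numeric matrix with intensities in \eqn{[0, 255]} (values
#'   are clamped).
#' @param path output path.
#' @export
writeTextureImage <- function(image, path) {
  m <- image / 255
  m[m < 0] <- 0
  m[m > 1] <- 1
  png::writePNG(m, path)
  invisible(path)
}

histogramToRecord <- function(h) {
  list(class = h@classRef, rho = h@baseRadius, lambda = h@adaptedRadius,
       fallback = h@fallback, bins = h@bins)
}

recordToHistogram <- function(rec) {
  new("PatternHistogram", bins = as.numeric(rec$bins),
      classRef = as.character(rec$class), baseRadius = rec$rho,
      adaptedRadius = rec$lambda, fallback = isTRUE(rec$fallback))
}

descriptorToRecord <- function(d) {
  list(type = "descriptor", id = d@id, label = d@label, mode = d@mode,
       fallback = d@fallback,
       scale = list(sTilde = d@scale@sTilde, s = d@scale@s, u = d@scale@u,
                    valid = d@scale@valid),
       orientation = if (length(d@orientation)) {
         list(o = d@orientation[[1]]@o, fitStd = d@orientation[[1]]@fitStd)
       },
       features = unname(lapply(d@features, histogramToRecord)))
}

recordToDescriptor <- function(rec) {
  feats <- lapply(rec$features, recordToHistogram)
  names(feats) <- vapply(feats, function(h) featureKey(h@classRef, h@baseRadius),
                         character(1))
  sc <- rec$scale
  est <- new("ScaleEstimate",
             sTilde = if (is.null(sc$sTilde)) NA_real_ else as.numeric(sc$sTilde),
             s = if (is.null(sc$s)) NA_real_ else as.numeric(sc$s),
             u = if (is.null(sc$u)) NA_real_ else as.numeric(sc$u),
             valid = isTRUE(sc$valid))
  ori <- if (!is.null(rec$orientation)) {
    list(new("OrientationEstimate", o = as.numeric(rec$orientation$o),
             fitStd = if (is.null(rec$orientation$fitStd)) NA_real_
                      else as.numeric(rec$orientation$fitStd)))
  } else list()
  new("MetaDescriptor", features = feats, scale = est, orientation = ori,
      fallback = isTRUE(rec$fallback), mode = rec$mode,
      id = as.character(rec$id), label = as.character(rec$label))
}

#' Create a descriptor store
#'
#' @param base a [TrainedBaseScales].
#' @param descriptors list of [MetaDescriptor].
#' @return A [DescriptorStore].
#' @export
descriptorStore <- function(base, descriptors = list()) {
  new("DescriptorStore", version = STORE_VERSION, baseScales = base,
      descriptors = descriptors)
}

#' Save a descriptor store as JSON lines
#'
#' One header line (format version and trained base scales) followed by one
#' JSON record per descriptor. Numbers are written at full precision, so a
#' save/load round trip leaves descriptor distances unchanged.
#'
#' @param store a [DescriptorStore].
#' @param path output path.
#' @export
saveStore <- function(store, path) {
  stopifnot(is(store, "DescriptorStore"))
  header <- list(type = "header", version = store@version,
                 baseScales = as.list(store@baseScales@scales))
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"),
    vapply(store@descriptors, function(d)
      as.character(jsonlite::toJSON(descriptorToRecord(d), auto_unbox = TRUE,
                                    digits = NA, null = "null")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Load a descriptor store from JSON lines
#'
#' Verifies the format version and re-validates every histogram
#' (normalization, bin count) on read; a malformed file fails without
#' partial state.
#'
#' @param path file written by [saveStore()].
#' @return A [DescriptorStore].
#' @export
loadStore <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty store file: ", path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  if (!identical(header$type, "header")) stop("not a descriptor store: ", path)
  if (!identical(header$version, STORE_VERSION))
    stop("store version mismatch: found ", header$version,
         ", expected ", STORE_VERSION)
  scales <- unlist(header$baseScales)
  base <- new("TrainedBaseScales", scales = scales)
  descs <- lapply(lines[-1], function(l)
    recordToDescriptor(jsonlite::fromJSON(l, simplifyVector = FALSE)))
  for (d in descs) {
    validObject(d)
    for (h in d@features) validObject(h)
  }
  new("DescriptorStore", version = STORE_VERSION, baseScales = base,
      descriptors = descs)
}

setMethod("show", "DescriptorStore", function(object) {
  cat(sprintf("DescriptorStore v%s: %d classes, %d descriptors\n",
              object@version, length(object@baseScales@scales),
              length(object@descriptors)))
})
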