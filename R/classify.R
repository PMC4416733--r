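# Vote on a single query given its distances to all training descriptors.
# Infinite distances rank last and carry no class evidence; ties on
# distance are broken by training-set order (stable sort), ties on vote by
# the smallest mean distance among the tied classes.
voteFromDistances <- function(d, labels, k) {
  if (all(!is.finite(d))) return("unclassifiable")
  ord <- order(d)            # stable: equal distances keep training order
  nn <- ord[seq_len(min(k, length(d)))]
  nn <- nn[is.finite(d[nn])]
  if (length(nn) == 0L) return("unclassifiable")
  tab <- table(labels[nn])
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  means <- vapply(top, function(l) mean(d[nn][labels[nn] == l]), numeric(1))
  top[which.min(means)]
}

#' k-nearest-neighbor classification of a meta-descriptor
#'
#' Majority vote over the \code{k} training descriptors closest in
#' [descriptorDistance()]. Infinite distances (incomparable descriptors)
#' rank last and are excluded from the vote; a query at infinite distance
#' from every training descriptor is \code{"unclassifiable"} (counted as an
#' error by the evaluation harness).
#'
#' @param query a [MetaDescriptor] (evaluation mode).
#' @param training list of training [MetaDescriptor]s with labels.
#' @param k neighbor count.
#' @param base the [TrainedBaseScales] the descriptors were built against.
#' @return class label, or \code{"unclassifiable"}.
#' @export
knnClassify <- function(query, training, k, base) {
  stopifnot(k >= 1L, length(training) > 0L)
  d <- vapply(training, function(tr) descriptorDistance(query, tr, base), numeric(1))
  labels <- vapply(training, function(tr) tr@label, character(1))
  voteFromDistances(d, labels, k)
}

#' Distance matrix between evaluation and training descriptors
#'
#' @param evalDescs,trainDescs lists of [MetaDescriptor].
#' @param base the common [TrainedBaseScales].
#' @return numeric matrix, rows = evaluation, columns = training.
#' @export
distanceMatrix <- function(evalDescs, trainDescs, base) {
  m <- matrix(Inf, length(evalDescs), length(trainDescs))
  for (i in seq_along(evalDescs)) {
    for (j in seq_along(trainDescs)) {
      m[i, j] <- descriptorDistance(evalDescs[[i]], trainDescs[[j]], base)
    }
  }
  m
}

sampleStratified <- function(labels, fraction) {
  idx <- seq_along(labels)
  unlist(lapply(split(idx, labels), function(i) {
    ns <- max(1L, round(fraction * length(i)))
    if (length(i) == 1L) i else sample(i, ns)
  }), use.names = FALSE)
}

#' Scale-constrained cross-validation
#'
#' Evaluation harness mirroring a scale-constrained protocol: training
#' descriptors come from images at one fixed scale, evaluation descriptors
#' from images at a probe scale. Each iteration draws a stratified random
#' 75\% of the training set and 25\% of the evaluation set, classifies every
#' sampled evaluation descriptor with [knnClassify()] for every
#' \eqn{k = 1..k_{max}} (\eqn{k_{max}} = smallest per-class count in the
#' sampled training subset, capped at \code{kMax}), and records the
#' accuracy. Unclassifiable queries count as errors. The reported accuracy
#' is the mean over all \eqn{k} and iterations; the standard deviation is
#' over the per-iteration means.
#'
#' @param trainDescs,evalDescs lists of labeled [MetaDescriptor]s.
#' @param base the common [TrainedBaseScales].
#' @param iterations number of cross-validation iterations (default 100).
#' @param trainFraction,evalFraction sampling fractions (defaults 0.75,
#'   0.25).
#' @param kMax cap on the neighbor count (default 20).
#' @param seed integer seed; identical seeds reproduce identical subsets
#'   and accuracies.
#' @param distances optional precomputed [distanceMatrix()] (rows =
#'   evaluation, columns = training).
#' @return list with \code{accuracy} (mean), \code{std} (over iterations)
#'   and \code{perIteration}.
#' @export
scaleConstrainedCV <- function(trainDescs, evalDescs, base, iterations = 100,
                               trainFraction = 0.75, evalFraction = 0.25,
                               kMax = 20, seed = 1, distances = NULL) {
  stopifnot(iterations >= 1, trainFraction > 0, trainFraction <= 1,
            evalFraction > 0, evalFraction <= 1)
  trainLab <- vapply(trainDescs, function(d) d@label, character(1))
  evalLab <- vapply(evalDescs, function(d) d@label, character(1))
  if (any(!nzchar(trainLab)) || any(!nzchar(evalLab)))
    stop("all descriptors must carry labels")
  if (is.null(distances)) distances <- distanceMatrix(evalDescs, trainDescs, base)

  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(seed)

  perIter <- numeric(iterations)
  for (it in seq_len(iterations)) {
    ti <- sampleStratified(trainLab, trainFraction)
    ei <- sampleStratified(evalLab, evalFraction)
    kmax <- min(kMax, min(table(trainLab[ti])))
    accs <- numeric(kmax)
    for (k in seq_len(kmax)) {
      pred <- vapply(ei, function(i)
        voteFromDistances(distances[i, ti], trainLab[ti], k), character(1))
      accs[k] <- mean(pred == evalLab[ei])
    }
    perIter[it] <- mean(accs)
  }
  list(accuracy = mean(perIter), std = stats::sd(perIter), perIteration = perIter)
}
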