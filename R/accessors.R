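#' Node labels and counts
#'
#' @param object a [RoiTimeSeriesSet-class] or [DirectedNetwork-class].
#' @return \code{nodes()}: character vector of node labels; \code{nNodes()}:
#'   integer.
#' @name nodes
#' @aliases nodes,DirectedNetwork-method
#' @export
setMethod("nodes", "DirectedNetwork", function(object) object@nodes)

#' @rdname nodes
#' @export
setMethod("nodes", "RoiTimeSeriesSet", function(object) object@nodeLabels)

#' @rdname nodes
#' @export
setMethod("nNodes", "DirectedNetwork",
          function(object) length(object@nodes))

#' @rdname nodes
#' @export
setMethod("nNodes", "RoiTimeSeriesSet",
          function(object) dim(object@values)[2L])

#' Number of trials / frames in a time-series set
#'
#' @param object a [RoiTimeSeriesSet-class].
#' @return integer.
#' @export
nTrials <- function(object) dim(object@values)[3L]

#' @rdname nTrials
#' @export
nFrames <- function(object) dim(object@values)[1L]

#' Weight matrix of a directed network
#'
#' @param object a [DirectedNetwork-class].
#' @return the square numeric weight matrix (rows = sources,
#'   columns = targets).
#' @name weightMatrix
#' @export
setMethod("weightMatrix", "DirectedNetwork", function(object) object@weights)

#' Edge list of a directed network
#'
#' @param object a [DirectedNetwork-class].
#' @param ... unused.
#' @return data.frame with columns source, target, weight, p_value, one row
#'   per nonzero edge, in column-major (target-major) node order.
#' @name edgeList
#' @export
setMethod("edgeList", "DirectedNetwork", function(object, ...) {
  idx <- which(object@weights > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    source = object@nodes[idx[, 1L]],
    target = object@nodes[idx[, 2L]],
    weight = object@weights[idx],
    p_value = object@pvalues[idx],
    stringsAsFactors = FALSE
  )
})

#' Values of a coreness or node-metric map
#'
#' @param x a [CorenessMap-class] or [NodeMetricMap-class].
#' @param normalized logical; for coreness maps, return the max-normalized
#'   values instead.
#' @return named numeric vector.
#' @export
metricValues <- function(x, normalized = FALSE) {
  if (is(x, "CorenessMap")) {
    if (normalized) {
      if (length(x@normalized) == 0)
        stop("normalized coreness not computed")
      return(x@normalized)
    }
    return(x@values)
  }
  if (is(x, "NodeMetricMap")) return(x@values)
  stop("not a CorenessMap or NodeMetricMap")
}

#' Complexes as a data frame
#'
#' @param decomp a [ComplexDecomposition-class].
#' @return data.frame with columns complex_id, mc_weight, parent_id, members
#'   (comma-joined labels), n_members.
#' @export
complexTable <- function(decomp) {
  stopifnot(is(decomp, "ComplexDecomposition"))
  k <- length(decomp@members)
  data.frame(
    complex_id = seq_len(k),
    mc_weight = decomp@mcWeights,
    parent_id = decomp@parent,
    members = vapply(decomp@members, paste, character(1), collapse = ","),
    n_members = vapply(decomp@members, length, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Members of the strongest complex
#'
#' @param decomp a [ComplexDecomposition-class].
#' @param rank which complex, 1 = largest min-cut weight.
#' @return character vector of node labels (sorted), or NULL if there are
#'   fewer than \code{rank} complexes.
#' @export
complexMembers <- function(decomp, rank = 1L) {
  stopifnot(is(decomp, "ComplexDecomposition"))
  if (rank > length(decomp@members)) return(NULL)
  sort(decomp@members[[rank]])
}

setMethod("show", "RoiTimeSeriesSet", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "RoiTimeSeriesSet: %d frames x %d nodes x %d trials (dt = %g s)%s\n",
    d[1L], d[2L], d[3L], object@samplingInterval,
    if (object@preprocessed) ", preprocessed" else ""))
  cat("nodes:", paste(utils::head(object@nodeLabels, 8), collapse = ", "),
      if (d[2L] > 8) "..." else "", "\n")
})

setMethod("show", "DirectedNetwork", function(object) {
  m <- sum(object@weights > 0)
  n <- length(object@nodes)
  cat(sprintf("DirectedNetwork: %d nodes, %d edges (density %.3f)\n",
              n, m, if (n > 1) m / (n * (n - 1)) else 0))
  cat("total weight:", sum(object@weights), "\n")
})

setMethod("show", "ComplexDecomposition", function(object) {
  cat(sprintf("ComplexDecomposition: %d complexes on %d nodes\n",
              length(object@members), length(object@nodes)))
  if (length(object@members) > 0) {
    print(utils::head(complexTable(object), 10))
    if (length(object@members) > 10) cat("...\n")
  }
})

setMethod("show", "CorenessMap", function(object) {
  cat(sprintf("CorenessMap%s: %d nodes, max coreness %g\n",
              if (nzchar(object@conditionLabel))
                paste0(" [", object@conditionLabel, "]") else "",
              length(object@values), max(object@values)))
  print(utils::head(sort(object@values, decreasing = TRUE), 8))
})

setMethod("show", "NodeMetricMap", function(object) {
  cat(sprintf("NodeMetricMap (%s): %d nodes\n", object@metricKind,
              length(object@values)))
  print(utils::head(sort(object@values, decreasing = TRUE), 8))
})

setMethod("show", "EdgeEstimate", function(object) {
  cat(sprintf(
    "EdgeEstimate %s -> %s: TE = %.5g nats, norm = %.5g, NDTE = %.5g%s\n",
    object@source, object@target, object@te, object@normFactor, object@ndte,
    if (!is.na(object@pValue)) sprintf(", p = %.4g", object@pValue) else ""))
})

setMethod("show", "CutResult", function(object) {
  if (length(object@left) == 0 && length(object@right) == 0) {
    cat("CutResult: single node, strength 0\n")
  } else {
    cat(sprintf(
      "CutResult: |L| = %d, |R| = %d, w(L->R) = %g, w(R->L) = %g, strength = %g\n",
      length(object@left), length(object@right),
      object@forwardWeight, object@backwardWeight, object@strength))
  }
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("r = %.4f, %s 95%% CI [%.4f, %.4f] (n = %d, %d resamples)\n",
              object@r, object@method, object@ciLow, object@ciHigh,
              object@n, object@nBoot))
})

setMethod("show", "BivariateVarModel", function(object) {
  cat(sprintf("BivariateVarModel: order %d, %d pooled observations\n",
              object@lagOrder, object@nEffectiveObs))
  cat("residual covariance:\n")
  print(object@residualCovariance)
})
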