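#' @import methods
NULL

#' Multi-trial region-of-interest time series
#'
#' Container for multi-trial, multi-node time series, the input to directed
#' network estimation. Values are stored as a numeric array with dimensions
#' (time, node, trial) so that a single trial is a plain time-by-node matrix.
#' After preprocessing (per-series z-scoring followed by zero-phase band-pass
#' filtering) the \code{preprocessed} flag is set.
#'
#' @slot values numeric array, dim = c(nTime, nNodes, nTrials).
#' @slot nodeLabels character vector of node (region) names.
#' @slot samplingInterval sampling interval in seconds per frame.
#' @slot preprocessed logical flag set by [preprocessTimeSeries()].
#'
#' @seealso [RoiTimeSeriesSet()], [preprocessTimeSeries()],
#'   [buildDirectedNetwork()]
#' @export
setClass("RoiTimeSeriesSet",
  representation(
    values = "array",
    nodeLabels = "character",
    samplingInterval = "numeric",
    preprocessed = "logical"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("values must be a 3-d array (time, node, trial)")
  if (dim(v)[2L] != length(object@nodeLabels))
    return("length(nodeLabels) must equal dim(values)[2]")
  if (anyDuplicated(object@nodeLabels))
    return("node labels must be unique")
  if (any(!is.finite(v)))
    return("values contain missing or non-finite entries")
  if (length(object@samplingInterval) != 1L || object@samplingInterval <= 0)
    return("samplingInterval must be a single positive number")
  if (length(object@preprocessed) != 1L)
    return("preprocessed must be a single logical")
  TRUE
})

#' Construct a RoiTimeSeriesSet
#'
#' @param values numeric array (time, node, trial); a time-by-node matrix is
#'   promoted to a single trial.
#' @param nodeLabels character node names; defaults to column names of
#'   \code{values} or \code{"N1"..}.
#' @param samplingInterval seconds per frame (default 0.72, a typical fMRI TR).
#' @param preprocessed logical; whether the series are already z-scored and
#'   band-pass filtered.
#' @return A [RoiTimeSeriesSet-class] object.
#' @examples
#' x <- array(rnorm(100 * 3 * 2), c(100, 3, 2))
#' ts <- RoiTimeSeriesSet(x, nodeLabels = c("A", "B", "C"))
#' nNodes(ts)
#' @export
RoiTimeSeriesSet <- function(values, nodeLabels = NULL,
                             samplingInterval = 0.72,
                             preprocessed = FALSE) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (is.null(nodeLabels)) {
    nodeLabels <- dimnames(values)[[2L]]
    if (is.null(nodeLabels)) nodeLabels <- paste0("N", seq_len(dim(values)[2L]))
  }
  dimnames(values) <- list(NULL, nodeLabels, NULL)
  new("RoiTimeSeriesSet", values = values, nodeLabels = nodeLabels,
      samplingInterval = as.numeric(samplingInterval),
      preprocessed = preprocessed)
}

#' Estimation parameters for directed network construction
#'
#' Bundles the tunable parameters of the NDTE network estimation stage.
#' Defaults follow common practice for BOLD-like series: VAR lag order 10,
#' 100 block-permutation surrogates with block size equal to the lag order,
#' alpha 0.05 with Bonferroni correction over all ordered node pairs, and no
#' density thresholding (density = 1).
#'
#' @slot lagOrder positive integer, VAR model order.
#' @slot nSurrogates positive integer, number of surrogate data sets per edge.
#' @slot blockSize positive integer, block length for block permutation.
#' @slot alpha significance level in (0, 1).
#' @slot correction "bonferroni" or "none".
#' @slot density fraction of strongest edges retained, in (0, 1].
#' @slot seed integer seed controlling all surrogate randomness.
#' @export
setClass("EstimationParams",
  representation(
    lagOrder = "integer",
    nSurrogates = "integer",
    blockSize = "integer",
    alpha = "numeric",
    correction = "character",
    density = "numeric",
    seed = "integer"
  )
)

setValidity("EstimationParams", function(object) {
  if (object@lagOrder < 1L) return("lagOrder must be >= 1")
  if (object@nSurrogates < 1L) return("nSurrogates must be >= 1")
  if (object@blockSize < 1L) return("blockSize must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (!object@correction %in% c("bonferroni", "none"))
    return("correction must be 'bonferroni' or 'none'")
  if (object@density <= 0 || object@density > 1)
    return("density must be in (0, 1]")
  TRUE
})

#' @rdname EstimationParams-class
#' @param lagOrder,nSurrogates,blockSize,alpha,correction,density,seed see
#'   slot documentation.
#' @return An [EstimationParams-class] object.
#' @export
estimationParams <- function(lagOrder = 10L, nSurrogates = 100L,
                             blockSize = 10L, alpha = 0.05,
                             correction = c("bonferroni", "none"),
                             density = 1, seed = 1L) {
  new("EstimationParams",
      lagOrder = as.integer(lagOrder), nSurrogates = as.integer(nSurrogates),
      blockSize = as.integer(blockSize), alpha = alpha,
      correction = match.arg(correction), density = density,
      seed = as.integer(seed))
}

#' Fitted bivariate VAR model for one ordered node pair
#'
#' Ordinary-least-squares fit of a bivariate VAR(T) model pooled over trials.
#' Variable 1 is the source, variable 2 the target. The residual covariance
#' is the maximum-likelihood estimate (sum of squared residuals divided by
#' the number of pooled regression rows), so nested-model residual-variance
#' comparisons are monotone in sample.
#'
#' @slot coefficients list of T 2x2 matrices A_k mapping the pair at lag k to
#'   the present.
#' @slot residualCovariance 2x2 ML residual covariance.
#' @slot lagOrder integer model order T.
#' @slot nEffectiveObs pooled number of regression rows.
#' @export
setClass("BivariateVarModel",
  representation(
    coefficients = "list",
    residualCovariance = "matrix",
    lagOrder = "integer",
    nEffectiveObs = "integer"
  )
)

setValidity("BivariateVarModel", function(object) {
  if (length(object@coefficients) != object@lagOrder)
    return("coefficients must contain exactly lagOrder matrices")
  if (!all(vapply(object@coefficients,
                  function(a) is.matrix(a) && all(dim(a) == 2L), logical(1))))
    return("each coefficient matrix must be 2x2")
  S <- object@residualCovariance
  if (!all(dim(S) == 2L)) return("residualCovariance must be 2x2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    return("residualCovariance must be symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("residualCovariance must be positive semidefinite")
  TRUE
})

#' Directed-influence estimate for one ordered node pair
#'
#' Holds the Gaussian transfer entropy (nats), the normalization factor
#' (total mutual information between the target's next value and the joint
#' past, in nats) and their ratio, the normalized directed transfer entropy
#' (NDTE) in [0, 1]. The p-value slot is NA until a surrogate test is run.
#'
#' @slot source,target node labels (source drives target).
#' @slot te transfer entropy in nats, >= 0.
#' @slot normFactor normalization factor in nats, >= te.
#' @slot ndte te / normFactor, in [0, 1].
#' @slot pValue surrogate-test p-value in [0, 1], or NA.
#' @export
setClass("EdgeEstimate",
  representation(
    source = "character",
    target = "character",
    te = "numeric",
    normFactor = "numeric",
    ndte = "numeric",
    pValue = "numeric"
  )
)

setValidity("EdgeEstimate", function(object) {
  if (object@te < -1e-12) return("te must be nonnegative")
  if (object@ndte < -1e-9 || object@ndte > 1 + 1e-9)
    return("ndte must lie in [0, 1]")
  if (object@te > object@normFactor + 1e-9 * max(1, object@normFactor))
    return("te must not exceed normFactor")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  TRUE
})

#' Weighted directed network
#'
#' A weighted directed graph stored as a square nonnegative weight matrix
#' with zero diagonal; \code{weights[u, v]} is the weight of edge u -> v
#' (0 means no edge). Node order is fixed and serialized with the network so
#' that outputs are reproducible. An optional matrix of per-edge surrogate
#' p-values is carried along by [buildDirectedNetwork()].
#'
#' @slot nodes ordered character vector of node labels.
#' @slot weights numeric matrix, nonnegative, zero diagonal.
#' @slot pvalues numeric matrix of the same shape (NA where not computed).
#'
#' @seealso [directedNetwork()], [listComplexes()], [coreness()]
#' @export
setClass("DirectedNetwork",
  representation(
    nodes = "character",
    weights = "matrix",
    pvalues = "matrix"
  )
)

setValidity("DirectedNetwork", function(object) {
  W <- object@weights
  n <- length(object@nodes)
  if (!all(dim(W) == n)) return("weights must be n x n")
  if (anyDuplicated(object@nodes)) return("node labels must be unique")
  if (any(!is.finite(W))) return("weights must be finite")
  if (any(W < 0)) return("weights must be nonnegative")
  if (n > 0 && any(diag(W) != 0)) return("self-loops are not allowed")
  if (!all(dim(object@pvalues) == n))
    return("pvalues must be n x n")
  TRUE
})

#' Construct a DirectedNetwork
#'
#' @param weights square numeric matrix of nonnegative edge weights
#'   (\code{weights[u, v]} = weight of u -> v); the diagonal must be zero.
#' @param nodes node labels; defaults to the matrix dimnames or "N1"..
#' @param pvalues optional matrix of per-edge p-values.
#' @return A [DirectedNetwork-class] object.
#' @examples
#' W <- rbind(c(0, 2), c(5, 0))
#' net <- directedNetwork(W, nodes = c("a", "b"))
#' minCut(net)
#' @export
directedNetwork <- function(weights, nodes = NULL, pvalues = NULL) {
  weights <- as.matrix(weights)
  if (is.null(nodes)) {
    nodes <- rownames(weights)
    if (is.null(nodes)) nodes <- paste0("N", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(nodes, nodes)
  if (is.null(pvalues)) {
    pvalues <- matrix(NA_real_, nrow(weights), ncol(weights),
                      dimnames = dimnames(weights))
  } else {
    pvalues <- as.matrix(pvalues)
    dimnames(pvalues) <- dimnames(weights)
  }
  new("DirectedNetwork", nodes = nodes, weights = weights, pvalues = pvalues)
}

#' Result of evaluating one bipartition of a network
#'
#' For a bipartition (left, right) of a node set, \code{forwardWeight} and
#' \code{backwardWeight} are the summed weights of edges crossing
#' left -> right and right -> left, and \code{strength} is their minimum, the
#' strength of bidirectional connections across the cut. The minimum of
#' \code{strength} over all bipartitions is the min-cut weight; a single-node
#' (sub)graph has strength 0 by convention, marked by empty partitions.
#'
#' @slot left,right character node subsets.
#' @slot forwardWeight,backwardWeight,strength numeric cut weights.
#' @export
setClass("CutResult",
  representation(
    left = "character",
    right = "character",
    forwardWeight = "numeric",
    backwardWeight = "numeric",
    strength = "numeric"
  )
)

setValidity("CutResult", function(object) {
  if (length(intersect(object@left, object@right)) > 0)
    return("left and right must be disjoint")
  if (object@forwardWeight < 0 || object@backwardWeight < 0)
    return("cut weights must be nonnegative")
  if (abs(object@strength -
          min(object@forwardWeight, object@backwardWeight)) > 1e-9)
    return("strength must equal min(forwardWeight, backwardWeight)")
  TRUE
})

#' Hierarchical decomposition of a network into complexes
#'
#' A complex is an induced subgraph whose min-cut weight is positive and
#' strictly exceeds the min-cut weight of every induced supergraph. Complexes
#' are pairwise nested or disjoint, and nesting implies strictly decreasing
#' min-cut weight, so they form a hierarchy. Slot \code{parent} gives, for
#' each complex, the index of its smallest strict superset complex (NA for
#' the outermost ones). Complexes are sorted by descending min-cut weight.
#'
#' @slot nodes node labels of the decomposed network.
#' @slot members list of character vectors, one per complex.
#' @slot mcWeights numeric min-cut weight of each complex.
#' @slot parent integer index of the enclosing complex, or NA.
#'
#' @seealso [listComplexes()], [coreness()]
#' @export
setClass("ComplexDecomposition",
  representation(
    nodes = "character",
    members = "list",
    mcWeights = "numeric",
    parent = "integer"
  )
)

setValidity("ComplexDecomposition", function(object) {
  k <- length(object@members)
  if (length(object@mcWeights) != k || length(object@parent) != k)
    return("members, mcWeights and parent must have equal length")
  if (k > 0 && any(object@mcWeights <= 0))
    return("complexes must have positive min-cut weight")
  if (k > 0 && any(vapply(object@members, length, integer(1)) < 2L))
    return("complexes must have at least two members")
  if (k > 1 && any(diff(object@mcWeights) > 1e-9))
    return("complexes must be sorted by descending min-cut weight")
  for (i in seq_len(k)) {
    p <- object@parent[i]
    if (!is.na(p)) {
      if (p < 1 || p > k) return("parent index out of range")
      if (!all(object@members[[i]] %in% object@members[[p]]))
        return("parent must be a superset")
      if (object@mcWeights[p] >= object@mcWeights[i])
        return("nesting must strictly decrease min-cut weight")
    }
  }
  TRUE
})

#' Per-node coreness
#'
#' The coreness of a node is the largest min-cut weight among the complexes
#' containing it (equivalently, among all subnetworks containing it), and 0
#' for nodes contained in no complex. The \code{normalized} slot divides by
#' the maximum coreness over nodes, the convention used when averaging
#' across experimental conditions.
#'
#' @slot values named numeric, coreness per node.
#' @slot normalized named numeric, values / max(values) (all-zero maps stay
#'   zero), or empty if not computed.
#' @slot conditionLabel free-text label of the condition the map belongs to.
#' @export
setClass("CorenessMap",
  representation(
    values = "numeric",
    normalized = "numeric",
    conditionLabel = "character"
  )
)

setValidity("CorenessMap", function(object) {
  if (is.null(names(object@values))) return("values must be named by node")
  if (any(object@values < 0)) return("coreness must be nonnegative")
  if (length(object@normalized) > 0) {
    if (!identical(names(object@normalized), names(object@values)))
      return("normalized must be named like values")
    if (max(object@values) > 0 &&
        abs(max(object@normalized) - 1) > 1e-9)
      return("normalized maximum must be 1 when any coreness is positive")
  }
  TRUE
})

#' Generic per-node network metric
#'
#' Named nonnegative per-node values for one of the comparison metrics:
#' weighted degree, s-coreness, or coreness of the symmetrized
#' (bidirectionality-ignored) network.
#'
#' @slot values named numeric, one value per network node.
#' @slot metricKind one of "weighted_degree", "s_coreness",
#'   "coreness_undirected".
#' @export
setClass("NodeMetricMap",
  representation(values = "numeric", metricKind = "character")
)

setValidity("NodeMetricMap", function(object) {
  if (is.null(names(object@values))) return("values must be named by node")
  if (any(object@values < 0)) return("metric values must be nonnegative")
  if (!object@metricKind %in%
      c("weighted_degree", "s_coreness", "coreness_undirected"))
    return("unknown metricKind")
  TRUE
})

#' Pearson correlation with BCa bootstrap confidence interval
#'
#' @slot r sample Pearson correlation.
#' @slot ciLow,ciHigh bias-corrected and accelerated (BCa) bootstrap bounds.
#' @slot n sample size.
#' @slot nBoot number of bootstrap resamples.
#' @slot seed seed used for resampling.
#' @slot method "bca" or "percentile" (degenerate-case fallback).
#' @export
setClass("CorrelationResult",
  representation(
    r = "numeric", ciLow = "numeric", ciHigh = "numeric",
    n = "integer", nBoot = "integer", seed = "integer", method = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  if (object@r < -1 - 1e-9 || object@r > 1 + 1e-9)
    return("r must lie in [-1, 1]")
  if (object@ciLow > object@ciHigh + 1e-12)
    return("ciLow must not exceed ciHigh")
  TRUE
})
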