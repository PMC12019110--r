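#' Extract all complexes of a weighted directed network
#'
#' A complex is an induced subgraph G[S] whose min-cut weight w^mc (the
#' minimum over bipartitions of the strength of bidirectional connections,
#' see [minCut()]) is positive and strictly greater than the min-cut weight
#' of G[T] for every strict superset T. Complexes are the network's
#' bidirectionally inseparable cores and form a nested hierarchy: complexes
#' with stronger bidirectional connections are contained in weaker ones.
#'
#' The search is exact and uses hierarchical divide and conquer: the min-cut
#' of the whole node set is found, and because any subset straddling a
#' minimum cut has a min-cut weight no larger than the cut's strength (its
#' induced bipartition crosses fewer edges in both directions), every
#' complex other than the whole set lies entirely on one side; the search
#' recurses into both sides. A recursion-tree subset is a complex exactly
#' when its w^mc is positive and strictly exceeds the w^mc of all its
#' ancestors (equality within a relative tolerance of 1e-9 does not count
#' as exceeding). If the whole graph's w^mc is zero (e.g. disconnected or
#' partly unidirectional networks), the whole graph is not a complex and
#' extraction simply recurses into both sides of the zero cut.
#'
#' @param net a [DirectedNetwork-class].
#' @param bruteForceLimit passed to [minCut()].
#' @return A [ComplexDecomposition-class]; complexes sorted by descending
#'   min-cut weight, with parent links to the smallest enclosing complex.
#' @examples
#' net <- makeToyNetwork("fig1d_like")
#' listComplexes(net)
#' @export
setMethod("listComplexes", "DirectedNetwork",
          function(net, bruteForceLimit = 12L) {
  n <- length(net@nodes)
  if (n == 0L) stop("network is empty")
  W <- net@weights
  members <- list(); weights <- numeric(0); parentOf <- integer(0)

  rec <- function(idx, ancMax, ancComplexId) {
    if (length(idx) < 2L) return(invisible(NULL))
    cut <- .minCutIdx(W, idx, bruteForceLimit)
    val <- cut$value
    myId <- ancComplexId
    if (val > .MC_TOL && .strictlyGreater(val, ancMax)) {
      members[[length(members) + 1L]] <<- net@nodes[sort(idx)]
      weights[length(weights) + 1L] <<- val
      parentOf[length(parentOf) + 1L] <<- ancComplexId
      myId <- length(members)
    }
    newMax <- max(ancMax, val)
    rec(cut$left, newMax, myId)
    rec(cut$right, newMax, myId)
    invisible(NULL)
  }
  rec(seq_len(n), 0, NA_integer_)

  ord <- order(-weights, vapply(members, length, integer(1)))
  members <- members[ord]
  weights <- weights[ord]
  # remap parent ids through the sort
  old2new <- integer(length(ord)); old2new[ord] <- seq_along(ord)
  parentOf <- parentOf[ord]
  parentOf <- ifelse(is.na(parentOf), NA_integer_, old2new[parentOf])
  new("ComplexDecomposition", nodes = net@nodes, members = members,
      mcWeights = weights, parent = as.integer(parentOf))
})

#' Per-node coreness of a directed network
#'
#' The coreness k_v of node v is the largest min-cut weight among the
#' complexes containing v (equivalently, the largest w^mc over all
#' subnetworks containing v), and 0 for nodes contained in no complex.
#' Nodes deep inside strongly bidirectional cores get high coreness; nodes
#' attached only unidirectionally get 0.
#'
#' @param net a [DirectedNetwork-class].
#' @param bruteForceLimit passed to [minCut()].
#' @param conditionLabel label stored in the result (e.g. the brain state).
#' @return A [CorenessMap-class] with raw and max-normalized values.
#' @examples
#' coreness(makeToyNetwork("fig1d_like"))
#' @export
setMethod("coreness", "DirectedNetwork",
          function(net, bruteForceLimit = 12L, conditionLabel = "") {
  dec <- listComplexes(net, bruteForceLimit = bruteForceLimit)
  corenessFromComplexes(dec, conditionLabel = conditionLabel)
})

#' @rdname coreness
#' @param decomp a [ComplexDecomposition-class] (alternative entry point if
#'   the decomposition is already available).
#' @export
corenessFromComplexes <- function(decomp, conditionLabel = "") {
  stopifnot(is(decomp, "ComplexDecomposition"))
  k <- stats::setNames(numeric(length(decomp@nodes)), decomp@nodes)
  # complexes are sorted by descending weight: first hit is the maximum
  for (i in seq_along(decomp@members)) {
    mem <- decomp@members[[i]]
    unset <- mem[k[mem] == 0]
    k[unset] <- decomp@mcWeights[i]
  }
  norm <- if (max(k) > 0) k / max(k) else k
  new("CorenessMap", values = k, normalized = norm,
      conditionLabel = conditionLabel)
}

#' Normalize per-condition maps and average them
#'
#' Each map is divided by its own maximum (the per-condition normalization
#' used before comparing brain states; an all-zero map is left as zero with
#' a warning), then a (weighted) per-node mean is taken. Unequal weights
#' support conventions such as averaging two resting-state sessions into a
#' single condition before pooling with task conditions (give each rest
#' session weight 0.5).
#'
#' @param maps list of [CorenessMap-class], [NodeMetricMap-class], or named
#'   numeric vectors, all sharing one node set.
#' @param weights optional numeric vector, one per map; default equal.
#' @param conditionLabel label for the output map.
#' @return A [CorenessMap-class] holding the weighted mean of the
#'   normalized maps (its \code{values} are the averaged normalized values).
#' @examples
#' m1 <- c(a = 2, b = 0); m2 <- c(a = 0, b = 3)
#' metricValues(normalizeAverageCoreness(list(m1, m2)))  # 0.5, 0.5
#' @export
normalizeAverageCoreness <- function(maps, weights = NULL,
                                     conditionLabel = "average") {
  vals <- lapply(maps, function(m) {
    if (is(m, "CorenessMap") || is(m, "NodeMetricMap")) m@values
    else if (is.numeric(m) && !is.null(names(m))) m
    else stop("maps must be CorenessMap, NodeMetricMap or named numeric")
  })
  ref <- names(vals[[1L]])
  for (m in vals) {
    if (!setequal(names(m), ref))
      stop("all maps must share the same node set")
  }
  vals <- lapply(vals, function(m) m[ref])
  if (is.null(weights)) weights <- rep(1, length(vals))
  if (length(weights) != length(vals))
    stop("need one weight per map")
  normed <- lapply(seq_along(vals), function(i) {
    m <- vals[[i]]
    mx <- max(m)
    if (mx <= 0) {
      warning(sprintf("map %d is all zero; left unnormalized", i))
      m
    } else m / mx
  })
  acc <- Reduce(`+`, Map(function(m, w) m * w, normed, weights))
  avg <- acc / sum(weights)
  new("CorenessMap", values = avg,
      normalized = if (max(avg) > 0) avg / max(avg) else avg,
      conditionLabel = conditionLabel)
}
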