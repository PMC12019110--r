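# relative tolerance used for all min-cut weight comparisons
.MC_TOL <- 1e-9

.approxEqual <- function(a, b) {
  abs(a - b) <= .MC_TOL * max(1, abs(a), abs(b))
}

# strictly greater, treating values equal within tolerance as equal
.strictlyGreater <- function(a, b) {
  a > b && !.approxEqual(a, b)
}

#' Strength of bidirectional connections across a bipartition
#'
#' For a bipartition (left, right) of the network's nodes, sums the weights
#' of edges crossing left -> right and right -> left separately and returns
#' their minimum as the strength of bidirectional connections: it is zero
#' when the two sides are linked only unidirectionally, and large only when
#' both directions are strong.
#'
#' @param net a [DirectedNetwork-class].
#' @param left,right character vectors of node labels forming a bipartition
#'   of \code{nodes(net)} (both nonempty, disjoint, jointly exhaustive).
#' @return A [CutResult-class].
#' @examples
#' W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' W["a", "c"] <- 3; W["c", "a"] <- 1
#' net <- directedNetwork(W)
#' bidirectionalStrength(net, c("a", "b"), c("c", "d"))
#' @export
setMethod("bidirectionalStrength", "DirectedNetwork",
          function(net, left, right) {
  if (length(left) == 0 || length(right) == 0)
    stop("both sides of the bipartition must be nonempty")
  left <- as.character(left); right <- as.character(right)
  if (length(intersect(left, right)) > 0)
    stop("left and right must be disjoint")
  if (!setequal(union(left, right), net@nodes))
    stop("the bipartition must cover exactly the network's nodes")
  W <- net@weights
  fwd <- sum(W[left, right, drop = FALSE])
  bwd <- sum(W[right, left, drop = FALSE])
  new("CutResult", left = left, right = right,
      forwardWeight = fwd, backwardWeight = bwd,
      strength = min(fwd, bwd))
})

# exhaustive enumeration of all bipartitions of idx (node indices into W);
# returns list(left, right (indices), value). Deterministic: the first
# minimum in mask order wins.
.minCutBrute <- function(W, idx) {
  k <- length(idx)
  bits <- 2^(0:(k - 2L))
  best <- Inf; bestMask <- NULL
  for (m in seq_len(2^(k - 1L) - 1L)) {
    sel <- bitwAnd(m, bits) > 0
    L <- idx[c(sel, FALSE)]
    R <- setdiff(idx, L)
    s <- min(sum(W[L, R, drop = FALSE]), sum(W[R, L, drop = FALSE]))
    if (s < best) {
      best <- s
      bestMask <- L
      if (best == 0) break
    }
  }
  list(left = bestMask, right = setdiff(idx, bestMask), value = best)
}

# exact global minimum via max-flow: the objective min(w(L->R), w(R->L)) is
# invariant under swapping the sides, and swapping exchanges the two
# directed sums, so its global minimum over bipartitions equals the global
# minimum *directed* cut of the digraph, which igraph computes exactly.
.minCutFlow <- function(W, idx) {
  Wi <- W[idx, idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(Wi, mode = "directed",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0) {
    return(list(left = idx[1L], right = idx[-1L], value = 0))
  }
  mc <- igraph::min_cut(g, capacity = igraph::E(g)$weight,
                        value.only = FALSE)
  L <- idx[as.integer(mc$partition1)]
  R <- idx[as.integer(mc$partition2)]
  list(left = L, right = R, value = mc$value)
}

.minCutIdx <- function(W, idx, bruteForceLimit) {
  if (length(idx) <= bruteForceLimit) .minCutBrute(W, idx)
  else .minCutFlow(W, idx)
}

#' Minimum bidirectional cut of a network or subnetwork
#'
#' Finds a bipartition of the (induced sub)network minimizing the strength
#' of bidirectional connections, and the corresponding min-cut weight w^mc:
#' the subnetwork's inseparability score. The search is exact at all sizes:
#' exhaustive enumeration of all 2^(n-1) - 1 bipartitions up to
#' \code{bruteForceLimit} nodes, and a max-flow global minimum directed cut
#' above it (the bidirectional objective is symmetric under swapping the
#' sides, which exchanges the two directed sums, so its global minimum
#' equals the global minimum directed cut). A single-node subgraph has
#' w^mc = 0 by convention, returned with empty partition sides.
#'
#' @param net a [DirectedNetwork-class].
#' @param subset optional character vector of node labels; default all
#'   nodes.
#' @param bruteForceLimit switch point between enumeration and max-flow.
#' @return A [CutResult-class]; \code{strength} is w^mc.
#' @examples
#' net <- makeToyNetwork("reciprocal_pair", wBidirectional = 2, wAttach = 5)
#' minCut(net)@strength  # 2
#' @export
setMethod("minCut", "DirectedNetwork",
          function(net, subset = NULL, bruteForceLimit = 12L) {
  W <- net@weights
  if (is.null(subset)) {
    idx <- seq_along(net@nodes)
  } else {
    idx <- match(as.character(subset), net@nodes)
    if (anyNA(idx)) stop("subset contains unknown node labels")
    if (length(idx) == 0) stop("subset must be nonempty")
  }
  if (length(idx) == 1L) {
    return(new("CutResult", left = character(0), right = character(0),
               forwardWeight = 0, backwardWeight = 0, strength = 0))
  }
  res <- .minCutIdx(W, idx, bruteForceLimit)
  L <- net@nodes[res$left]; R <- net@nodes[res$right]
  fwd <- sum(W[res$left, res$right, drop = FALSE])
  bwd <- sum(W[res$right, res$left, drop = FALSE])
  new("CutResult", left = L, right = R, forwardWeight = fwd,
      backwardWeight = bwd, strength = min(fwd, bwd))
})
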