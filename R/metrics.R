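#' Symmetrize a directed network (ignore bidirectionality)
#'
#' Returns the network with connection matrix W' = (W + W^T) / 2. Summing
#' the weights of all edges crossing a bipartition regardless of direction
#' (with a factor 1/2 for consistency with the bidirectional measure) is
#' equivalent to applying the bidirectional connection strength to this
#' symmetrized network, so running [listComplexes()] on the output extracts
#' cores regardless of bidirectionality.
#'
#' @param net a [DirectedNetwork-class].
#' @return A [DirectedNetwork-class] with symmetric weights (p-values are
#'   dropped).
#' @examples
#' W <- rbind(c(0, 4), c(0, 0))
#' weightMatrix(symmetrize(directedNetwork(W)))  # 2 each way
#' @export
setMethod("symmetrize", "DirectedNetwork", function(net) {
  W <- (net@weights + t(net@weights)) / 2
  directedNetwork(W, nodes = net@nodes)
})

#' Weighted degree of every node
#'
#' deg(v) is the sum of the weights of all edges attached to v, regardless
#' of direction (in-strength plus out-strength). Summed over the graph this
#' equals twice the total edge weight.
#'
#' @param net a [DirectedNetwork-class].
#' @return A [NodeMetricMap-class] with \code{metricKind = "weighted_degree"}.
#' @examples
#' weightedDegree(makeToyNetwork("fig1d_like"))
#' @export
setMethod("weightedDegree", "DirectedNetwork", function(net) {
  W <- net@weights
  v <- rowSums(W) + colSums(W)
  new("NodeMetricMap", values = stats::setNames(v, net@nodes),
      metricKind = "weighted_degree")
})

#' s-core decomposition of a symmetric network
#'
#' Weighted generalization of k-core decomposition: for increasing strength
#' level s, nodes whose strength (weighted degree within the remaining
#' subgraph) falls below s are deleted iteratively; a node's s-coreness is
#' the largest level at which it survives. Levels are taken at the distinct
#' node-strength values encountered during peeling (one node with minimum
#' strength is removed at a time and all strengths recomputed), so the
#' decomposition is parameter-free and exact for continuous weights.
#'
#' @param net a [DirectedNetwork-class] with symmetric weights (apply
#'   [symmetrize()] first for a directed network).
#' @return A [NodeMetricMap-class] with \code{metricKind = "s_coreness"}.
#' @examples
#' sCore(symmetrize(makeToyNetwork("fig1d_like")))
#' @export
setMethod("sCore", "DirectedNetwork", function(net) {
  W <- net@weights
  if (max(abs(W - t(W))) > 1e-9 * max(1, max(W)))
    stop("sCore requires symmetric weights; apply symmetrize() first")
  n <- length(net@nodes)
  score <- stats::setNames(numeric(n), net@nodes)
  alive <- seq_len(n)
  level <- 0
  while (length(alive) > 0) {
    s <- rowSums(W[alive, alive, drop = FALSE]) +
      colSums(W[alive, alive, drop = FALSE])
    i <- which.min(s)  # first index among ties: deterministic
    level <- max(level, s[i])
    score[net@nodes[alive[i]]] <- level
    alive <- alive[-i]
  }
  new("NodeMetricMap", values = score, metricKind = "s_coreness")
})

#' Functional rich-club score of a node subset
#'
#' Evaluates G_FRIC(k) = sum_{i in k} sum_{j in k} W_ij +
#' sum_{i in k} sum_j W_ij - sum_i sum_{j in k} W_ij for a subset k: the
#' within-subset weight plus the subset's total out-strength minus its total
#' in-strength. On a symmetric network the last two terms cancel and the
#' score reduces to the within-subset weight sum.
#'
#' @param net a [DirectedNetwork-class].
#' @param subset nonempty character vector of node labels.
#' @return numeric scalar.
#' @examples
#' net <- makeToyNetwork("fig1d_like")
#' fricScore(net, c("E", "F", "I", "J"))
#' @export
setMethod("fricScore", "DirectedNetwork", function(net, subset) {
  subset <- as.character(subset)
  if (length(subset) == 0) stop("subset must be nonempty")
  idx <- match(subset, net@nodes)
  if (anyNA(idx)) stop("subset contains unknown node labels")
  W <- net@weights
  sum(W[idx, idx]) + sum(W[idx, ]) - sum(W[, idx])
})

#' Identify a functional rich club by exhaustive enumeration
#'
#' Demonstration routine for small graphs: for every subset size with at
#' least \code{minCount} same-size subsets (so that a 95th-percentile cutoff
#' is proper), all subsets are scored with [fricScore()] and those at or
#' above the 95th percentile of their size class qualify ("top 5 percent of
#' subnetworks of the same size"). The largest qualifying subnetwork is
#' returned; ties at the largest size are broken by score, then
#' lexicographically. Complexity is exponential in the node count; intended
#' for toy graphs of about a dozen nodes.
#'
#' @param net a [DirectedNetwork-class] (small).
#' @param minCount minimum number of same-size subsets for a size class to
#'   enter the search (default 20).
#' @return list with elements \code{members} (character), \code{score},
#'   \code{size}.
#' @examples
#' fricRichClub(makeToyNetwork("fig1d_like"))
#' @export
fricRichClub <- function(net, minCount = 20L) {
  stopifnot(is(net, "DirectedNetwork"))
  n <- length(net@nodes)
  if (n > 16L) stop("exhaustive rich-club search is limited to 16 nodes")
  best <- NULL
  for (size in seq.int(2L, n)) {
    if (choose(n, size) < minCount) next
    sets <- utils::combn(n, size)
    scores <- apply(sets, 2L, function(ix) {
      W <- net@weights
      sum(W[ix, ix]) + sum(W[ix, ]) - sum(W[, ix])
    })
    thr <- stats::quantile(scores, 0.95, names = FALSE)
    qual <- which(scores >= thr)
    topIx <- qual[which.max(scores[qual])]
    cand <- list(members = net@nodes[sets[, topIx]],
                 score = scores[topIx], size = size)
    if (is.null(best) || cand$size > best$size ||
        (cand$size == best$size && cand$score > best$score))
      best <- cand
  }
  if (is.null(best))
    stop("no size class has enough subsets; decrease minCount")
  best
}
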