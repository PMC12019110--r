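#' Toy directed networks with known core structure
#'
#' Deterministic generators for the worked-example graphs used throughout
#' the package:
#' \describe{
#'   \item{fig1d_like}{10 nodes A..J. The quartet \{E, F, I, J\} is a
#'     complete reciprocal clique at \code{wBidirectional}; node B is
#'     reciprocally attached to E and J at the weaker \code{wAttach};
#'     \{A, C, D, G, H\} are connected in a feedforward-only manner at
#'     \code{wFeedforward} (A feeds C and D, C and D feed every core node,
#'     every core node feeds G and H). The bidirectional complexes are
#'     \{E,F,I,J\} and \{B,E,F,I,J\} and never contain feedforward-only
#'     nodes, while on the symmetrized graph the strongest complex admits
#'     them (with the default weights).}
#'   \item{two_modules}{Two reciprocal triangles \{A,B,C\} and \{D,E,F\}
#'     (all weights \code{wBidirectional}) joined by a single reciprocal
#'     bridge C--D of the same weight: the two modules are the two
#'     maximal-strength complexes.}
#'   \item{reciprocal_pair}{Two nodes with edges a -> b at
#'     \code{wBidirectional} and b -> a at \code{wAttach}; its min-cut
#'     weight is the minimum of the two.}
#'   \item{random_digraph}{\code{nNodes} nodes; every ordered pair
#'     receives an independent weight drawn uniformly from
#'     \{0, 0.1, ..., 1\} (seeded, reproducible).}
#' }
#'
#' @param pattern one of "fig1d_like", "two_modules", "reciprocal_pair",
#'   "random_digraph".
#' @param nNodes node count, used by random_digraph only.
#' @param wBidirectional weight of reciprocal core edges (default 3).
#' @param wAttach weight of the weak reciprocal attachment (default 2).
#' @param wFeedforward weight of feedforward-only edges (default 5).
#' @param seed integer seed, used by random_digraph only.
#' @return A [DirectedNetwork-class].
#' @examples
#' net <- makeToyNetwork("fig1d_like")
#' complexMembers(listComplexes(net), 1)  # E F I J
#' @export
makeToyNetwork <- function(pattern = c("fig1d_like", "two_modules",
                                       "reciprocal_pair", "random_digraph"),
                           nNodes = NULL, wBidirectional = 3, wAttach = 2,
                           wFeedforward = 5, seed = 1L) {
  pattern <- match.arg(pattern)
  if (min(wBidirectional, wAttach, wFeedforward) < 0)
    stop("weights must be nonnegative")
  if (pattern == "fig1d_like") {
    lab <- LETTERS[1:10]
    W <- matrix(0, 10, 10, dimnames = list(lab, lab))
    core <- c("E", "F", "I", "J")
    for (u in core) for (v in core) if (u != v) W[u, v] <- wBidirectional
    for (v in c("E", "J")) { W["B", v] <- wAttach; W[v, "B"] <- wAttach }
    ff <- wFeedforward
    W["A", "C"] <- ff; W["A", "D"] <- ff
    for (v in core) { W["C", v] <- ff; W["D", v] <- ff }
    for (u in core) { W[u, "G"] <- ff; W[u, "H"] <- ff }
    return(directedNetwork(W))
  }
  if (pattern == "two_modules") {
    lab <- LETTERS[1:6]
    W <- matrix(0, 6, 6, dimnames = list(lab, lab))
    for (m in list(c("A", "B", "C"), c("D", "E", "F")))
      for (u in m) for (v in m) if (u != v) W[u, v] <- wBidirectional
    W["C", "D"] <- wBidirectional; W["D", "C"] <- wBidirectional
    return(directedNetwork(W))
  }
  if (pattern == "reciprocal_pair") {
    W <- matrix(c(0, wAttach, wBidirectional, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    return(directedNetwork(W))
  }
  # random_digraph
  if (is.null(nNodes) || nNodes < 2)
    stop("random_digraph requires nNodes >= 2")
  set.seed(as.integer(seed))
  n <- as.integer(nNodes)
  W <- matrix(sample(seq(0, 1, by = 0.1), n * n, replace = TRUE), n, n)
  diag(W) <- 0
  directedNetwork(W, nodes = paste0("N", seq_len(n)))
}

#' Simulate multi-trial VAR(1) time series with planted coupling
#'
#' Generates Z_t = A Z_{t-1} + e_t per trial, with e_t drawn from
#' N(0, noiseCov), after a discarded burn-in (default 100 frames, far beyond
#' ten times the lag span) so the retained segment is approximately
#' stationary. The coupling matrix A is the ground truth against which
#' estimated directed networks can be checked; a reciprocal block in A
#' plants a bidirectional core.
#'
#' @param coupling n x n matrix of lag-1 coefficients (A[i, j] is the
#'   influence of node j's past on node i -- rows receive, columns send).
#' @param noiseCov innovation covariance (default identity), symmetric
#'   positive definite.
#' @param nTrials,nTime number of trials and retained frames per trial.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param burnIn discarded initial frames per trial.
#' @param samplingInterval seconds per frame for the returned container.
#' @param nodeLabels optional node names.
#' @return A [RoiTimeSeriesSet-class] (not flagged preprocessed).
#' @examples
#' A <- rbind(c(0.2, 0.4), c(0.4, 0.2))
#' ts <- simulateVarTimeSeries(A, nTrials = 3, nTime = 100, seed = 1)
#' @export
simulateVarTimeSeries <- function(coupling, noiseCov = NULL, nTrials = 20L,
                                  nTime = 500L, seed = 1L, burnIn = 100L,
                                  samplingInterval = 0.72,
                                  nodeLabels = NULL) {
  A <- as.matrix(coupling)
  n <- nrow(A)
  stopifnot(ncol(A) == n)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable coupling: spectral radius %.4f >= 1", rho))
  if (is.null(noiseCov)) noiseCov <- diag(n)
  noiseCov <- as.matrix(noiseCov)
  if (max(abs(noiseCov - t(noiseCov))) > 1e-10)
    stop("noiseCov must be symmetric")
  ch <- tryCatch(chol(noiseCov),
                 error = function(e) stop("noiseCov must be positive definite"))
  if (is.null(nodeLabels)) nodeLabels <- paste0("N", seq_len(n))
  set.seed(as.integer(seed))
  total <- burnIn + nTime
  out <- array(0, c(nTime, n, nTrials))
  for (tr in seq_len(nTrials)) {
    eps <- matrix(stats::rnorm(total * n), total, n) %*% ch
    z <- matrix(0, total, n)
    z[1L, ] <- eps[1L, ]
    for (t in 2:total) z[t, ] <- as.vector(A %*% z[t - 1L, ]) + eps[t, ]
    out[, , tr] <- z[(burnIn + 1L):total, , drop = FALSE]
  }
  RoiTimeSeriesSet(out, nodeLabels = nodeLabels,
                   samplingInterval = samplingInterval,
                   preprocessed = FALSE)
}
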