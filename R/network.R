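#' Estimate a significance-filtered weighted directed network
#'
#' For every ordered node pair (X, Y) the NDTE F_XY is computed from the
#' pooled-trial bivariate VAR fit, and tested against \code{nSurrogates}
#' block-permutation surrogates of the source series (each trial permuted
#' independently; the target and hence its reduced model are untouched).
#' Upper-tail p-values come from a Gaussian KDE of the surrogate NDTE
#' distribution. An edge with weight F_XY is retained iff
#' p < alpha / m with m = n(n-1) ordered pairs under Bonferroni correction
#' (or p < alpha with \code{correction = "none"}). Self-loops are never
#' created. The per-pair surrogate streams are seeded deterministically from
#' \code{params@seed} and the pair identity, so results do not depend on
#' iteration order and identical inputs with an identical seed give
#' bit-identical networks.
#'
#' Density thresholding is a separate step; see [thresholdToDensity()].
#'
#' @param ts a preprocessed [RoiTimeSeriesSet-class] with >= 2 nodes.
#' @param params an [EstimationParams-class].
#' @return A [DirectedNetwork-class]; the \code{pvalues} slot holds the
#'   p-value of every ordered pair (also non-significant ones).
#' @examples
#' A <- rbind(c(0.2, 0.4, 0), c(0.4, 0.2, 0), c(0, 0, 0.2))
#' ts <- simulateVarTimeSeries(A, nTrials = 5, nTime = 200, seed = 1)
#' p <- estimationParams(lagOrder = 3, nSurrogates = 20, blockSize = 5,
#'                       seed = 1)
#' net <- buildDirectedNetwork(ts, p)
#' @export
buildDirectedNetwork <- function(ts, params = estimationParams()) {
  stopifnot(is(ts, "RoiTimeSeriesSet"), is(params, "EstimationParams"))
  n <- nNodes(ts)
  if (n < 2L) stop("need at least 2 nodes")
  nT <- nFrames(ts)
  if (params@lagOrder >= nT) stop("lagOrder must be smaller than trial length")
  if (params@blockSize > nT) stop("blockSize must not exceed trial length")
  labels <- ts@nodeLabels
  p <- params@lagOrder
  nTr <- nTrials(ts)

  # per-node pooled lag blocks and reduced-model quantities, cached
  blocks <- vector("list", n)
  for (v in seq_len(n)) {
    b <- .lagBlock(ts@values[, v, , drop = TRUE], p)
    b$reducedVar <- .residVarLS(b$lags, b$resp)
    b$varY <- mean((b$resp - mean(b$resp))^2)
    blocks[[v]] <- b
  }

  m <- n * (n - 1L)
  alphaAdj <- if (params@correction == "bonferroni")
    params@alpha / m else params@alpha
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  P <- matrix(NA_real_, n, n, dimnames = list(labels, labels))

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      by <- blocks[[j]]
      obs <- tryCatch(
        .ndteFromBlocks(by$lags, blocks[[i]]$lags, by$resp,
                        reducedVar = by$reducedVar, varY = by$varY),
        error = function(e) stop(sprintf(
          "NDTE failed for pair (%s -> %s): %s",
          labels[i], labels[j], conditionMessage(e))))
      set.seed(.pairSeed(params@seed, i, j))
      surr <- numeric(params@nSurrogates)
      xmat <- .asTrialMatrix(ts@values[, i, , drop = TRUE])
      for (s in seq_len(params@nSurrogates)) {
        xs <- xmat
        for (tr in seq_len(nTr))
          xs[, tr] <- blockPermutation(xmat[, tr], params@blockSize)
        bxs <- .lagBlock(xs, p)
        st <- .ndteFromBlocks(by$lags, bxs$lags, by$resp,
                              reducedVar = by$reducedVar, varY = by$varY)
        surr[s] <- st$ndte
      }
      pij <- edgePValue(obs$ndte, surr)
      P[i, j] <- pij
      if (pij < alphaAdj) W[i, j] <- obs$ndte
    }
  }
  directedNetwork(W, nodes = labels, pvalues = P)
}

#' Threshold a network to a fixed edge density
#'
#' Keeps the \code{floor(density * n * (n - 1))} largest-weight directed
#' edges (reference densities in functional connectomics are typically 5, 10
#' or 20 percent, matching the sparsity of anatomical connections). Ties at
#' the cutoff weight are broken by lexicographic (source, target) node order
#' for reproducibility. If fewer edges exist than the quota, all are kept
#' and a message reports the shortfall.
#'
#' @param net a [DirectedNetwork-class].
#' @param density fraction in (0, 1].
#' @return A [DirectedNetwork-class] with at most the quota of edges.
#' @examples
#' net <- makeToyNetwork("random_digraph", nNodes = 10, seed = 1)
#' thresholdToDensity(net, 0.10)
#' @export
thresholdToDensity <- function(net, density) {
  stopifnot(is(net, "DirectedNetwork"))
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  n <- nNodes(net)
  quota <- floor(density * n * (n - 1L))
  W <- net@weights
  idx <- which(W > 0, arr.ind = TRUE)
  if (nrow(idx) <= quota) {
    if (nrow(idx) < quota && density < 1)
      message(sprintf("only %d significant edges for a quota of %d; keeping all",
                      nrow(idx), quota))
    return(net)
  }
  # sort by weight desc, then (source, target) lexicographic by node order
  ord <- order(-W[idx], idx[, 1L], idx[, 2L])
  keep <- idx[ord[seq_len(quota)], , drop = FALSE]
  W2 <- matrix(0, n, n, dimnames = dimnames(W))
  W2[keep] <- W[keep]
  directedNetwork(W2, nodes = net@nodes, pvalues = net@pvalues)
}
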