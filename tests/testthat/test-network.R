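smallParams <- function(seed = 1, ...) {
  estimationParams(lagOrder = 3, nSurrogates = 40, blockSize = 5,
                   alpha = 0.05, seed = seed, ...)
}

test_that("independent nodes yield (almost) no Bonferroni-corrected edges", {
  ts <- simulateVarTimeSeries(diag(0.2, 5), nTrials = 4, nTime = 150,
                              seed = 21)
  net <- buildDirectedNetwork(ts, smallParams(seed = 21))
  # expected false positives ~ alpha = 0.05 over all 20 ordered pairs
  expect_lte(nrow(edgeList(net)), 1)
  expect_true(all(diag(weightMatrix(net)) == 0))
  expect_identical(dim(net@pvalues), c(5L, 5L))
  expect_true(all(!is.na(net@pvalues[row(net@pvalues) != col(net@pvalues)])))
})

test_that("a planted reciprocal pair is retained among independent nodes", {
  A <- diag(0.2, 4)
  A[1, 2] <- 0.4; A[2, 1] <- 0.4
  for (s in 1:3) {
    ts <- simulateVarTimeSeries(A, nTrials = 8, nTime = 250, seed = s)
    net <- buildDirectedNetwork(ts, smallParams(seed = s))
    W <- weightMatrix(net)
    expect_gt(W["N1", "N2"], 0)
    expect_gt(W["N2", "N1"], 0)
  }
})

test_that("network estimation is bit-identical under identical seeds", {
  ts <- simulateVarTimeSeries(diag(0.3, 3), nTrials = 3, nTime = 120,
                              seed = 8)
  p <- estimationParams(lagOrder = 3, nSurrogates = 20, blockSize = 5,
                        seed = 77)
  n1 <- buildDirectedNetwork(ts, p)
  n2 <- buildDirectedNetwork(ts, p)
  expect_identical(n1@weights, n2@weights)
  expect_identical(n1@pvalues, n2@pvalues)
})

test_that("estimation rejects invalid sizes", {
  ts <- simulateVarTimeSeries(diag(0.2, 2), nTrials = 2, nTime = 50, seed = 1)
  expect_error(buildDirectedNetwork(
    ts, estimationParams(lagOrder = 60)), "lagOrder")
  expect_error(buildDirectedNetwork(
    ts, estimationParams(blockSize = 60)), "blockSize")
})

test_that("density thresholding keeps the exact quota of strongest edges", {
  net <- makeToyNetwork("random_digraph", nNodes = 10, seed = 3)
  W <- weightMatrix(net)
  W[W == 0 & row(W) != col(W)] <- 0.05  # complete digraph, 90 edges
  full <- directedNetwork(W)
  thr <- thresholdToDensity(full, 0.10)
  kept <- edgeList(thr)
  expect_identical(nrow(kept), 9L)
  dropped <- weightMatrix(full)[weightMatrix(thr) == 0 &
                                  row(W) != col(W)]
  expect_gte(min(kept$weight), max(dropped))
  # identity at density 1
  expect_identical(weightMatrix(thresholdToDensity(full, 1)),
                   weightMatrix(full))
  # reference densities are accepted configuration values
  for (d in c(0.05, 0.10, 0.20))
    expect_s4_class(thresholdToDensity(full, d), "DirectedNetwork")
  expect_error(thresholdToDensity(full, 0), "density")
  expect_message(thresholdToDensity(makeToyNetwork("reciprocal_pair"), 1),
                 NA)  # quota met: no shortfall message
})

test_that("density ties break lexicographically by (source, target)", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 1; W["a", "c"] <- 1; W["b", "a"] <- 1; W["c", "a"] <- 0.5
  net <- directedNetwork(W)
  thr <- thresholdToDensity(net, 2 / 6)  # quota 2 of the three weight-1 ties
  el <- edgeList(thr)
  expect_identical(paste(el$source, el$target),
                   c("a b", "a c"))
})
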