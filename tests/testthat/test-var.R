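# analytic covariance of a stationary bivariate VAR(1): vec(G) solves
# (I - A (x) A) vec(G) = vec(Sigma); used as the population oracle for TE
popTeVar1 <- function(A, Sigma = diag(2)) {
  G <- matrix(solve(diag(4) - kronecker(A, A), as.vector(Sigma)), 2, 2)
  g1yy <- (A %*% G)[2, 2]
  redPop <- G[2, 2] - g1yy^2 / G[2, 2]
  0.5 * log(redPop / Sigma[2, 2])
}

test_that("white noise yields coefficients within 3 standard errors of 0", {
  set.seed(10)
  x <- matrix(rnorm(500 * 100), 500, 100)
  y <- matrix(rnorm(500 * 100), 500, 100)
  m <- fitBivariateVar(x, y, lagOrder = 1)
  se <- 1 / sqrt(m@nEffectiveObs)
  expect_true(all(abs(m@coefficients[[1]]) < 3 * se))
})

test_that("simulate-then-refit recovers coefficients and noise covariance", {
  A1 <- rbind(c(0.5, 0.2), c(0.0, 0.4))
  ts <- simulateVarTimeSeries(A1, nTrials = 50, nTime = 1000, seed = 42)
  m <- fitBivariateVar(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 1)
  expect_lt(max(abs(m@coefficients[[1]] - A1)), 0.05)
  expect_lt(max(abs(m@residualCovariance - diag(2))), 0.05)
  expect_length(m@coefficients, 1L)
})

test_that("duplicated series trigger the rank-deficiency fallback", {
  set.seed(3)
  x <- matrix(rnorm(200 * 2), 200, 2)
  expect_warning(fitBivariateVar(x, x, lagOrder = 2), "rank-deficient")
})

test_that("transfer entropy matches the analytic population value", {
  A <- rbind(c(0.3, 0.0), c(0.4, 0.3))  # x drives y, not vice versa
  ts <- simulateVarTimeSeries(A, nTrials = 50, nTime = 1000, seed = 7)
  m <- fitBivariateVar(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 1)
  red <- fitReducedAr(ts@values[, 2, ], 1)
  expect_lt(abs(transferEntropy(m, red) - popTeVar1(A)), 0.01)
})

test_that("transfer entropy degenerate and error cases behave", {
  A <- rbind(c(0.3, 0.0), c(0.4, 0.3))
  ts <- simulateVarTimeSeries(A, nTrials = 5, nTime = 200, seed = 1)
  m <- fitBivariateVar(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 1)
  # reduced variance equal to the full model's target residual variance
  expect_identical(transferEntropy(m, m@residualCovariance[2, 2]), 0)
  expect_error(transferEntropy(m, -1), "positive")
  # independent pair at large sample: te below 2 / n_eff
  tsI <- simulateVarTimeSeries(diag(0.0, 2), nTrials = 20, nTime = 500,
                               seed = 2)
  mI <- fitBivariateVar(tsI@values[, 1, ], tsI@values[, 2, ], lagOrder = 1)
  redI <- fitReducedAr(tsI@values[, 2, ], 1)
  expect_lt(transferEntropy(mI, redI), 2 / mI@nEffectiveObs)
})

test_that("NDTE is bounded, small under independence, and normalized", {
  tsI <- simulateVarTimeSeries(diag(0.2, 2), nTrials = 10, nTime = 400,
                               seed = 5)
  e <- ndteEdge(tsI@values[, 1, ], tsI@values[, 2, ], lagOrder = 5)
  expect_lt(e@ndte, 0.05)
  # bounds on assorted random inputs, te <= normFactor
  for (s in 1:10) {
    A <- matrix(runif(4, -0.4, 0.4), 2, 2)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 0.95) next
    ts <- simulateVarTimeSeries(A, nTrials = 3, nTime = 150, seed = s)
    e <- ndteEdge(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 3)
    expect_gte(e@ndte, 0)
    expect_lte(e@ndte, 1)
    expect_lte(e@te, e@normFactor + 1e-9 * max(1, e@normFactor))
  }
})

test_that("unidirectional coupling gives asymmetric NDTE almost always", {
  A <- rbind(c(0.3, 0.0), c(0.4, 0.3))  # x -> y only
  wins <- 0L
  for (s in 1:100) {
    ts <- simulateVarTimeSeries(A, nTrials = 5, nTime = 300, seed = s)
    fxy <- ndteEdge(ts@values[, 1, ], ts@values[, 2, ], 5)@ndte
    fyx <- ndteEdge(ts@values[, 2, ], ts@values[, 1, ], 5)@ndte
    wins <- wins + (fxy > fyx)
  }
  expect_gte(wins, 95)
})
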