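# compare a ComplexDecomposition with the exhaustive-definition oracle
expectMatchesOracle <- function(net, bruteForceLimit) {
  W <- weightMatrix(net)
  dec <- listComplexes(net, bruteForceLimit = bruteForceLimit)
  ora <- oracleComplexes(W)
  got <- canonComplexes(lapply(dec@members, function(m) match(m, nodes(net))),
                        dec@mcWeights)
  want <- canonComplexes(ora$members, ora$weights)
  expect_identical(got$sets, want$sets)
  expect_equal(got$weights, want$weights, tolerance = 1e-9)
  # coreness via complexes must equal the all-subsets maximum
  k <- metricValues(coreness(net, bruteForceLimit = bruteForceLimit))
  expect_equal(unname(k), oracleCorenessAllSubsets(W), tolerance = 1e-9)
  dec
}

test_that("an edgeless graph has no complexes and zero coreness", {
  net <- directedNetwork(matrix(0, 4, 4), nodes = letters[1:4])
  dec <- listComplexes(net)
  expect_length(dec@members, 0L)
  expect_true(all(metricValues(coreness(net)) == 0))
})

test_that("fig1d-like toy: quartet strongest, B-augmented second, no
           feedforward nodes in any complex", {
  net <- makeToyNetwork("fig1d_like")
  dec <- listComplexes(net)
  expect_identical(complexMembers(dec, 1), c("E", "F", "I", "J"))
  expect_identical(complexMembers(dec, 2), c("B", "E", "F", "I", "J"))
  inAny <- unique(unlist(dec@members))
  expect_true(all(!c("A", "C", "D", "G", "H") %in% inAny))
  k <- metricValues(coreness(net))
  expect_gt(k[["E"]], k[["B"]])
  expect_gt(k[["B"]], max(k[c("A", "C", "D", "G", "H")]))
  # matches the exhaustive definition
  expectMatchesOracle(net, bruteForceLimit = 1L)
})

test_that("two bridged modules are the two maximal-strength complexes", {
  net <- makeToyNetwork("two_modules")
  dec <- expectMatchesOracle(net, bruteForceLimit = 1L)
  top <- dec@mcWeights == max(dec@mcWeights)
  expect_identical(sum(top), 2L)
  expect_setequal(lapply(dec@members[top], sort),
                  list(c("A", "B", "C"), c("D", "E", "F")))
  expect_true(all(vapply(dec@members[top], length, integer(1)) == 3L))
})

test_that("fast path equals the exhaustive definition on random digraphs", {
  for (s in 1:30) {
    n <- 4 + (s %% 4)  # 4..7
    net <- makeToyNetwork("random_digraph", nNodes = n, seed = 300 + s)
    expectMatchesOracle(net, bruteForceLimit = 1L)   # max-flow path
    expectMatchesOracle(net, bruteForceLimit = 12L)  # enumeration path
  }
})

test_that("complexes are nested or disjoint with strictly decreasing
           min-cut weight", {
  for (s in 1:20) {
    net <- makeToyNetwork("random_digraph", nNodes = 7, seed = 400 + s)
    dec <- listComplexes(net)
    k <- length(dec@members)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      a <- dec@members[[i]]; b <- dec@members[[j]]
      inter <- length(intersect(a, b))
      expect_true(inter == 0 || inter == length(a) || inter == length(b))
      if (inter == length(a) && length(a) < length(b))
        expect_gt(dec@mcWeights[i], dec@mcWeights[j])
    }
  }
})

test_that("scaling all weights scales weights and coreness, not membership", {
  net <- makeToyNetwork("random_digraph", nNodes = 6, seed = 17)
  dec1 <- listComplexes(net)
  net3 <- directedNetwork(weightMatrix(net) * 3, nodes = nodes(net))
  dec3 <- listComplexes(net3)
  expect_identical(dec1@members, dec3@members)
  expect_equal(dec3@mcWeights, 3 * dec1@mcWeights, tolerance = 1e-12)
  expect_equal(metricValues(coreness(net3)),
               3 * metricValues(coreness(net)), tolerance = 1e-12)
})

test_that("relabeling nodes permutes the outputs correspondingly", {
  net <- makeToyNetwork("random_digraph", nNodes = 6, seed = 23)
  prm <- c(4, 2, 6, 1, 3, 5)
  W <- weightMatrix(net)[prm, prm]
  netP <- directedNetwork(W, nodes = nodes(net)[prm])
  canon <- function(d) canonComplexes(lapply(d@members, sort), d@mcWeights)
  expect_identical(canon(listComplexes(net)), canon(listComplexes(netP)))
  kp <- metricValues(coreness(netP))
  k <- metricValues(coreness(net))
  expect_equal(kp[names(k)], k, tolerance = 1e-12)
})

test_that("normalize-and-average follows the per-condition convention", {
  m <- c(a = 4, b = 2, c = 0)
  one <- normalizeAverageCoreness(list(m))
  expect_equal(metricValues(one), c(a = 1, b = 0.5, c = 0))
  # averaging identical maps is idempotent
  eight <- normalizeAverageCoreness(rep(list(m), 8))
  expect_equal(metricValues(eight), metricValues(one))
  # hand-computed two-map case
  two <- normalizeAverageCoreness(list(c(a = 2, b = 0), c(a = 0, b = 3)))
  expect_equal(metricValues(two), c(a = 0.5, b = 0.5))
  # rest-session weighting: two half-weight maps behave as one condition
  wtd <- normalizeAverageCoreness(list(m, m, c(a = 0, b = 1, c = 1)),
                                  weights = c(0.5, 0.5, 1))
  expect_equal(metricValues(wtd),
               (c(a = 1, b = 0.5, c = 0) + c(a = 0, b = 1, c = 1)) / 2)
  expect_error(normalizeAverageCoreness(list(m, c(x = 1, y = 2, z = 3))),
               "node set")
  expect_warning(normalizeAverageCoreness(list(c(a = 0, b = 0))), "zero")
})
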