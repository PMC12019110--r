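test_that("symmetrization halves single-direction edges and fixes
           symmetric networks", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 4
  sym <- symmetrize(directedNetwork(W))
  expect_equal(weightMatrix(sym)["a", "b"], 2)
  expect_equal(weightMatrix(sym)["b", "a"], 2)
  expect_identical(weightMatrix(symmetrize(sym)), weightMatrix(sym))
})

test_that("symmetrized toy admits feedforward nodes into the top core", {
  net <- makeToyNetwork("fig1d_like")
  topBidir <- complexMembers(listComplexes(net), 1)
  topSym <- complexMembers(listComplexes(symmetrize(net)), 1)
  ff <- c("A", "C", "D", "G", "H")
  expect_true(all(!ff %in% topBidir))
  expect_gt(length(intersect(ff, topSym)), 0)
  # verified against the exhaustive definition on the symmetrized graph
  ora <- oracleComplexes(weightMatrix(symmetrize(net)))
  expect_identical(sort(nodes(net)[ora$members[[1]]]), topSym)
})

test_that("weighted degree sums attached edge weights in both directions", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- 2; W["b", "a"] <- 3; W["b", "c"] <- 1
  net <- directedNetwork(W)
  d <- metricValues(weightedDegree(net))
  expect_equal(d[["b"]], 6)
  expect_equal(d[["c"]], 1)
  # isolated node and handshake identity
  W4 <- rbind(cbind(W, 0), 0)
  net4 <- directedNetwork(W4, nodes = c("a", "b", "c", "iso"))
  d4 <- metricValues(weightedDegree(net4))
  expect_identical(d4[["iso"]], 0)
  expect_equal(sum(d4), 2 * sum(W4))
})

test_that("s-core decomposition: clique symmetry, star pruning order,
           and the defining property on random graphs", {
  # uniform clique: one shared s-coreness
  n <- 5
  K <- matrix(1, n, n); diag(K) <- 0
  sc <- metricValues(sCore(directedNetwork(K, nodes = letters[1:n])))
  expect_identical(length(unique(sc)), 1L)
  # star: leaves never outlast the hub
  S <- matrix(0, 5, 5, dimnames = list(c("h", paste0("l", 1:4)),
                                       c("h", paste0("l", 1:4))))
  S["h", -1] <- 1; S[-1, "h"] <- 1
  scs <- metricValues(sCore(directedNetwork(S)))
  expect_true(all(scs[paste0("l", 1:4)] <= scs[["h"]]))
  # random symmetric graphs satisfy the s-core defining property
  for (s in 1:10) {
    net <- symmetrize(makeToyNetwork("random_digraph", nNodes = 8,
                                     seed = 500 + s))
    sc <- metricValues(sCore(net))
    expect_true(oracleCheckSCore(weightMatrix(net), unname(sc)))
  }
  expect_error(sCore(makeToyNetwork("fig1d_like")), "symmetric")
})

test_that("functional rich-club score follows the printed formula", {
  # single node with out-weight 3 and in-weight 1: score 3 - 1 = 2
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 3; W["c", "a"] <- 1
  expect_equal(fricScore(directedNetwork(W), "a"), 2)
  # symmetric network: score reduces to the within-subset weight sum
  net <- symmetrize(makeToyNetwork("random_digraph", nNodes = 6, seed = 2))
  Ws <- weightMatrix(net)
  sub <- nodes(net)[1:3]
  expect_equal(fricScore(net, sub), sum(Ws[1:3, 1:3]))
  expect_error(fricScore(net, character(0)), "nonempty")
  expect_error(fricScore(net, "nope"), "unknown")
})

test_that("rich-club demo selects a core with feedforward nodes on the toy", {
  net <- makeToyNetwork("fig1d_like")
  rc <- fricRichClub(net)
  ff <- c("A", "C", "D", "G", "H")
  expect_gt(length(intersect(ff, rc$members)), 0)
  top <- complexMembers(listComplexes(net), 1)
  expect_true(all(!ff %in% top))
})
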