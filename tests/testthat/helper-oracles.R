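# Independent brute-force oracles, written against the definitions only and
# deliberately in a different style from the package internals (intToBits
# masks, plain loops). Used to verify cuts, complexes and coreness on small
# graphs.

# min over all bipartitions of min(w(L->R), w(R->L)) for the induced
# subgraph on integer indices `members`; 0 for single nodes.
oracleSubsetMc <- function(W, members) {
  k <- length(members)
  if (k < 2L) return(0)
  best <- Inf
  for (m in 1:(2^(k - 1L) - 1L)) {
    pick <- as.logical(intToBits(m))[1:k]
    L <- members[pick]
    R <- members[!pick]
    fwd <- 0; bwd <- 0
    for (u in L) for (v in R) { fwd <- fwd + W[u, v]; bwd <- bwd + W[v, u] }
    s <- min(fwd, bwd)
    if (s < best) best <- s
  }
  best
}

# tolerance semantics matching the package: equal-within-1e-9 does not count
# as strictly greater
oracleStrictGt <- function(a, b) {
  a > b && abs(a - b) > 1e-9 * max(1, abs(a), abs(b))
}

# all complexes by exhaustive application of the definition: subsets S with
# w^mc > 0 strictly exceeding w^mc of every strict superset. Returns a list
# with masks, member index vectors and weights, sorted by descending weight.
oracleComplexes <- function(W) {
  n <- nrow(W)
  masks <- integer(0); vals <- numeric(0); mem <- list()
  for (m in 1:(2^n - 1L)) {
    S <- which(as.logical(intToBits(m))[1:n])
    if (length(S) < 2L) next
    masks <- c(masks, m); mem <- c(mem, list(S))
    vals <- c(vals, oracleSubsetMc(W, S))
  }
  isComplex <- logical(length(masks))
  for (i in seq_along(masks)) {
    if (!(vals[i] > 1e-9)) next
    ok <- TRUE
    for (j in seq_along(masks)) {
      if (j == i) next
      if (bitwAnd(masks[i], masks[j]) == masks[i]) {  # j is a superset
        if (!oracleStrictGt(vals[i], vals[j])) { ok <- FALSE; break }
      }
    }
    isComplex[i] <- ok
  }
  keep <- which(isComplex)
  ord <- keep[order(-vals[keep])]
  list(members = mem[ord], weights = vals[ord])
}

# Eq.-12-style coreness: max w^mc over all subsets containing the node
oracleCorenessAllSubsets <- function(W) {
  n <- nrow(W)
  k <- numeric(n)
  for (m in 1:(2^n - 1L)) {
    S <- which(as.logical(intToBits(m))[1:n])
    if (length(S) < 2L) next
    v <- oracleSubsetMc(W, S)
    k[S] <- pmax(k[S], v)
  }
  k
}

# canonical representation of a set of complexes for comparison
canonComplexes <- function(members, weights) {
  ord <- order(-weights,
               vapply(members, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  list(
    sets = lapply(members[ord], sort),
    weights = weights[ord]
  )
}

# s-core property check: for every realized score level s, the nodes with
# score >= s must be exactly the s-core, i.e. the maximal subgraph in which
# every node's within-subgraph strength is >= s (computed by repeated
# deletion with strengths recomputed from scratch after every removal).
oracleCheckSCore <- function(W, score) {
  n <- nrow(W)
  strengthIn <- function(alive) rowSums(W[alive, alive, drop = FALSE]) +
    colSums(W[alive, alive, drop = FALSE])
  for (s in sort(unique(score[score > 0]))) {
    alive <- seq_len(n)
    repeat {
      if (length(alive) == 0) break
      st <- strengthIn(alive)
      bad <- alive[st < s - 1e-9]
      if (length(bad) == 0) break
      alive <- setdiff(alive, bad)
    }
    if (!setequal(alive, which(score >= s - 1e-9))) return(FALSE)
  }
  TRUE
}
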