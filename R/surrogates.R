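#' Block-permutation surrogate of a time series
#'
#' Partitions a series into contiguous blocks of \code{blockSize} points and
#' permutes the block order uniformly at random, preserving the within-block
#' ordering. This destroys cross-series coupling while keeping short-range
#' autocorrelation, which makes it a robust null for short series (a series
#' of 200 points with block size 10 yields about 20! distinct surrogates).
#' If the length is not a multiple of \code{blockSize}, the trailing short
#' block is treated as one block and permuted with the rest, so the value
#' multiset is always conserved.
#'
#' Randomness comes from the R session RNG; call \code{set.seed()} first for
#' reproducibility.
#'
#' @param series numeric vector (one trial of one node).
#' @param blockSize positive integer, at most \code{length(series)}.
#' @return numeric vector, a permutation of the input blocks.
#' @examples
#' set.seed(1)
#' blockPermutation(1:20, 5)
#' @export
blockPermutation <- function(series, blockSize) {
  n <- length(series)
  blockSize <- as.integer(blockSize)
  if (blockSize < 1L) stop("blockSize must be >= 1")
  if (blockSize > n) stop("blockSize exceeds series length")
  nBlocks <- ceiling(n / blockSize)
  if (nBlocks == 1L) return(series)
  blockId <- rep(seq_len(nBlocks), each = blockSize, length.out = n)
  ord <- sample.int(nBlocks)
  series[sequence(tabulate(blockId)[ord],
                  from = (ord - 1L) * blockSize + 1L)]
}

#' Upper-tail surrogate p-value via Gaussian kernel density estimation
#'
#' Fits a Gaussian-kernel density (Silverman's rule-of-thumb bandwidth,
#' \code{stats::bw.nrd0}) to the surrogate values and returns the analytic
#' upper-tail mass of the mixture at the observed value: only excess
#' predictability is evidence of influence, so the test is one-sided. When
#' the surrogates are all identical (zero bandwidth), the empirical rank
#' p-value (1 + #{surrogate >= observed}) / (n + 1) is used instead, with a
#' warning.
#'
#' @param observed observed statistic (e.g. NDTE of the unpermuted data).
#' @param surrogates numeric vector of surrogate statistics (length >= 2).
#' @return p-value in [0, 1], monotonically non-increasing in
#'   \code{observed}.
#' @examples
#' edgePValue(0.9, runif(100) * 0.2)
#' @export
edgePValue <- function(observed, surrogates) {
  if (length(surrogates) < 2L) stop("need at least 2 surrogate values")
  h <- if (diff(range(surrogates)) == 0) 0
       else tryCatch(stats::bw.nrd0(surrogates), error = function(e) 0)
  if (!is.finite(h) || h <= 0) {
    warning("degenerate surrogate distribution; using empirical rank p-value")
    return((1 + sum(surrogates >= observed)) / (length(surrogates) + 1))
  }
  mean(stats::pnorm(observed, mean = surrogates, sd = h, lower.tail = FALSE))
}

# Deterministic per-pair seed so that per-edge surrogate streams do not
# depend on the pair iteration order. Lehmer-style mixing, kept < 2^31 - 1.
.pairSeed <- function(seed, i, j) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + i * 100003 + j) %% m
  as.integer(s)
}
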