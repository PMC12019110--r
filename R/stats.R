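# vectorized Pearson correlations of paired bootstrap resamples:
# idx is a B x n matrix of row indices into (x, y)
.bootCors <- function(x, y, idx) {
  B <- nrow(idx); n <- ncol(idx)
  X <- matrix(x[idx], B, n)
  Y <- matrix(y[idx], B, n)
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxy <- rowSums(X * Y) - n * mx * my
  sxx <- rowSums(X * X) - n * mx * mx
  syy <- rowSums(Y * Y) - n * my * my
  sxy / sqrt(sxx * syy)
}

#' BCa interval from a bootstrap distribution
#'
#' Computes the bias-corrected and accelerated percentile interval given a
#' bootstrap distribution of a statistic, the point estimate, and
#' (optionally) jackknife leave-one-out values of the statistic from which
#' the acceleration constant is derived. With zero bias (half of the
#' bootstrap distribution below the estimate) and zero acceleration, the
#' interval reduces to the plain percentile interval. Degenerate cases
#' (constant bootstrap distribution, or an infinite bias z-score because no
#' or all resamples fall below the estimate) fall back to the percentile
#' interval with a warning.
#'
#' @param boots numeric vector of bootstrap statistic values.
#' @param estimate the statistic on the original sample.
#' @param jackknife optional numeric vector of leave-one-out statistic
#'   values; when NULL the acceleration is 0.
#' @param level confidence level (default 0.95).
#' @return list with \code{low}, \code{high}, and \code{method} ("bca" or
#'   "percentile").
#' @export
bcaInterval <- function(boots, estimate, jackknife = NULL, level = 0.95) {
  alpha <- (1 - level) / 2
  probs <- c(alpha, 1 - alpha)
  pct <- stats::quantile(boots, probs, names = FALSE, type = 6)
  propBelow <- mean(boots < estimate)
  if (stats::sd(boots) == 0 || propBelow <= 0 || propBelow >= 1) {
    warning("degenerate bootstrap distribution; using percentile interval")
    return(list(low = pct[1L], high = pct[2L], method = "percentile"))
  }
  z0 <- stats::qnorm(propBelow)
  a <- 0
  if (!is.null(jackknife)) {
    d <- mean(jackknife) - jackknife
    denom <- 6 * sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / denom
  }
  zq <- stats::qnorm(probs)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(boots, adj, names = FALSE, type = 6)
  list(low = ci[1L], high = ci[2L], method = "bca")
}

#' Pearson correlation with a BCa bootstrap confidence interval
#'
#' The sample Pearson correlation of paired values with a bias-corrected and
#' accelerated (BCa) percentile bootstrap interval: pairs (x_i, y_i) are
#' resampled jointly, the bias correction comes from the fraction of the
#' bootstrap distribution below the sample correlation, and the acceleration
#' from the skewness of jackknife leave-one-out correlations.
#'
#' @param x,y paired numeric vectors, length >= 3, no missing values.
#' @param nBoot number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return A [CorrelationResult-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.5 * x + rnorm(50)
#' pearsonBca(x, y, nBoot = 2000, seed = 1)
#' @export
pearsonBca <- function(x, y, nBoot = 10000L, level = 0.95, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  set.seed(as.integer(seed))
  nBoot <- as.integer(nBoot)
  # chunked to bound memory at ~8e6 indices per slab
  chunk <- max(1L, min(nBoot, as.integer(8e6 / n)))
  rb <- numeric(nBoot)
  done <- 0L
  while (done < nBoot) {
    b <- min(chunk, nBoot - done)
    idx <- matrix(sample.int(n, b * n, replace = TRUE), b, n)
    rb[(done + 1L):(done + b)] <- .bootCors(x, y, idx)
    done <- done + b
  }
  rb <- rb[is.finite(rb)]  # drop resamples with zero variance (tiny n)
  jk <- vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), numeric(1))
  ci <- bcaInterval(rb, r, jackknife = jk, level = level)
  new("CorrelationResult", r = r,
      ciLow = max(-1, ci$low), ciHigh = min(1, ci$high),
      n = as.integer(n), nBoot = nBoot, seed = as.integer(seed),
      method = ci$method)
}

#' Confidence band for a simple linear regression line
#'
#' For the least-squares line of y on x, the pointwise confidence band is
#' yhat +/- T_{1 - (1 - level)/2} * s_err * sqrt(1/n + (x - xbar)^2 /
#' sum_i (x_i - xbar)^2), with the t quantile on n - 2 degrees of freedom
#' and s_err the residual standard error. At x = xbar the half-width
#' reduces to T * s_err / sqrt(n); perfectly collinear data give a
#' zero-width band.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @param level confidence level (default 0.95).
#' @param xout abscissae at which to evaluate the band (default \code{x}).
#' @return data.frame with columns x, fit, halfWidth, lower, upper.
#' @examples
#' x <- 1:10; y <- 2 * x + rnorm(10)
#' regressionBand(x, y)
#' @export
regressionBand <- function(x, y, level = 0.95, xout = x) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  serr <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  yhat <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * xout
  hw <- tq * serr * sqrt(1 / n + (xout - mean(x))^2 / sxx)
  data.frame(x = xout, fit = as.numeric(yhat), halfWidth = hw,
             lower = as.numeric(yhat) - hw, upper = as.numeric(yhat) + hw)
}

#' One-way ANOVA with eta-squared effect size
#'
#' Classic between/within sums-of-squares decomposition across k groups:
#' F = (SS_between / (k - 1)) / (SS_within / (N - k)), p from the F
#' distribution, and eta^2 = SS_between / SS_total. Fully separated groups
#' with zero within-group variance give eta^2 = 1 (and an infinite F).
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list with \code{F}, \code{p}, \code{etaSquared}, \code{dfBetween},
#'   \code{dfWithin}.
#' @examples
#' oneWayAnova(list(rnorm(10), rnorm(10, mean = 2)))
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("each group needs at least 2 values")
  all <- unlist(groups)
  if (anyNA(all)) stop("missing values are not allowed")
  N <- length(all); k <- length(groups)
  gm <- mean(all)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sst <- ssb + ssw
  if (sst == 0) stop("all values identical; ANOVA undefined")
  Fst <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (N - k))
  p <- if (is.infinite(Fst)) 0 else
    stats::pf(Fst, k - 1, N - k, lower.tail = FALSE)
  list(F = Fst, p = p, etaSquared = ssb / sst,
       dfBetween = k - 1L, dfWithin = N - k)
}
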