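# Pooled lagged design matrices. Each trial contributes its own rows
# (response frames lagOrder+1 .. nTime), so lags never cross trials.

.asTrialMatrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  as.matrix(x)
}

# lag block of one series matrix (time x trials): pooled (rows x lagOrder)
# matrix with column k holding the series at lag k, plus the pooled response.
.lagBlock <- function(x, lagOrder) {
  x <- .asTrialMatrix(x)
  nt <- ncol(x)
  resp <- vector("list", nt)
  lags <- vector("list", nt)
  for (j in seq_len(nt)) {
    e <- stats::embed(x[, j], lagOrder + 1L)
    resp[[j]] <- e[, 1L]
    lags[[j]] <- e[, -1L, drop = FALSE]
  }
  list(resp = unlist(resp), lags = do.call(rbind, lags))
}

# ML residual variance of the least-squares fit of y on X
.residVarLS <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  mean(fit$residuals^2)
}

# core NDTE computation given pooled lag blocks of target (Ly) and source
# (Lx), the pooled target response, and the cached reduced residual variance
.ndteFromBlocks <- function(Ly, Lx, yresp, reducedVar = NULL,
                            varY = NULL) {
  if (is.null(reducedVar)) reducedVar <- .residVarLS(Ly, yresp)
  if (is.null(varY)) varY <- mean((yresp - mean(yresp))^2)
  fullVar <- .residVarLS(cbind(Ly, Lx), yresp)
  if (fullVar <= 0 || reducedVar <= 0 || varY <= 0)
    stop("nonpositive residual variance; input series may be degenerate")
  teRaw <- 0.5 * log(reducedVar / fullVar)
  te <- max(0, teRaw)
  norm <- 0.5 * log(varY / fullVar)
  if (norm <= 1e-12) {
    warning("normalization factor ~ 0 (target unpredictable); NDTE set to 0")
    ndte <- 0
    norm <- max(norm, 0)
  } else {
    ndte <- min(1, te / norm)
  }
  list(te = te, teRaw = teRaw, normFactor = norm, ndte = ndte,
       fullVar = fullVar, reducedVar = reducedVar, varY = varY)
}

#' Fit a bivariate VAR model by pooled ordinary least squares
#'
#' Fits Z_t = sum_k A_k Z_{t-k} + e_t for the pair Z_t = (x_t, y_t) by OLS,
#' pooling trials as independent realizations (each trial contributes its own
#' lagged rows; the first \code{lagOrder} frames of every trial are excluded
#' from the response). Series are assumed zero-mean (z-scored); no intercept
#' is fitted. The residual covariance is the ML estimate.
#'
#' @param x,y numeric matrices (time x trial) or vectors; x is the source
#'   (variable 1), y the target (variable 2).
#' @param lagOrder VAR order T.
#' @return A [BivariateVarModel-class].
#' @examples
#' ts <- simulateVarTimeSeries(rbind(c(0.5, 0.2), c(0, 0.4)),
#'                             nTrials = 5, nTime = 300, seed = 1)
#' m <- fitBivariateVar(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 1)
#' m@coefficients[[1]]
#' @export
fitBivariateVar <- function(x, y, lagOrder) {
  lagOrder <- as.integer(lagOrder)
  x <- .asTrialMatrix(x); y <- .asTrialMatrix(y)
  if (!all(dim(x) == dim(y)))
    stop("x and y must have identical (time x trial) dimensions")
  if (nrow(x) < lagOrder + 2L)
    stop("need at least 2 frames beyond lagOrder per trial")
  bx <- .lagBlock(x, lagOrder)
  by <- .lagBlock(y, lagOrder)
  # columns ordered (x_{t-1}, y_{t-1}, x_{t-2}, y_{t-2}, ...)
  p <- lagOrder
  D <- matrix(0, nrow = length(bx$resp), ncol = 2L * p)
  D[, seq(1L, 2L * p, by = 2L)] <- bx$lags
  D[, seq(2L, 2L * p, by = 2L)] <- by$lags
  Y <- cbind(bx$resp, by$resp)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient VAR design; using pseudo-inverse solution")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    B <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  } else {
    B <- qr.coef(qrD, Y)
  }
  res <- Y - D %*% B
  Sigma <- crossprod(res) / nrow(res)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(c("x", "y"), c("x", "y"))
  A <- lapply(seq_len(p), function(k) {
    Ak <- t(B[c(2L * k - 1L, 2L * k), , drop = FALSE])
    dimnames(Ak) <- list(c("x", "y"), c("x", "y"))
    Ak
  })
  new("BivariateVarModel", coefficients = A, residualCovariance = Sigma,
      lagOrder = p, nEffectiveObs = nrow(res))
}

#' Fit a univariate AR model and return its ML residual variance
#'
#' The reduced model of the NDTE computation: the target regressed on its own
#' \code{lagOrder} lags by pooled OLS over trials, on the same sample range
#' as the bivariate fit.
#'
#' @param y numeric matrix (time x trial) or vector.
#' @param lagOrder AR order.
#' @return ML residual variance (scalar).
#' @export
fitReducedAr <- function(y, lagOrder) {
  b <- .lagBlock(.asTrialMatrix(y), as.integer(lagOrder))
  .residVarLS(b$lags, b$resp)
}

#' Gaussian transfer entropy from a fitted bivariate VAR model
#'
#' Under the linear-Gaussian model, the transfer entropy from source to
#' target is the log ratio of the target's residual variances in the reduced
#' (target-only AR) and full (bivariate VAR) models:
#' TE = 1/2 log(sigma2_reduced / sigma2_full), in nats. Negative sampling
#' estimates are clipped to 0 (the population value is nonnegative) with the
#' raw value reported via a message.
#'
#' @param full a [BivariateVarModel-class]; the target is variable 2, so its
#'   full-model residual variance is \code{residualCovariance[2, 2]}.
#' @param reducedResidVar residual variance of the target's univariate
#'   AR(lagOrder) model fitted on the same sample range
#'   (see [fitReducedAr()]).
#' @return transfer entropy in nats (nonnegative scalar).
#' @export
transferEntropy <- function(full, reducedResidVar) {
  stopifnot(is(full, "BivariateVarModel"))
  sigmaFull <- full@residualCovariance[2L, 2L]
  if (!is.finite(reducedResidVar) || reducedResidVar <= 0)
    stop("reducedResidVar must be a positive finite scalar")
  if (sigmaFull <= 0)
    stop("full-model residual variance is nonpositive")
  raw <- 0.5 * log(reducedResidVar / sigmaFull)
  if (raw < 0) {
    message(sprintf("negative sample TE (%.3g nats) clipped to 0", raw))
    return(0)
  }
  raw
}

#' Normalized directed transfer entropy between two series
#'
#' Computes the NDTE F_{XY} = TE / I(Y_{i+1}; X^i, Y^i) for the ordered pair
#' (x -> y) under the Gaussian closed form: with sigma2_full the target's
#' bivariate-VAR residual variance, sigma2_red its univariate-AR residual
#' variance and Var(Y) its marginal variance over the pooled response rows,
#' TE = 1/2 log(sigma2_red / sigma2_full) and the normalization factor is
#' 1/2 log(Var(Y) / sigma2_full) = TE + I(Y_{i+1}; Y^i). The ratio lies in
#' [0, 1]: the normalization compares the source's predictive contribution
#' with the target's total predictability.
#'
#' @param x,y numeric matrices (time x trial) or vectors; x drives y.
#' @param lagOrder VAR order (default 10).
#' @param sourceLabel,targetLabel node labels stored in the result.
#' @return An [EdgeEstimate-class] with \code{pValue = NA} (run a surrogate
#'   test, e.g. via [buildDirectedNetwork()], to obtain one).
#' @examples
#' ts <- simulateVarTimeSeries(rbind(c(0.3, 0), c(0.4, 0.3)),
#'                             nTrials = 5, nTime = 300, seed = 2)
#' ndteEdge(ts@values[, 1, ], ts@values[, 2, ], lagOrder = 3)
#' @export
ndteEdge <- function(x, y, lagOrder = 10L, sourceLabel = "x",
                     targetLabel = "y") {
  lagOrder <- as.integer(lagOrder)
  bx <- .lagBlock(.asTrialMatrix(x), lagOrder)
  by <- .lagBlock(.asTrialMatrix(y), lagOrder)
  st <- .ndteFromBlocks(by$lags, bx$lags, by$resp)
  new("EdgeEstimate", source = sourceLabel, target = targetLabel,
      te = st$te, normFactor = st$normFactor, ndte = st$ndte,
      pValue = NA_real_)
}
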