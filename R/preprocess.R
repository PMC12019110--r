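#' Z-score and band-pass filter multi-trial time series
#'
#' Standard preprocessing for BOLD-like region time series before directed
#' network estimation: each (trial, node) series is first normalized to
#' z-scores, then band-pass filtered with a zero-phase (forward-backward)
#' Butterworth filter. The default band 0.008--0.08 Hz with a second-order
#' filter targets the slow fluctuations carrying functional connectivity at
#' typical fMRI sampling rates.
#'
#' @param raw a [RoiTimeSeriesSet-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   0 < lowHz < highHz < Nyquist.
#' @param filterOrder Butterworth order (of each of the low/high sections).
#' @param bandpass logical; if FALSE, only the z-scoring stage is applied
#'   (useful for inspecting the two stages separately).
#' @return A preprocessed [RoiTimeSeriesSet-class] (same shape,
#'   \code{preprocessed = TRUE}).
#' @examples
#' ts <- simulateVarTimeSeries(diag(0.3, 2), nTrials = 2, nTime = 200,
#'                             seed = 1)
#' pp <- preprocessTimeSeries(ts)
#' @export
preprocessTimeSeries <- function(raw, lowHz = 0.008, highHz = 0.08,
                                 filterOrder = 2L, bandpass = TRUE) {
  stopifnot(is(raw, "RoiTimeSeriesSet"))
  v <- raw@values
  d <- dim(v)
  fs <- 1 / raw@samplingInterval
  nyq <- fs / 2
  if (bandpass) {
    if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
      stop(sprintf(
        "band edges must satisfy 0 < lowHz < highHz < Nyquist (%.4g Hz)",
        nyq))
    filt <- signal::butter(filterOrder, c(lowHz, highHz) / nyq, type = "pass")
  }
  out <- v
  for (tr in seq_len(d[3L])) {
    for (nd in seq_len(d[2L])) {
      x <- v[, nd, tr]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0)
        stop(sprintf("constant series: trial %d, node '%s'",
                     tr, raw@nodeLabels[nd]))
      z <- (x - mean(x)) / s
      out[, nd, tr] <- if (bandpass) signal::filtfilt(filt, z) else z
    }
  }
  new("RoiTimeSeriesSet", values = out, nodeLabels = raw@nodeLabels,
      samplingInterval = raw@samplingInterval, preprocessed = TRUE)
}

#' Magnitude response of the preprocessing band-pass filter
#'
#' Evaluates |H(f)|^2 of the zero-phase Butterworth band-pass used by
#' [preprocessTimeSeries()] at given frequencies, by direct evaluation of the
#' filter polynomials on the unit circle (the squaring accounts for the
#' forward-backward pass).
#'
#' @param freqHz frequencies at which to evaluate, Hz.
#' @param samplingInterval seconds per frame.
#' @param lowHz,highHz,filterOrder as in [preprocessTimeSeries()].
#' @return numeric vector of squared magnitudes.
#' @export
bandpassGain <- function(freqHz, samplingInterval = 0.72, lowHz = 0.008,
                         highHz = 0.08, filterOrder = 2L) {
  nyq <- 1 / (2 * samplingInterval)
  filt <- signal::butter(filterOrder, c(lowHz, highHz) / nyq, type = "pass")
  w <- pi * freqHz / nyq
  z <- exp(-1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(filt$b * zz^(seq_along(filt$b) - 1))
    den <- sum(filt$a * zz^(seq_along(filt$a) - 1))
    Mod(num / den)
  }, numeric(1))
  h^2
}
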