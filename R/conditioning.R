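## Signal conditioning: linear detrend, unit-maximum normalization, and the
## ideal (brick-wall) frequency-domain band-pass filter.

#' Remove the best-fit linear trend
#'
#' Fits a straight line to the whole trace by least squares and subtracts
#' it, removing slow sensor drift (and the mean) before analysis.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Detrended vector of the same length, zero mean.
#' @examples
#' detrendSignal(5 * (0:9) + 3)   # a pure ramp vanishes
#' @export
detrendSignal <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("detrendSignal needs at least 2 samples")
  t0 <- seq_len(n) - (n + 1) / 2          # centered time index
  slope <- sum(t0 * samples) / sum(t0 * t0)
  out <- samples - mean(samples) - slope * t0
  ## a trace that is linear to machine precision leaves only rounding
  ## residue; snap it to exact zero so downstream code sees it as degenerate
  if (max(abs(out)) < 1e-10 * max(abs(samples), 1)) out[] <- 0
  out
}

#' Normalize a trace to unit maximum amplitude
#'
#' Divides by the absolute maximum so the result is unitless with
#' \code{max(abs(x)) == 1}, making peak thresholds comparable across
#' subjects and channels.
#'
#' @param samples Numeric vector, not all zeros.
#' @return \code{samples / max(abs(samples))}.
#' @examples
#' normalizeSignal(c(2, -4, 1))
#' @export
normalizeSignal <- function(samples) {
  if (length(samples) == 0L) stop("degenerate signal: empty")
  m <- max(abs(samples))
  if (m == 0) stop("degenerate signal: all zeros")
  samples / m
}

#' Ideal frequency-domain band-pass filter
#'
#' Brick-wall filter: the discrete Fourier transform of the trace is
#' computed, bins whose frequency magnitude lies in \code{[w1_hz, w2_hz]}
#' (inclusive, positive and negative frequencies symmetrically) are kept
#' with unit gain, all other bins are zeroed, and the real part of the
#' inverse transform is returned.  No windowing or padding is applied; the
#' filter is a projection, so applying it twice equals applying it once.
#'
#' @param samples Numeric vector.
#' @param rate_hz Sampling rate in Hz.
#' @param w1_hz,w2_hz Band edges, \code{0 <= w1 < w2 <= rate_hz / 2}.
#' @return Filtered vector, same length as the input.
#' @examples
#' t <- seq(0, 1 - 1/60, by = 1/60)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t)
#' y <- idealBandpass(x, 60, 0.5, 10)   # keeps only the 5 Hz tone
#' @export
idealBandpass <- function(samples, rate_hz, w1_hz, w2_hz) {
  if (w1_hz < 0 || w1_hz >= w2_hz)
    stop("band edges must satisfy 0 <= w1 < w2")
  if (w2_hz > rate_hz / 2 + 1e-12)
    stop("w2 exceeds the Nyquist frequency (", rate_hz / 2, " Hz)")
  n <- length(samples)
  if (n < 2L) stop("idealBandpass needs at least 2 samples")
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * rate_hz / n    # |frequency| of each bin
  keep <- freq >= w1_hz & freq <= w2_hz
  X <- fft(samples)
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Condition a sensor channel
#'
#' Applies the conditioning chain in order: linear detrend, normalization
#' to unit maximum amplitude, ideal band-pass.  The applied band edges are
#' recorded as attributes \code{w1_hz} / \code{w2_hz}.
#'
#' @param samples Numeric vector.
#' @param rate_hz Sampling rate in Hz.
#' @param w1_hz Low cutoff (Hz).
#' @param w2_hz High cutoff (Hz).
#' @return Conditioned numeric vector with attributes \code{rate_hz},
#'   \code{w1_hz}, \code{w2_hz}.
#' @export
conditionSignal <- function(samples, rate_hz, w1_hz, w2_hz) {
  out <- idealBandpass(normalizeSignal(detrendSignal(samples)),
                       rate_hz, w1_hz, w2_hz)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "w1_hz") <- w1_hz
  attr(out, "w2_hz") <- w2_hz
  out
}

#' Condition a channel of a recording
#'
#' Fetches \code{(site, quantity, axis)} from the recording (computing the
#' joint range-of-motion trace on the fly when \code{quantity = "rom"}) and
#' applies \code{\link{conditionSignal}}.
#'
#' @param rec A \linkS4class{TugRecording}.
#' @param site,quantity,axis Channel identity; \code{quantity = "rom"}
#'   with e.g. \code{site = "left_knee"} uses \code{\link{romTrace}}.
#' @param w2_hz High cutoff (Hz).
#' @param w1_hz Low cutoff (Hz, default 0.0025).
#' @return Conditioned numeric vector (see \code{\link{conditionSignal}}).
#' @export
conditionChannel <- function(rec, site, quantity, axis, w2_hz,
                             w1_hz = 0.0025) {
  samples <- if (identical(quantity, "rom")) {
    romTrace(rec, joint = site)$angles_deg
  } else {
    getChannel(rec, site, quantity, axis)
  }
  out <- conditionSignal(samples, rateHz(rec), w1_hz, w2_hz)
  attr(out, "source") <- c(site = site, quantity = quantity, axis = axis)
  out
}
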