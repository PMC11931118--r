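## Zero-phase low-pass filtering.
##
## Coefficients come from signal::butter; the forward-backward application is
## done here because it needs odd-reflection end padding and steady-state
## initial conditions to keep edge transients bounded — a constant input must
## come back unchanged. Direct-form II transposed; n is at most a few
## thousand samples, so plain R loops are fast enough.

.iirFilter <- function(b, a, x, zi) {
  n <- length(x); m <- length(a)
  y <- numeric(n); z <- zi
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (m > 2L)
      for (j in seq_len(m - 2L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
    z[m - 1L] <- b[m] * x[i] - a[m] * y[i]
  }
  y
}

## Steady-state filter state for a unit-step input. For a unity-DC-gain
## filter the DF2T state satisfies z_j = sum_{k>j} (b_k - a_k).
.steadyState <- function(b, a) rev(cumsum(rev(b[-1L] - a[-1L])))

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forwards and
#' backwards (zero phase; the effective magnitude response is the squared
#' single-pass response, with -3 dB of the single pass at `cutoffHz`).
#' Ends are extended by odd reflection and the filter is started from its
#' steady state, so a constant series passes through unchanged and edge
#' transients stay small. Zero phase matters here because pattern timing is
#' compared across body regions: a causal filter's group delay would shift
#' one pattern against the other and bias their cosine similarity.
#'
#' @param x Numeric vector, uniformly sampled, no missing values.
#' @param cutoffHz Cutoff frequency in Hz (default 0.08).
#' @param fps Sampling rate in frames/second (default 8.7).
#' @param order Filter order for each pass (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
#' @examples
#' t <- (0:869) / 8.7
#' x <- sin(2 * pi * 0.01 * t) + 0.5 * sin(2 * pi * 1 * t)
#' y <- lowpassFilter(x)         # the 1 Hz component is removed
lowpassFilter <- function(x, cutoffHz = 0.08, fps = 8.7, order = 4L) {
  .checkNumber(cutoffHz, "cutoffHz", lower = 0, strict_lower = TRUE)
  .checkNumber(fps, "fps", lower = 0, strict_lower = TRUE)
  if (cutoffHz >= fps / 2)
    configError("cutoffHz (%g) must be below the Nyquist rate %g", cutoffHz,
                fps / 2)
  if (anyNA(x)) inputError("lowpassFilter requires a gapless series")
  n <- length(x)
  if (n < 3L * order + 1L)
    degenerateInputError(
      "series of length %d is shorter than the filter warm-up (%d points)",
      n, 3L * order + 1L)
  bf <- signal::butter(order, cutoffHz / (fps / 2), type = "low")
  b <- bf$b; a <- bf$a
  ## the reflection padding must cover the filter's settling time, which for
  ## a cutoff far below Nyquist is ~ several / cutoffHz seconds; too-short
  ## padding leaks edge transients across the whole record
  padlen <- min(n - 1L,
                max(3L * max(length(a), length(b)),
                    as.integer(ceiling(3 * fps / cutoffHz))))
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- .steadyState(b, a)
  y <- .iirFilter(b, a, ext, zi * ext[1L])
  y <- rev(.iirFilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Squared-magnitude response of the zero-phase Butterworth filter
#'
#' Analytic amplitude gain of [lowpassFilter()] at frequency `freqHz`:
#' `1 / (1 + (f / fc)^(2 * order))` for the forward-backward application
#' (i.e. the single-pass power response becomes the two-pass amplitude
#' response).
#'
#' @param freqHz Frequency in Hz (vectorized).
#' @param cutoffHz Cutoff frequency in Hz.
#' @param order Per-pass filter order.
#' @return Amplitude gain(s) in `[0, 1]`.
#' @export
butterworthGain <- function(freqHz, cutoffHz = 0.08, order = 4L) {
  1 / (1 + (freqHz / cutoffHz)^(2L * order))
}
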