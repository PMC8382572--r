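## Continuous-data cleaning: zero-phase band-pass filtering and adaptive
## (NLMS) ocular-artifact removal referenced to the EOG channel.

#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass (default 0.5-20 Hz) forward and
#' backward (`signal::filtfilt`) to every channel, EOG included. Zero-phase
#' filtering preserves peak latencies; the squared magnitude response keeps
#' the mid-band gain within a few percent of unity.
#'
#' @param recording a [RawRecording-class].
#' @param low,high band edges in Hz; need `0 < low < high < rate/2`.
#' @param order Butterworth order (default 4).
#' @return the filtered [RawRecording-class] (same length, same markers).
#' @export
bandpassFilter <- function(recording, low = 0.5, high = 20, order = 4) {
  fs <- sampleRate(recording)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- eegData(recording)
  for (i in seq_len(nrow(x)))
    x[i, ] <- signal::filtfilt(bf, x[i, ])
  RawRecording(x, sampleRate = fs, markers = markers(recording))
}

## Normalized least-mean-squares filter: predict `d` from the last `order`
## samples of reference `u`; returns the prediction error (the cleaned signal).
nlmsClean <- function(d, u, order = 3, mu = 0.01, eps = 1e-8) {
  n <- length(d)
  ## lagged reference matrix: row t = u[t], u[t-1], ..., u[t-order+1]
  U <- matrix(0, n, order)
  for (k in seq_len(order)) U[k:n, k] <- u[seq_len(n - k + 1L)]
  nrm <- rowSums(U^2)
  w <- numeric(order)
  out <- numeric(n)
  for (t in seq_len(n)) {
    ut <- U[t, ]
    e <- d[t] - sum(w * ut)
    out[t] <- e
    w <- w + (mu / (eps + nrm[t])) * e * ut
  }
  out
}

#' Remove ocular artifacts with an adaptive filter
#'
#' Subtracts the EOG-correlated component from each scalp channel using a
#' normalized least-mean-squares (NLMS) adaptive filter with the EOG channel
#' as reference. With a silent EOG the weights never update and the scalp
#' channels pass through unchanged.
#'
#' @param recording a [RawRecording-class] containing an `EOG` channel.
#' @param order number of filter taps (default 3).
#' @param mu NLMS step size (default 0.001; small enough that weight-noise
#'   leakage of stimulus-locked signal is negligible while blink weights
#'   converge within seconds).
#' @return the corrected [RawRecording-class]; EOG passed through unchanged.
#' @export
removeOcularArtifacts <- function(recording, order = 3, mu = 0.001) {
  x <- eegData(recording)
  if (!"EOG" %in% rownames(x))
    stop("recording has no EOG channel; ocular correction needs one")
  eog <- x["EOG", ]
  for (ch in setdiff(rownames(x), "EOG"))
    x[ch, ] <- nlmsClean(x[ch, ], eog, order = order, mu = mu)
  RawRecording(x, sampleRate = sampleRate(recording),
               markers = markers(recording))
}
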