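## Epoch segmentation, baseline correction, amplitude-threshold rejection,
## participant-level QC, and condition averaging.

#' Segment a recording into baseline-corrected epochs
#'
#' Cuts one epoch per marker of an analyzable condition (`standard`,
#' `deviant`, `congruent`, `incongruent`; word primes are not epoched) and
#' subtracts the per-channel mean over the baseline interval. Epochs whose
#' window would overlap a recording edge are dropped and counted in the
#' `nDropped` slot.
#'
#' @param recording a [RawRecording-class] with markers.
#' @param window `c(pre, post)` in ms relative to stimulus onset (pre < 0).
#' @param baseline `c(b0, b1)` in ms; must lie inside `window`.
#' @return an [EpochSet-class].
#' @export
segmentEpochs <- function(recording, window = c(-100, 900),
                          baseline = c(-100, 0)) {
  if (window[1] >= 0 || window[2] <= 0)
    stop("window must be c(pre, post) with pre < 0 < post")
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline interval must lie inside the epoch window")
  fs <- sampleRate(recording)
  x <- eegData(recording)
  ev <- events(markers(recording))
  ev <- ev[ev$condition %in% c("standard", "deviant", "congruent",
                               "incongruent"), , drop = FALSE]
  if (!nrow(ev)) warning("no analyzable markers; returning empty epoch set")

  preS <- round(window[1] * fs / 1000)         # negative
  postS <- round(window[2] * fs / 1000)
  nsamp <- postS - preS + 1L
  bIdx <- which(seq(preS, postS) * 1000 / fs >= baseline[1] &
                  seq(preS, postS) * 1000 / fs <= baseline[2])

  eps <- list(); cond <- character(0); dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    onset <- round(ev$onset[i] * fs) + 1L      # sample index of onset
    i0 <- onset + preS; i1 <- onset + postS
    if (i0 < 1L || i1 > ncol(x)) { dropped <- dropped + 1L; next }
    e <- x[, i0:i1, drop = FALSE]
    e <- e - rowMeans(e[, bIdx, drop = FALSE]) # baseline correction
    eps[[length(eps) + 1L]] <- e
    cond <- c(cond, ev$condition[i])
  }
  if (dropped > 0L)
    message(dropped, " epoch(s) dropped at recording edges")
  new("EpochSet", epochs = eps, condition = cond, sampleRate = fs,
      windowMs = window, baselineMs = baseline,
      channels = rownames(x), rejected = rep(FALSE, length(eps)),
      rejectionReason = rep(NA_character_, length(eps)), nDropped = dropped)
}

#' Flag epochs exceeding an absolute amplitude threshold
#'
#' An epoch is flagged rejected iff any sample on any scalp channel (EOG is
#' not consulted) exceeds `threshold` in absolute value. Epochs remain in
#' the set so rejection fractions can be computed.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold uV (default 75, i.e. the +/-75 uV rule).
#' @return the flagged [EpochSet-class].
#' @export
rejectEpochs <- function(epochs, threshold = 75) {
  if (threshold <= 0) stop("threshold must be > 0")
  es <- epochs
  scalp <- setdiff(es@channels, "EOG")
  for (i in seq_along(es@epochs)) {
    mx <- max(abs(es@epochs[[i]][scalp, , drop = FALSE]))
    if (mx > threshold) {
      es@rejected[i] <- TRUE
      es@rejectionReason[i] <- sprintf("amplitude %.1f uV > %g uV", mx,
                                       threshold)
    } else {
      es@rejected[i] <- FALSE
      es@rejectionReason[i] <- NA_character_
    }
  }
  es
}

#' Participant-level data-quality check
#'
#' @param epochs an [EpochSet-class] (after [rejectEpochs()]).
#' @param maxRejection exclusion bound; the participant-session is
#'   `excluded_quality` iff the rejected fraction strictly exceeds it
#'   (default 0.25).
#' @return list with `qc` (`"included"`/`"excluded_quality"`) and
#'   `rejectionFraction`.
#' @export
qcParticipant <- function(epochs, maxRejection = 0.25) {
  n <- nEpochs(epochs)
  if (n == 0L) stop("no epochs to assess")
  frac <- sum(isRejected(epochs)) / n
  list(qc = if (frac > maxRejection) "excluded_quality" else "included",
       rejectionFraction = frac)
}

#' AverageWaveform: condition average at one electrode
#'
#' @slot condition condition label.
#' @slot electrode electrode label.
#' @slot samples the averaged time series (uV).
#' @slot nEpochsIncluded number of non-rejected epochs averaged.
#' @slot sampleRate Hz.
#' @slot windowMs epoch window in ms.
#' @export
setClass("AverageWaveform",
         representation(condition = "character", electrode = "character",
                        samples = "numeric", nEpochsIncluded = "integer",
                        sampleRate = "numeric", windowMs = "numeric"))

setValidity("AverageWaveform", function(object) {
  if (object@nEpochsIncluded < 1L) return("nEpochsIncluded must be >= 1")
  nsamp <- round(diff(object@windowMs) * object@sampleRate / 1000) + 1L
  if (length(object@samples) != nsamp)
    return("sample count does not match the window")
  TRUE
})

setMethod("show", "AverageWaveform", function(object) {
  cat(sprintf("AverageWaveform: %s @ %s, %d epochs, [%g, %g] ms\n",
              object@condition, object@electrode, object@nEpochsIncluded,
              object@windowMs[1], object@windowMs[2]))
})

#' Average non-rejected epochs of one condition at one electrode
#'
#' @param epochs an [EpochSet-class].
#' @param condition condition label to average.
#' @param electrode channel label.
#' @return an [AverageWaveform-class].
#' @export
averageCondition <- function(epochs, condition, electrode) {
  keep <- which(epochs@condition == condition & !epochs@rejected)
  if (!length(keep))
    stop(sprintf("no usable '%s' epochs; measure is missing", condition))
  if (!electrode %in% epochs@channels)
    stop("unknown electrode: ", electrode)
  acc <- rowMeans(vapply(keep, function(i) epochs@epochs[[i]][electrode, ],
                         numeric(ncol(epochs@epochs[[1]]))))
  new("AverageWaveform", condition = condition, electrode = electrode,
      samples = acc, nEpochsIncluded = length(keep),
      sampleRate = epochs@sampleRate, windowMs = epochs@windowMs)
}
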