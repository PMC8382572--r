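## Central S4 containers. Each class has a validity method and a same-named
## constructor; slots are reached through the accessors in AllGenerics.R.

#' StimulusSequence: ordered auditory stimulus events
#'
#' Holds the event list of one stimulus paradigm: oddball tones
#' (`standard_tone`/`deviant_tone`) and/or word pairs
#' (`word_prime`/`word_target`). Onsets are seconds from recording start and
#' strictly increasing; every `word_target` immediately follows its
#' `word_prime` and carries a `congruent`/`incongruent` condition.
#'
#' @slot events data.frame with columns `onset` (s), `kind`, `condition`,
#'   and for word events `word` (the token presented, `NA` for tones).
#' @export
setClass("StimulusSequence", representation(events = "data.frame"))

.stim_kinds <- c("standard_tone", "deviant_tone", "word_prime", "word_target")
.stim_conditions <- c("standard", "deviant", "congruent", "incongruent", "none")

setValidity("StimulusSequence", function(object) {
  ev <- object@events
  need <- c("onset", "kind", "condition")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ev) == 0L) return(TRUE)
  if (any(!is.finite(ev$onset)) || any(ev$onset < 0))
    return("onsets must be finite and >= 0")
  if (is.unsorted(ev$onset, strictly = TRUE))
    return("onsets must be strictly increasing")
  if (!all(ev$kind %in% .stim_kinds))
    return("unknown event kind")
  if (!all(ev$condition %in% .stim_conditions))
    return("unknown event condition")
  tgt <- which(ev$kind == "word_target")
  if (length(tgt)) {
    if (any(tgt == 1L) || any(ev$kind[tgt - 1L] != "word_prime"))
      return("every word_target must follow a word_prime")
    if (!all(ev$condition[tgt] %in% c("congruent", "incongruent")))
      return("word_target condition must be congruent or incongruent")
  }
  TRUE
})

#' @rdname StimulusSequence-class
#' @param events data.frame of events (see slot description).
#' @return A `StimulusSequence`.
#' @export
StimulusSequence <- function(events) {
  if (!"word" %in% names(events))
    events$word <- rep(NA_character_, nrow(events))
  rownames(events) <- NULL
  new("StimulusSequence", events = events)
}

#' RawRecording: multichannel sampled EEG with event markers
#'
#' A continuous multichannel recording in microvolts, channels in rows.
#' The default montage is the three midline scalp electrodes Fz, Cz, Pz plus
#' an EOG channel, sampled at 500 Hz.
#'
#' @slot sampleRate sampling rate in Hz.
#' @slot data numeric matrix, channels x samples, rownames = channel labels.
#' @slot markers a [StimulusSequence-class] aligned to the sample clock.
#' @export
setClass("RawRecording",
         representation(sampleRate = "numeric", data = "matrix",
                        markers = "StimulusSequence"))

setValidity("RawRecording", function(object) {
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    return("sampleRate must be a single positive number")
  if (is.null(rownames(object@data)))
    return("data must have channel labels as rownames")
  if (!all(is.finite(object@data)))
    return("data must be finite")
  ev <- object@markers@events
  if (nrow(ev) && max(ev$onset) * object@sampleRate > ncol(object@data))
    return("recording shorter than last marker onset")
  TRUE
})

#' @rdname RawRecording-class
#' @param data channels x samples numeric matrix (rownames = channels).
#' @param sampleRate Hz.
#' @param markers a `StimulusSequence` (default: empty).
#' @return A `RawRecording`.
#' @export
RawRecording <- function(data, sampleRate = 500,
                         markers = StimulusSequence(data.frame(
                           onset = numeric(0), kind = character(0),
                           condition = character(0)))) {
  new("RawRecording", sampleRate = sampleRate, data = data, markers = markers)
}

#' EpochSet: stimulus-locked epochs cut from a recording
#'
#' One epoch per analyzable marker, stored as channels x samples matrices,
#' baseline-corrected over the configured baseline interval. Rejected epochs
#' stay in the set (flagged) so that rejection fractions can be computed.
#'
#' @slot epochs list of channels x samples matrices (uV).
#' @slot condition condition label per epoch.
#' @slot sampleRate Hz.
#' @slot windowMs `c(pre, post)` in ms relative to stimulus onset (pre < 0).
#' @slot baselineMs `c(b0, b1)` baseline interval in ms.
#' @slot channels channel labels.
#' @slot rejected logical flag per epoch.
#' @slot rejectionReason character per epoch (`NA` if kept).
#' @slot nDropped epochs dropped at segmentation because they overlapped a
#'   recording edge.
#' @export
setClass("EpochSet",
         representation(epochs = "list", condition = "character",
                        sampleRate = "numeric", windowMs = "numeric",
                        baselineMs = "numeric", channels = "character",
                        rejected = "logical", rejectionReason = "character",
                        nDropped = "integer"))

setValidity("EpochSet", function(object) {
  n <- length(object@epochs)
  if (length(object@condition) != n || length(object@rejected) != n ||
      length(object@rejectionReason) != n)
    return("per-epoch slots must have one entry per epoch")
  if (length(object@windowMs) != 2L || object@windowMs[1] >= 0 ||
      object@windowMs[2] <= 0)
    return("windowMs must be c(pre, post) with pre < 0 < post")
  nsamp <- round(diff(object@windowMs) * object@sampleRate / 1000) + 1L
  for (e in object@epochs) {
    if (!is.matrix(e) || ncol(e) != nsamp || nrow(e) != length(object@channels))
      return("epoch matrices must be channels x window samples")
  }
  TRUE
})

#' ErpMeasurementSet: the six brain vital signs of one participant-session
#'
#' @slot participantId participant label.
#' @slot session session index (1 = first scan, 2 = retest).
#' @slot measures named numeric of the six measures ([bvsMeasures()]);
#'   amplitudes are magnitudes in uV, latencies in ms; `NA` = missing.
#' @slot qc one of `"included"`, `"excluded_quality"`,
#'   `"n400_missing_language"`.
#' @slot rejectionFraction fraction of epochs rejected for this session.
#' @slot edgeFallback named logical per measure: peak taken at a window edge
#'   because no interior local extremum existed.
#' @export
setClass("ErpMeasurementSet",
         representation(participantId = "character", session = "integer",
                        measures = "numeric", qc = "character",
                        rejectionFraction = "numeric",
                        edgeFallback = "logical"))

setValidity("ErpMeasurementSet", function(object) {
  if (!identical(names(object@measures), bvsMeasures()))
    return("measures must be named by bvsMeasures(), in order")
  if (!object@qc %in% c("included", "excluded_quality", "n400_missing_language"))
    return("invalid qc status")
  amp <- object@measures[c(1, 3, 5)]
  if (any(!is.na(amp) & amp < 0))
    return("amplitudes are magnitudes and must be >= 0")
  rf <- object@rejectionFraction
  if (length(rf) != 1L || is.na(rf) || rf < 0 || rf > 1)
    return("rejectionFraction must be in [0, 1]")
  if (identical(object@qc, "excluded_quality") != (rf > 0.25))
    return("qc is excluded_quality iff rejectionFraction > 0.25")
  TRUE
})

#' @rdname ErpMeasurementSet-class
#' @param participantId,session,measures,qc,rejectionFraction,edgeFallback
#'   see slots.
#' @return An `ErpMeasurementSet`.
#' @export
ErpMeasurementSet <- function(participantId, session, measures,
                              qc = "included", rejectionFraction = 0,
                              edgeFallback = setNames(rep(FALSE, 6L),
                                                      bvsMeasures())) {
  m <- setNames(rep(NA_real_, 6L), bvsMeasures())
  m[names(measures)] <- measures
  new("ErpMeasurementSet", participantId = as.character(participantId),
      session = as.integer(session), measures = m, qc = qc,
      rejectionFraction = rejectionFraction, edgeFallback = edgeFallback)
}

#' ReferenceDistribution: normative mean/SD per measure
#'
#' The anchor for 0-100 standardized scoring: per-measure sample mean,
#' sample SD (denominator n-1) and n from a reference cohort.
#'
#' @slot stats data.frame with columns `measure`, `mean`, `sd`, `n`, `unit`.
#' @export
setClass("ReferenceDistribution", representation(stats = "data.frame"))

setValidity("ReferenceDistribution", function(object) {
  s <- object@stats
  need <- c("measure", "mean", "sd", "n", "unit")
  if (!all(need %in% names(s)))
    return(sprintf("stats must have columns %s", paste(need, collapse = ", ")))
  if (any(duplicated(s$measure))) return("duplicate measures")
  if (!all(s$measure %in% bvsMeasures())) return("unknown measure name")
  if (any(!is.finite(s$sd)) || any(s$sd <= 0)) return("sd must be > 0")
  TRUE
})

#' @rdname ReferenceDistribution-class
#' @param stats data.frame (see slot description).
#' @return A `ReferenceDistribution`.
#' @export
ReferenceDistribution <- function(stats) {
  stats <- stats[match(intersect(bvsMeasures(), stats$measure), stats$measure), ]
  rownames(stats) <- NULL
  new("ReferenceDistribution", stats = stats)
}

#' StandardizedProfile: six 0-100 scores for one participant-session
#'
#' @slot scores named numeric of 0-100 scores in [bvsMeasures()] order.
#' @slot z the underlying z-values.
#' @slot label profile label (used in radar legends).
#' @export
setClass("StandardizedProfile",
         representation(scores = "numeric", z = "numeric", label = "character"))

setValidity("StandardizedProfile", function(object) {
  if (!identical(names(object@scores), bvsMeasures()))
    return("scores must be named by bvsMeasures(), in order")
  ok <- is.na(object@scores) | (object@scores >= 0 & object@scores <= 100)
  if (!all(ok)) return("scores must lie in [0, 100]")
  if (any(is.infinite(object@z))) return("z must be finite or NA")
  TRUE
})
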