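## Peak measurement: local-extremum search inside per-component detection
## windows, and the end-to-end per-recording pipeline driver.

## time axis (ms) of an AverageWaveform
.waveTimes <- function(wf) {
  fs <- wf@sampleRate
  seq(round(wf@windowMs[1] * fs / 1000),
      round(wf@windowMs[2] * fs / 1000)) * 1000 / fs
}

## zero-phase Gaussian kernel smoothing with edge replication
gaussSmooth <- function(x, sigmaMs, fs) {
  if (sigmaMs <= 0) return(x)
  dt <- 1000 / fs
  half <- ceiling(4 * sigmaMs / dt)
  k <- stats::dnorm(seq(-half, half) * dt, 0, sigmaMs)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_along(x)]
}

## Most extreme interior local extremum of `x` within index range;
## falls back to the window-edge extremum (flagged) when none exists.
## Ties on value break to the earliest sample.
findPeak <- function(x, times, window, polarity) {
  sel <- which(times >= window[1] & times <= window[2])
  if (length(sel) < 3L)
    stop("detection window too narrow for the sampling rate")
  y <- x[sel] * polarity            # search for a maximum of polarity * x
  n <- length(y)
  interior <- 2:(n - 1L)
  isLoc <- y[interior] >= y[interior - 1L] & y[interior] >= y[interior + 1L] &
    (y[interior] > y[interior - 1L] | y[interior] > y[interior + 1L])
  cand <- interior[isLoc]
  fallback <- length(cand) == 0L
  if (fallback) cand <- c(1L, n)
  best <- cand[order(-y[cand], cand)][1L]      # most extreme, earliest on tie
  list(amplitude = abs(x[sel][best]),
       latency = times[sel][best],
       fallback = fallback)
}

#' Measure the six brain vital signs from condition-average waveforms
#'
#' N100 = most negative local extremum of the deviant-tone average inside its
#' window; P300 = most positive local extremum of the deviant-tone average;
#' N400 = most negative local extremum of the incongruent-minus-congruent
#' difference wave (or of the incongruent average alone when
#' `n400Mode = "incongruent"`). Amplitudes are reported as magnitudes (uV) at
#' the peak sample; latencies in ms at the peak sample, hence integer
#' multiples of the sample period (2 ms at 500 Hz). Windows without an
#' interior local extremum fall back to the window-edge extremum with the
#' `edgeFallback` flag set.
#'
#' @param waveforms list of [AverageWaveform-class] objects; must contain the
#'   deviant average at the N100 and P300 electrodes and (for the N400) the
#'   congruent and incongruent averages at the N400 electrode.
#' @param participantId,session identify the output set.
#' @param config a [pipelineConfig()] (windows, electrodes, `n400Mode`).
#' @param qc,rejectionFraction QC results from [qcParticipant()].
#' @param fluent when `FALSE` the N400 measures are withheld and the set is
#'   flagged `n400_missing_language`.
#' @return an [ErpMeasurementSet-class].
#' @export
measurePeaks <- function(waveforms, participantId = "unknown", session = 1L,
                         config = pipelineConfig(), qc = "included",
                         rejectionFraction = 0, fluent = TRUE) {
  tw <- config$templates
  getWave <- function(condition, electrode) {
    for (w in waveforms)
      if (w@condition == condition && w@electrode == electrode) return(w)
    NULL
  }
  m <- setNames(rep(NA_real_, 6L), bvsMeasures())
  fb <- setNames(rep(FALSE, 6L), bvsMeasures())

  pick <- function(comp, x, times, fs) {
    if (isTRUE(config$peakSmooth)) {
      ## latency from the matched-smoothed copy, amplitude from the raw
      ## average at that sample
      xs <- gaussSmooth(x, tw$widths[[comp]] / 2.3548, fs)
      p <- findPeak(xs, times, tw$windows[[comp]], tw$polarity[[comp]])
      p$amplitude <- abs(x[which(times == p$latency)[1L]])
      p
    } else {
      findPeak(x, times, tw$windows[[comp]], tw$polarity[[comp]])
    }
  }
  for (comp in c("n100", "p300")) {
    w <- getWave("deviant", tw$electrodes[[comp]])
    if (is.null(w)) next
    p <- pick(comp, w@samples, .waveTimes(w), w@sampleRate)
    m[paste0(comp, "_amplitude")] <- p$amplitude
    m[paste0(comp, "_latency")] <- p$latency
    fb[paste0(comp, "_amplitude")] <- fb[paste0(comp, "_latency")] <- p$fallback
  }
  if (fluent) {
    el <- tw$electrodes[["n400"]]
    inc <- getWave("incongruent", el)
    con <- getWave("congruent", el)
    x <- NULL
    if (!is.null(inc)) {
      x <- if (config$n400Mode == "difference") {
        if (!is.null(con)) inc@samples - con@samples else NULL
      } else inc@samples
    }
    if (!is.null(x)) {
      p <- pick("n400", x, .waveTimes(inc), inc@sampleRate)
      m["n400_amplitude"] <- p$amplitude
      m["n400_latency"] <- p$latency
      fb["n400_amplitude"] <- fb["n400_latency"] <- p$fallback
    }
  }
  if (!fluent && qc == "included") qc <- "n400_missing_language"
  if (qc == "excluded_quality") m[] <- NA_real_
  ErpMeasurementSet(participantId, session, m, qc = qc,
                    rejectionFraction = rejectionFraction, edgeFallback = fb)
}

#' Run the full extraction pipeline on one recording
#'
#' Chains band-pass filtering, adaptive ocular correction, epoch
#' segmentation with baseline correction, epoch-level wavelet denoising,
#' +/-75 uV rejection, participant QC and peak measurement. Each stage can
#' be disabled for diagnostic runs (a noiseless synthetic recording
#' round-trips exactly with `filter = FALSE, ocular = FALSE,
#' denoise = FALSE`).
#'
#' @param recording a [RawRecording-class] with markers.
#' @param participantId,session identify the output.
#' @param config a [pipelineConfig()].
#' @param filter,ocular,denoise enable/disable the cleaning stages.
#' @param fluent English-fluency flag (gates the N400).
#' @return an [ErpMeasurementSet-class]; `attr(, "epochs")` holds the
#'   [EpochSet-class] and `attr(, "waveforms")` the condition averages for
#'   plotting.
#' @export
processRecording <- function(recording, participantId = "unknown",
                             session = 1L, config = pipelineConfig(),
                             filter = TRUE, ocular = TRUE, denoise = TRUE,
                             fluent = TRUE) {
  rec <- recording
  if (filter)
    rec <- bandpassFilter(rec, config$filterBand[1], config$filterBand[2])
  if (ocular && "EOG" %in% channelNames(rec))
    rec <- removeOcularArtifacts(rec, order = config$nlmsOrder,
                                 mu = config$nlmsMu)
  eps <- segmentEpochs(rec, window = config$epochWindow,
                       baseline = config$baseline)
  if (denoise) eps <- denoiseEpochs(eps, level = config$waveletLevel)
  eps <- rejectEpochs(eps, threshold = config$rejectThreshold)
  q <- qcParticipant(eps, maxRejection = config$qcMaxRejection)

  tw <- config$templates
  wanted <- unique(rbind(
    data.frame(condition = "deviant", electrode = tw$electrodes[["n100"]]),
    data.frame(condition = "deviant", electrode = tw$electrodes[["p300"]]),
    data.frame(condition = "standard", electrode = tw$electrodes[["n100"]]),
    data.frame(condition = "congruent", electrode = tw$electrodes[["n400"]]),
    data.frame(condition = "incongruent", electrode = tw$electrodes[["n400"]])))
  waves <- list()
  for (i in seq_len(nrow(wanted))) {
    w <- tryCatch(averageCondition(eps, wanted$condition[i],
                                   wanted$electrode[i]),
                  error = function(e) NULL)
    if (!is.null(w)) waves[[length(waves) + 1L]] <- w
  }
  out <- measurePeaks(waves, participantId, session, config,
                      qc = q$qc, rejectionFraction = q$rejectionFraction,
                      fluent = fluent)
  attr(out, "epochs") <- eps
  attr(out, "waveforms") <- waves
  out
}
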