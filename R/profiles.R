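## Parameter bundles: ERP template definitions, pipeline configuration,
## per-participant ground-truth profiles, and noise model settings.

#' ERP component templates and detection windows
#'
#' Defines the three components as Gaussian-windowed deflections: polarity,
#' template width (full width at half maximum, ms), the detection window the
#' peak detector searches (ms post-stimulus), the measurement electrode, and
#' per-channel scalp weights. Weights are 1.0 on the measurement electrode so
#' that a noiseless synthetic recording round-trips exactly. Windows default
#' to ranges padded around the values observed in normative cohorts:
#' N100 \[70, 150\], P300 \[160, 450\], N400 \[280, 610\] ms.
#'
#' @param windows named list of `c(lo, hi)` ms detection windows.
#' @param electrodes named character: measurement electrode per component.
#' @param widths named numeric: template FWHM in ms.
#' @param weights 3x3 numeric matrix (components x Fz/Cz/Pz scalp weights).
#' @return list with class `"erpTemplates"`.
#' @export
erpTemplates <- function(windows = list(n100 = c(70, 150),
                                        p300 = c(160, 450),
                                        n400 = c(280, 610)),
                         electrodes = c(n100 = "Cz", p300 = "Pz", n400 = "Cz"),
                         widths = c(n100 = 50, p300 = 80, n400 = 100),
                         weights = NULL) {
  if (is.null(weights)) {
    weights <- rbind(n100 = c(Fz = 0.9, Cz = 1.0, Pz = 0.7),
                     p300 = c(Fz = 0.7, Cz = 0.9, Pz = 1.0),
                     n400 = c(Fz = 0.7, Cz = 1.0, Pz = 0.9))
  }
  comps <- c("n100", "p300", "n400")
  stopifnot(setequal(names(windows), comps),
            all(comps %in% names(electrodes)),
            all(comps %in% names(widths)),
            identical(rownames(weights), comps))
  for (w in windows) if (w[1] >= w[2] || w[1] < 0)
    stop("detection windows must be 0 <= lo < hi")
  structure(list(windows = windows, electrodes = electrodes,
                 widths = widths, weights = weights,
                 polarity = c(n100 = -1, p300 = +1, n400 = -1)),
            class = "erpTemplates")
}

#' Pipeline configuration
#'
#' All tunable parameters of the extraction pipeline in one place.
#'
#' @param filterBand band-pass edges in Hz (default 0.5-20).
#' @param epochWindow `c(pre, post)` epoch window in ms (pre < 0).
#' @param baseline `c(b0, b1)` baseline interval in ms.
#' @param rejectThreshold absolute amplitude rejection threshold in uV.
#' @param qcMaxRejection a participant-session is excluded when the fraction
#'   of rejected epochs strictly exceeds this (default 0.25).
#' @param nlmsOrder,nlmsMu adaptive ocular filter taps and step size.
#' @param waveletLevel DWT decomposition depth; `NULL` picks it from epoch
#'   length.
#' @param n400Mode `"difference"` (incongruent minus congruent, default) or
#'   `"incongruent"` (incongruent waveform alone).
#' @param peakSmooth estimate peak latencies on a copy of the average
#'   smoothed with a Gaussian kernel matched to the component template width
#'   (the amplitude is always read from the unsmoothed average at the chosen
#'   sample). Matched smoothing is the maximum-likelihood latency estimator
#'   for a known template in Gaussian noise and greatly stabilizes the broad
#'   P300/N400 peaks; disable for raw-argmax behavior.
#' @param templates an [erpTemplates()] bundle.
#' @return list with class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(filterBand = c(0.5, 20),
                           epochWindow = c(-100, 900),
                           baseline = c(-100, 0),
                           rejectThreshold = 75,
                           qcMaxRejection = 0.25,
                           nlmsOrder = 3, nlmsMu = 0.001,
                           waveletLevel = NULL,
                           n400Mode = c("difference", "incongruent"),
                           peakSmooth = TRUE,
                           templates = erpTemplates()) {
  n400Mode <- match.arg(n400Mode)
  stopifnot(length(filterBand) == 2L, filterBand[1] > 0,
            filterBand[1] < filterBand[2],
            epochWindow[1] < 0, epochWindow[2] > 0,
            baseline[1] >= epochWindow[1], baseline[2] <= epochWindow[2],
            rejectThreshold > 0)
  structure(list(filterBand = filterBand, epochWindow = epochWindow,
                 baseline = baseline, rejectThreshold = rejectThreshold,
                 qcMaxRejection = qcMaxRejection, nlmsOrder = nlmsOrder,
                 nlmsMu = nlmsMu, waveletLevel = waveletLevel,
                 n400Mode = n400Mode, peakSmooth = peakSmooth,
                 templates = templates),
            class = "pipelineConfig")
}

#' Participant ground-truth profile
#'
#' The true per-component amplitudes (uV, magnitudes), latencies (ms) and the
#' session-2 N400 habituation multiplier for one simulated participant.
#' Latencies must lie inside the template detection windows, otherwise the
#' ground truth would be unrecoverable by design.
#'
#' @param id participant label.
#' @param group `"A"` or `"B"`.
#' @param age years.
#' @param sex `"male"`, `"female"` or `"unspecified"`.
#' @param fluent English fluency flag (gates the N400 measures).
#' @param amplitudes named numeric `c(n100=, p300=, n400=)`, uV (> 0).
#' @param latencies named numeric `c(n100=, p300=, n400=)`, ms.
#' @param habituation session-2 N400 amplitude multiplier in `(0, 1]`.
#' @param templates the [erpTemplates()] defining the windows to validate
#'   against.
#' @return list with class `"participantProfile"`.
#' @export
participantProfile <- function(id, group = c("A", "B"), age = 16,
                               sex = c("male", "female", "unspecified"),
                               fluent = TRUE,
                               amplitudes = c(n100 = 9.5, p300 = 9.5, n400 = 6.3),
                               latencies = c(n100 = 110, p300 = 280, n400 = 438),
                               habituation = 1,
                               templates = erpTemplates()) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  comps <- c("n100", "p300", "n400")
  stopifnot(all(comps %in% names(amplitudes)), all(comps %in% names(latencies)))
  if (any(amplitudes[comps] <= 0))
    stop("amplitudes are magnitudes and must be > 0")
  if (habituation <= 0 || habituation > 1)
    stop("habituation factor must be in (0, 1]")
  for (cc in comps) {
    w <- templates$windows[[cc]]
    if (latencies[cc] < w[1] || latencies[cc] > w[2])
      stop(sprintf("%s latency %g ms outside its detection window [%g, %g]",
                   cc, latencies[cc], w[1], w[2]))
  }
  structure(list(id = as.character(id), group = group, age = age, sex = sex,
                 fluent = fluent, amplitudes = amplitudes[comps],
                 latencies = latencies[comps], habituation = habituation),
            class = "participantProfile")
}

#' Background-noise and blink-artifact settings
#'
#' Background noise is a mixture of 1/f-shaped ("pink") and white noise with
#' total standard deviation `sd`. Blinks are ~400 ms biphasic waveforms added
#' to the EOG channel at a Poisson rate and propagated onto the scalp
#' channels with fixed coefficients (strongest frontally).
#'
#' @param sd total background-noise SD per scalp channel, uV.
#' @param pinkFraction fraction of noise variance carried by the 1/f part.
#' @param blinkRate blinks per second (Poisson; 0 disables blinks).
#' @param blinkAmplitude peak blink amplitude on EOG, uV.
#' @param blinkPropagation named numeric: fraction of the EOG blink reaching
#'   each scalp channel.
#' @param eogNoiseSd noise floor on the EOG channel, uV.
#' @return list with class `"noiseConfig"`.
#' @export
noiseConfig <- function(sd = 10, pinkFraction = 0.8, blinkRate = 0.08,
                        blinkAmplitude = 120,
                        blinkPropagation = c(Fz = 0.35, Cz = 0.20, Pz = 0.10),
                        eogNoiseSd = 5) {
  stopifnot_scalar(sd, "sd", lower = 0)
  stopifnot_scalar(pinkFraction, "pinkFraction", 0, 1)
  stopifnot_scalar(blinkRate, "blinkRate", lower = 0)
  structure(list(sd = sd, pinkFraction = pinkFraction, blinkRate = blinkRate,
                 blinkAmplitude = blinkAmplitude,
                 blinkPropagation = blinkPropagation,
                 eogNoiseSd = eogNoiseSd),
            class = "noiseConfig")
}

#' Ground-truth measures implied by a profile at a given session
#'
#' @param profile a [participantProfile()].
#' @param session 1 or 2; session 2 applies the N400 habituation factor.
#' @return named numeric over [bvsMeasures()].
#' @export
profileTruth <- function(profile, session = 1L) {
  a <- profile$amplitudes
  l <- profile$latencies
  if (session >= 2L) a["n400"] <- a["n400"] * profile$habituation
  setNames(c(a["n100"], l["n100"], a["p300"], l["p300"], a["n400"], l["n400"]),
           bvsMeasures())
}
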