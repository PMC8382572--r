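## Forward model: turn stimulus sequences plus a participant profile into a
## continuous four-channel recording (Fz, Cz, Pz, EOG) with additive
## 1/f-shaped background noise and blink artifacts.

.scalpChannels <- c("Fz", "Cz", "Pz")
.allChannels <- c(.scalpChannels, "EOG")

## unit-SD 1/f-amplitude ("pink") noise via spectral shaping of white noise
pinkNoise <- function(n) {
  nfft <- 2L^ceiling(log2(max(n, 2L)))
  x <- rnorm(nfft)
  X <- stats::fft(x)
  f <- c(1, seq_len(nfft - 1L))          # avoid the DC singularity
  f <- pmin(f, nfft - f + 1)             # two-sided frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  (y - mean(y)) / sd(y)
}

## biphasic blink template: dominant positive lobe, small rebound; ~400 ms
blinkWave <- function(fs) {
  t <- seq(0, 0.45, by = 1 / fs)
  w <- exp(-(t - 0.15)^2 / (2 * 0.05^2)) - 0.25 * exp(-(t - 0.32)^2 / (2 * 0.08^2))
  w / max(w)
}

## Gaussian deflection, FWHM-parameterized, added in place
addTemplate <- function(sig, fs, onsetSec, latencyMs, amplitude, fwhmMs,
                        weights) {
  sigma <- fwhmMs / 2.3548 / 1000
  center <- onsetSec + latencyMs / 1000
  i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  i1 <- min(ncol(sig), ceiling((center + 4 * sigma) * fs) + 1L)
  if (i1 < i0) return(sig)
  tt <- (seq(i0, i1) - 1L) / fs
  g <- amplitude * exp(-(tt - center)^2 / (2 * sigma^2))
  for (ch in names(weights))
    sig[ch, i0:i1] <- sig[ch, i0:i1] + weights[[ch]] * g
  sig
}

#' Synthesize an event-related EEG recording
#'
#' Builds one participant-session recording from the forward model: deviant
#' tones add an N100 (negative) and a P300 (positive) template; standard
#' tones and word onsets add a scaled auditory N100; incongruent word targets
#' additionally add an N400 (negative) template — so the incongruent-minus-
#' congruent difference wave isolates the N400. Template latencies are
#' snapped to the sample grid so that a noiseless recording round-trips
#' through the pipeline exactly. Background noise and blinks are added per
#' [noiseConfig()].
#'
#' @param profile a [participantProfile()] carrying the ground truth.
#' @param tones a tone [StimulusSequence-class] (or `NULL`).
#' @param words a word-pair [StimulusSequence-class] (or `NULL`); appended
#'   after the tones with a `wordGap`-second pause.
#' @param noise a [noiseConfig()].
#' @param sampleRate Hz (default 500).
#' @param session 1 or 2; session 2 scales the N400 amplitude by the
#'   profile's habituation factor.
#' @param seed RNG seed for the noise/blink draws.
#' @param templates an [erpTemplates()] bundle.
#' @param standardScale N100 scaling for standard tones (relative to the
#'   deviant-tone N100).
#' @param wordScale N100 scaling for word onsets (primes and targets).
#' @param wordGap seconds between the last tone and the first word pair.
#' @return A [RawRecording-class]; `attr(, "truth")` holds the snapped
#'   ground-truth measures for this session.
#' @export
synthesizeRecording <- function(profile, tones, words = NULL,
                                noise = noiseConfig(), sampleRate = 500,
                                session = 1L, seed = NULL,
                                templates = erpTemplates(),
                                standardScale = 0.6, wordScale = 0.4,
                                wordGap = 2) {
  fs <- sampleRate
  if (fs <= 2 * 20)
    stop("sample rate must exceed twice the band-pass upper edge")
  ev <- if (is.null(tones)) NULL else events(tones)
  if (!is.null(words)) {
    wev <- events(words)
    off <- if (is.null(ev) || !nrow(ev)) 0 else max(ev$onset) + wordGap
    wev$onset <- wev$onset + off
    ev <- rbind(ev[, c("onset", "kind", "condition", "word")],
                wev[, c("onset", "kind", "condition", "word")])
  }
  if (is.null(ev) || !nrow(ev)) stop("no stimulus events supplied")
  ev$onset <- round(ev$onset * fs) / fs        # marker-to-sample alignment
  seq_all <- StimulusSequence(ev)

  dur <- max(ev$onset) + 1.2                   # covers the epoch post-window
  nsamp <- ceiling(dur * fs)
  sig <- matrix(0, nrow = length(.allChannels), ncol = nsamp,
                dimnames = list(.allChannels, NULL))

  amp <- profile$amplitudes
  if (session >= 2L) amp["n400"] <- amp["n400"] * profile$habituation
  lat <- round(profile$latencies * fs / 1000) / fs * 1000   # grid-align
  tw <- templates
  wts <- lapply(rownames(tw$weights),
                function(cc) as.list(tw$weights[cc, .scalpChannels]))
  names(wts) <- rownames(tw$weights)

  put <- function(sig, onset, comp, scale = 1) {
    addTemplate(sig, fs, onset, lat[comp],
                scale * tw$polarity[comp] * amp[comp], tw$widths[comp],
                wts[[comp]])
  }
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; on <- ev$onset[i]
    if (k == "deviant_tone") {
      sig <- put(sig, on, "n100")
      sig <- put(sig, on, "p300")
    } else if (k == "standard_tone") {
      sig <- put(sig, on, "n100", standardScale)
    } else if (k %in% c("word_prime", "word_target")) {
      sig <- put(sig, on, "n100", wordScale)
      if (k == "word_target" && ev$condition[i] == "incongruent")
        sig <- put(sig, on, "n400")
    }
  }

  withSeed(seed, {
    if (noise$sd > 0) {
      for (ch in .scalpChannels) {
        pf <- noise$pinkFraction
        sig[ch, ] <- sig[ch, ] + noise$sd *
          (sqrt(pf) * pinkNoise(nsamp) + sqrt(1 - pf) * rnorm(nsamp))
      }
    }
    if (noise$eogNoiseSd > 0)
      sig["EOG", ] <- sig["EOG", ] + noise$eogNoiseSd * rnorm(nsamp)
    if (noise$blinkRate > 0) {
      nBlink <- rpois(1, noise$blinkRate * dur)
      if (nBlink > 0) {
        bw <- blinkWave(fs) * noise$blinkAmplitude
        starts <- sort(floor(runif(nBlink, 0, nsamp - length(bw))))
        for (s in starts) {
          idx <- s + seq_along(bw)
          sig["EOG", idx] <- sig["EOG", idx] + bw
          for (ch in .scalpChannels)
            sig[ch, idx] <- sig[ch, idx] + noise$blinkPropagation[[ch]] * bw
        }
      }
    }
  })

  rec <- RawRecording(sig, sampleRate = fs, markers = seq_all)
  truth <- setNames(c(amp["n100"], lat["n100"], amp["p300"], lat["p300"],
                      amp["n400"], lat["n400"]), bvsMeasures())
  attr(rec, "truth") <- truth
  rec
}
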