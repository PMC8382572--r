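# Shared fixture builders. Everything is generated in code at test time.

# a standard ground-truth profile on the 2 ms grid
fixtureProfile <- function(id = "P1", ...) {
  participantProfile(id, "A",
                     amplitudes = c(n100 = 9.5, p300 = 9.5, n400 = 6.3),
                     latencies = c(n100 = 110, p300 = 280, n400 = 438), ...)
}

# small noiseless session: tones + word pairs, no noise, no blinks
noiselessRecording <- function(profile = fixtureProfile(), nTones = 40,
                               nPairs = 10, seed = 1) {
  tones <- generateToneSequence(nTones, 0.2, isi = 1, seed = seed)
  words <- generateWordPairSequence(nPairs, 0.5, seed = seed + 1)
  synthesizeRecording(profile, tones, words,
                      noise = noiseConfig(sd = 0, blinkRate = 0,
                                          eogNoiseSd = 0),
                      seed = seed + 2)
}

# an AverageWaveform over [-100, 900] ms at 500 Hz built from a function of
# time (ms)
waveFixture <- function(f, condition = "deviant", electrode = "Pz",
                        nEpochs = 10L) {
  t <- seq(-50, 450) * 2   # -100..900 ms in 2 ms steps
  new("AverageWaveform", condition = condition, electrode = electrode,
      samples = f(t), nEpochsIncluded = nEpochs, sampleRate = 500,
      windowMs = c(-100, 900))
}

gaussBump <- function(center, depth, fwhm = 30) {
  sigma <- fwhm / 2.3548
  function(t) depth * exp(-(t - center)^2 / (2 * sigma^2))
}

# an EpochSet built directly from a list of channels x samples matrices
epochSetFixture <- function(epochs, condition = rep("deviant", length(epochs)),
                            channels = c("Fz", "Cz", "Pz"), fs = 500,
                            window = c(-100, 900)) {
  epochs <- lapply(epochs, function(e) {
    rownames(e) <- channels
    e
  })
  new("EpochSet", epochs = epochs, condition = condition, sampleRate = fs,
      windowMs = window, baselineMs = c(-100, 0), channels = channels,
      rejected = rep(FALSE, length(epochs)),
      rejectionReason = rep(NA_character_, length(epochs)), nDropped = 0L)
}

# flat epoch with one sample set to `peak` on Cz
flatEpoch <- function(peak = 0, nChan = 3, nSamp = 501) {
  e <- matrix(0, nChan, nSamp)
  if (peak != 0) e[2, 250] <- peak
  e
}

# cheap wide table for the group-comparison tests
simWideTable <- function(seed = 1, nA = 52, nB = 135, diff = 0,
                         ageSlope = 0) {
  set.seed(seed)
  n <- nA + nB
  g <- c(rep("A", nA), rep("B", nB))
  age <- c(rnorm(nA, 16, 0.8), runif(nB, 8, 83))
  d <- data.frame(participant_id = sprintf("x%03d", 1:n), group = g,
                  age = age, sex = "unspecified", session = 1L)
  for (m in bvsMeasures())
    d[[m]] <- rnorm(n, 100, 10) + diff * (g == "B") + ageSlope * (age - 40)
  d
}
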