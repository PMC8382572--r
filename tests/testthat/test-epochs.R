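test_that("segmentation conserves counts, baselines to zero, and drops edge epochs", {
  rec <- noiselessRecording(nTones = 30, nPairs = 6)
  eps <- segmentEpochs(rec)
  expect_equal(sum(epochConditions(eps) == "deviant"),
               sum(events(markers(rec))$condition == "deviant"))
  # baseline means are zero per channel
  fs <- sampleRate(eps)
  bIdx <- 1:(round(100 * fs / 1000) + 1)
  for (e in eps@epochs[1:3])
    expect_lt(max(abs(rowMeans(e[, bIdx]))), 1e-9)

  # marker 50 ms before the end with a 900 ms post window is dropped
  x <- matrix(0, 4, 1000, dimnames = list(c("Fz", "Cz", "Pz", "EOG"), NULL))
  mk <- StimulusSequence(data.frame(onset = c(0.5, 1.95),
                                    kind = "deviant_tone",
                                    condition = "deviant"))
  short <- RawRecording(x, sampleRate = 500, markers = mk)
  expect_message(eps2 <- segmentEpochs(short), "dropped")
  expect_equal(nEpochs(eps2), 1)
  expect_equal(eps2@nDropped, 1L)
})

test_that("epochs are rejected exactly when a scalp sample exceeds the threshold", {
  eps <- epochSetFixture(list(flatEpoch(80), flatEpoch(74.9), flatEpoch(-80),
                              flatEpoch(0)))
  r <- rejectEpochs(eps, threshold = 75)
  expect_identical(isRejected(r), c(TRUE, FALSE, TRUE, FALSE))

  # an out-of-range EOG alone does not reject
  e <- matrix(0, 4, 501); e[4, 100] <- 200
  eps2 <- epochSetFixture(list(e), channels = c("Fz", "Cz", "Pz", "EOG"))
  expect_false(any(isRejected(rejectEpochs(eps2))))

  # engineered fixture: exactly 13 of 50 exceed
  set.seed(9)
  peaks <- c(rep(90, 13), rep(10, 37))[sample.int(50)]
  eps3 <- epochSetFixture(lapply(peaks, flatEpoch))
  expect_equal(sum(isRejected(rejectEpochs(eps3))), 13)
})

test_that("raising the threshold never increases the rejected count", {
  set.seed(10)
  eps <- epochSetFixture(lapply(runif(40, 0, 150), flatEpoch))
  prev <- Inf
  for (thr in c(50, 75, 100, 125)) {
    cnt <- sum(isRejected(rejectEpochs(eps, thr)))
    expect_lte(cnt, prev)
    prev <- cnt
  }
})

test_that("participant QC applies the strict >25% rule", {
  mk <- function(nBad, nTot) {
    eps <- epochSetFixture(lapply(c(rep(90, nBad), rep(0, nTot - nBad)),
                                  flatEpoch))
    qcParticipant(rejectEpochs(eps))
  }
  expect_identical(mk(13, 50)$qc, "excluded_quality")   # 26%
  expect_identical(mk(0, 50)$qc, "included")
  q25 <- mk(10, 40)                                      # exactly 25%
  expect_identical(q25$qc, "included")
  expect_equal(q25$rejectionFraction, 0.25)
  expect_error(qcParticipant(epochSetFixture(list())), "no epochs")
})

test_that("condition averaging is a pointwise mean over non-rejected epochs", {
  e1 <- matrix(1, 3, 501); e2 <- matrix(-1, 3, 501)
  eps <- epochSetFixture(list(e1, e1))
  av <- averageCondition(eps, "deviant", "Cz")
  expect_equal(av@samples, e1[2, ])
  expect_equal(av@nEpochsIncluded, 2L)

  av0 <- averageCondition(epochSetFixture(list(e1, e2)), "deviant", "Cz")
  expect_true(all(av0@samples == 0))

  # rejected epochs are excluded; zero usable epochs is an error
  eps2 <- epochSetFixture(list(e1, e2))
  eps2@rejected[2] <- TRUE
  expect_equal(averageCondition(eps2, "deviant", "Cz")@samples, e1[2, ])
  eps2@rejected[] <- TRUE
  expect_error(averageCondition(eps2, "deviant", "Cz"), "missing")

  # CLT bound: average of 100 noisy template epochs is close to the template
  set.seed(11)
  t <- seq(-100, 900, by = 2)
  tmpl <- 8 * exp(-(t - 300)^2 / (2 * 34^2))
  noisy <- lapply(1:100, function(i)
    rbind(tmpl, tmpl, tmpl) + matrix(rnorm(3 * 501, 0, 10), 3))
  avn <- averageCondition(epochSetFixture(noisy), "deviant", "Cz")
  frac <- mean(abs(avn@samples - tmpl) <= 3 * 10 / sqrt(100))
  expect_gte(frac, 0.99)
})
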