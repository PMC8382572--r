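test_that("cohort simulation is deterministic and reproduces the study margins", {
  a <- simulateCohort(seed = 61)
  b <- simulateCohort(seed = 61)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)

  m <- a$measurements
  ids <- unique(m$participant_id[m$group == "A"])
  expect_length(ids, 58)
  expect_length(unique(m$participant_id[m$group == "B"]), 135)

  dt <- descriptiveTable(m)
  cell <- function(g, s, meas) dt$n[dt$group == g & dt$session == s &
                                      dt$measure == meas]
  expect_equal(cell("A", 1, "n100_latency"), 52)   # 6 excluded for quality
  expect_equal(cell("A", 2, "n100_latency"), 46)   # retest subset
  expect_equal(cell("A", 1, "n400_amplitude"), 38) # non-fluent withheld
  expect_equal(cell("A", 2, "n400_amplitude"), 33)
  expect_equal(cell("B", 1, "n100_latency"), 134)  # one missing N100
  expect_equal(cell("B", 1, "p300_amplitude"), 135)

  # the truth table records every drawn value, including withheld ones
  expect_true(all(is.finite(a$truth$value)))
  expect_gt(sum(is.na(m$value)), 0)
})

test_that("quality exclusion is tied to the rejection fraction rule", {
  m <- simulateCohort(seed = 62)$measurements
  ex <- m$qc == "excluded_quality"
  expect_true(all(m$rejection_fraction[ex] > 0.25))
  expect_true(all(m$rejection_fraction[!ex] <= 0.25))
  expect_true(all(is.na(m$value[ex])))
})

test_that("perfect correlation without habituation gives identical sessions", {
  cfg <- cohortConfig(rho = setNames(rep(1, 6), bvsMeasures()),
                      habituation = 1)
  sim <- simulateCohort(cfg, seed = 63)
  w1 <- measuresWide(sim$truth, session = 1, dropExcluded = FALSE)
  w2 <- measuresWide(sim$truth, session = 2, dropExcluded = FALSE)
  common <- intersect(w1$participant_id[w1$group == "A"], w2$participant_id)
  i1 <- match(common, w1$participant_id); i2 <- match(common, w2$participant_id)
  for (m in bvsMeasures())
    expect_equal(w1[[m]][i1], w2[[m]][i2], tolerance = 1e-12)
})

test_that("simulated group-level moments converge to the configured ones", {
  cfg <- cohortConfig()
  sim <- simulateCohort(seed = 64)
  b <- sim$truth[sim$truth$group == "B", ]
  for (meas in c("n400_amplitude", "n100_latency", "p300_amplitude")) {
    v <- b$value[b$measure == meas]
    expect_lt(abs(mean(v) - cfg$meansB[[meas]]),
              3 * cfg$sdsB[[meas]] / sqrt(length(v)))
  }
})

test_that("a large paired cohort recovers the configured test-retest correlation", {
  cfg <- cohortConfig(nA = 500, nB = 2, retestN = 500, qualityExcludedA = 0,
                      fluentA = 500, missingN100B = 0,
                      rho = setNames(rep(0.7, 6), bvsMeasures()),
                      habituation = 1,
                      ageSlopes = setNames(rep(0, 6), bvsMeasures()))
  sim <- simulateCohort(cfg, seed = 65)
  w1 <- measuresWide(sim$measurements, session = 1)
  w2 <- measuresWide(sim$measurements, session = 2)
  i <- match(w2$participant_id, w1$participant_id)
  r <- iccAbsoluteSingle(w1$p300_amplitude[i], w2$p300_amplitude)
  expect_lt(abs(r$icc - 0.7), 0.05)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(cohortConfig(sdsA = setNames(c(-1, rep(1, 5)), bvsMeasures())),
               "SDs")
  expect_error(cohortConfig(rho = setNames(rep(1.2, 6), bvsMeasures())),
               "rho")
  expect_error(cohortConfig(habituation = 0), "habituation")
  expect_error(cohortConfig(retestN = 70), "subset")
})

test_that("cohort configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nA: 12", "nB: 20", "retestN: 10", "qualityExcludedA: 1",
               "fluentA: 10", "habituation: 0.9",
               "stimulus:", "  nTones: 40", "  isi: 0.5",
               "  deviantFraction: 0.2", "  nPairs: 8",
               "  congruentFraction: 0.5", "  soa: 0.9", "  pairPeriod: 2.2"),
             path)
  cfg <- readCohortConfig(path)
  expect_equal(cfg$nA, 12)
  expect_equal(cfg$habituation, 0.9)
  expect_equal(cfg$stimulus$nTones, 40)
  sim <- simulateCohort(cfg, seed = 66)
  expect_length(unique(sim$measurements$participant_id), 32)
})

test_that("recordings mode emits processable sessions whose truth matches the table", {
  cfg <- cohortConfig(nA = 2, nB = 1, retestN = 1, qualityExcludedA = 0,
                      fluentA = 2, missingN100B = 0,
                      stimulus = list(nTones = 60, isi = 0.5,
                                      deviantFraction = 0.2, nPairs = 10,
                                      congruentFraction = 0.5, soa = 0.9,
                                      pairPeriod = 2.2),
                      noise = noiseConfig(sd = 0, blinkRate = 0,
                                          eogNoiseSd = 0))
  sim <- simulateCohort(cfg, seed = 67, mode = "recordings")
  expect_length(sim$recordings, 4)  # 2 A sessions for one, 1 for other, 1 B
  r <- sim$recordings[[1]]
  m <- processRecording(r$recording, r$profile$id, r$session,
                        filter = FALSE, ocular = FALSE, denoise = FALSE)
  tr <- sim$truth
  want <- tr$value[tr$participant_id == r$profile$id &
                     tr$session == r$session]
  expect_equal(unname(measures(m)), want, tolerance = 1e-6)
})
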