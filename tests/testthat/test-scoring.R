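test_that("standardized scores honor the boundary rows and midpoint", {
  expect_equal(as.numeric(standardizeScore(10 + 4 * 2, "amplitude", 10, 2)), 100)
  expect_equal(as.numeric(standardizeScore(10 - 4 * 2, "amplitude", 10, 2)), 0)
  expect_equal(as.numeric(standardizeScore(10 + 4 * 2, "latency", 10, 2)), 0)
  expect_equal(as.numeric(standardizeScore(10 - 4 * 2, "latency", 10, 2)), 100)
  expect_equal(as.numeric(standardizeScore(10, "amplitude", 10, 2)), 50)
  expect_equal(as.numeric(standardizeScore(10, "latency", 10, 2)), 50)
  expect_error(standardizeScore(1, "amplitude", 0, 0), "sigma")
})

test_that("scores are monotone, symmetric and affine invariant", {
  mu <- 100; sigma <- 12
  xs <- seq(mu - 2.9 * sigma, mu + 2.9 * sigma, length.out = 41)
  amp <- as.numeric(standardizeScore(xs, "amplitude", mu, sigma))
  lat <- as.numeric(standardizeScore(xs, "latency", mu, sigma))
  expect_true(all(diff(amp) > 0))
  expect_true(all(diff(lat) < 0))
  for (d in c(0.5, 1, 2.5) * sigma) {
    for (kind in c("amplitude", "latency")) {
      s1 <- as.numeric(standardizeScore(mu + d, kind, mu, sigma))
      s2 <- as.numeric(standardizeScore(mu - d, kind, mu, sigma))
      expect_equal(s1 + s2, 100)
    }
  }
  # common positive rescaling of x, mu, sigma leaves the score unchanged
  for (f in c(0.1, 3, 1000))
    expect_equal(as.numeric(standardizeScore(f * 112, "latency", f * 100, f * 12)),
                 as.numeric(standardizeScore(112, "latency", 100, 12)))
})

test_that("references are sample mean/SD with n-1 over usable values", {
  tab <- data.frame(participant_id = c("a", "b", "c"), group = "B",
                    age = 30, sex = "female", session = 1,
                    measure = "n100_latency", value = c(100, 110, 120),
                    unit = "ms", qc = "included", rejection_fraction = 0)
  full <- do.call(rbind, lapply(bvsMeasures(), function(m) {
    t2 <- tab; t2$measure <- m; t2
  }))
  ref <- buildReference(full)
  s <- refStats(ref)
  expect_equal(s$mean[s$measure == "n100_latency"], 110)
  expect_equal(s$sd[s$measure == "n100_latency"], 10)
  expect_equal(s$n[s$measure == "n100_latency"], 3)

  one <- full[full$participant_id == "a", ]
  expect_error(buildReference(one), "at least 2")
})

test_that("a reference built from the simulated lifespan cohort matches its configuration", {
  sim <- simulateCohort(seed = 31)
  b <- sim$measurements[sim$measurements$group == "B", ]
  ref <- buildReference(b)
  s <- refStats(ref)
  cfg <- cohortConfig()
  for (m in c("n100_latency", "n400_amplitude")) {
    tol <- 3 * cfg$sdsB[[m]] / sqrt(s$n[s$measure == m])
    expect_lt(abs(s$mean[s$measure == m] - cfg$meansB[[m]]), tol)
  }
})

test_that("radar profiles standardize each axis locally", {
  s <- data.frame(measure = bvsMeasures(), mean = c(10, 100, 10, 300, 5, 450),
                  sd = c(2, 10, 2, 30, 1, 40), n = 100,
                  unit = unname(measureUnits()))
  ref <- ReferenceDistribution(s)
  atMean <- setNames(s$mean, bvsMeasures())
  pr <- radarProfile(atMean, ref, label = "mid")
  expect_true(all(scores(pr) == 50))

  shifted <- atMean
  shifted["p300_latency"] <- 300 + 3 * 30
  pr2 <- radarProfile(shifted, ref)
  expect_equal(scores(pr2)[["p300_latency"]], 0)
  expect_true(all(scores(pr2)[setdiff(bvsMeasures(), "p300_latency")] == 50))

  missing <- atMean; missing["n400_amplitude"] <- NA
  pr3 <- radarProfile(missing, ref)
  expect_true(is.na(scores(pr3)[["n400_amplitude"]]))
})

test_that("reference distributions survive CSV and JSON round trips", {
  sim <- simulateCohort(seed = 32)
  ref <- buildReference(sim$measurements[sim$measurements$group == "B", ])
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeReference(ref, path)
    back <- readReference(path)
    expect_equal(refStats(back)$mean, refStats(ref)$mean, tolerance = 1e-12)
    expect_equal(refStats(back)$sd, refStats(ref)$sd, tolerance = 1e-12)
  }
})
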