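test_that("descriptive cells follow their definitions", {
  tab <- do.call(rbind, lapply(bvsMeasures(), function(m)
    data.frame(participant_id = c("a", "b", "c"), group = "A", age = 16,
               sex = "male", session = 1, measure = m, value = c(2, 4, 6),
               unit = "uV", qc = "included", rejection_fraction = 0)))
  d <- descriptiveTable(tab)
  row <- d[d$measure == "n100_amplitude", ]
  expect_equal(row$n, 3)
  expect_equal(row$mean, 4)
  expect_equal(row$median, 4)
  expect_equal(row$range, 4)
  expect_equal(row$min, 2)
  expect_equal(row$max, 6)
  expect_equal(row$iqr, 2)   # type-7 quantiles: 75th = 5, 25th = 3
  expect_equal(row$sd, 2)
  expect_true(all(d$min <= d$median & d$median <= d$max))
})

test_that("radar coordinates place scores on six fixed axes", {
  ref <- ReferenceDistribution(data.frame(
    measure = bvsMeasures(), mean = c(10, 100, 10, 300, 5, 450),
    sd = c(2, 10, 2, 30, 1, 40), n = 100, unit = unname(measureUnits())))
  means <- setNames(c(10, 100, 10, 300, 5, 450), bvsMeasures())
  pr <- radarProfile(means, ref, label = "all-50")
  cc <- radarCoordinates(pr)
  expect_equal(nrow(cc), 6)
  radii <- sqrt(cc$x^2 + cc$y^2)
  expect_true(all(abs(radii - 50) < 1e-9))    # regular hexagon

  low <- means; low["n100_amplitude"] <- 10 - 3 * 2
  cc2 <- radarCoordinates(radarProfile(low, ref))
  r2 <- sqrt(cc2$x^2 + cc2$y^2)
  expect_equal(r2[cc2$measure == "n100_amplitude"], 0)  # touches the center
})

test_that("radar rendering overlays profiles and writes the coordinate CSV", {
  ref <- ReferenceDistribution(data.frame(
    measure = bvsMeasures(), mean = 10, sd = 2, n = 50,
    unit = unname(measureUnits())))
  p1 <- radarProfile(setNames(rep(10, 6), bvsMeasures()), ref, "t1")
  p2 <- radarProfile(setNames(rep(12, 6), bvsMeasures()), ref, "t2")
  out <- withr::local_tempfile(fileext = ".png")
  gg <- renderRadar(list(p1, p2), out)
  expect_true(file.exists(out))
  expect_true(file.exists(attr(gg, "csv")))
  built <- ggplot2::ggplot_build(gg)
  expect_equal(length(unique(built$data[[1]]$group)), 2)  # two polygons
})

test_that("violin and waveform figures render with their CSV records", {
  sim <- simulateCohort(seed = 71)
  out <- withr::local_tempfile(fileext = ".png")
  gg <- renderViolin(sim$measurements, out)
  expect_true(file.exists(out))
  csv <- attr(gg, "csv")
  expect_true(file.exists(csv))
  # deterministic CSV: re-render and compare bytes
  out2 <- withr::local_tempfile(fileext = ".png")
  renderViolin(sim$measurements, out2)
  expect_identical(readBin(csv, "raw", file.size(csv)),
                   readBin(sub("\\.png$", ".csv", out2), "raw",
                           file.size(csv)))

  # degenerate single-value cell still renders
  one <- sim$measurements[sim$measurements$participant_id ==
                            sim$measurements$participant_id[1], ]
  out3 <- withr::local_tempfile(fileext = ".png")
  expect_no_error(renderViolin(one, out3))

  # grand average over one participant equals that participant's average
  rec <- noiselessRecording(nTones = 20, nPairs = 4)
  mm <- processRecording(rec, filter = FALSE, ocular = FALSE, denoise = FALSE)
  wt <- waveformTable(attr(mm, "waveforms"))
  dev <- wt[wt$condition == "deviant" & wt$electrode == "Pz", ]
  avg <- averageCondition(attr(mm, "epochs"), "deviant", "Pz")
  expect_equal(dev$value, avg@samples)
  out4 <- withr::local_tempfile(fileext = ".png")
  expect_no_error(renderWaveforms(attr(mm, "waveforms"), out4))
})

test_that("the deviant-tone grand average shows the expected component polarities", {
  set.seed(72)
  p <- fixtureProfile()
  tones <- generateToneSequence(150, 0.2, isi = 0.5, seed = 73)
  rec <- synthesizeRecording(p, tones, noise = noiseConfig(sd = 6), seed = 74)
  mm <- processRecording(rec)
  wt <- waveformTable(attr(mm, "waveforms"))
  dev <- wt[wt$condition == "deviant" & wt$electrode == "Cz", ]
  n100win <- dev$value[dev$time_ms >= 70 & dev$time_ms <= 150]
  expect_lt(min(n100win), 0)                       # negative deflection
  devPz <- wt[wt$condition == "deviant" & wt$electrode == "Pz", ]
  p300win <- devPz$value[devPz$time_ms >= 160 & devPz$time_ms <= 450]
  expect_gt(max(p300win), 0)                       # positive deflection
})

test_that("recordings and measurement tables survive text round trips", {
  rec <- noiselessRecording(nTones = 10, nPairs = 2)
  dir <- withr::local_tempdir()
  paths <- writeRecording(rec, file.path(dir, "rec.csv"))
  back <- readRecording(file.path(dir, "rec.csv"))
  expect_equal(sampleRate(back), sampleRate(rec))
  expect_equal(unname(eegData(back)), unname(eegData(rec)),
               tolerance = 1e-12)
  expect_equal(events(markers(back))$kind, events(markers(rec))$kind)

  sim <- simulateCohort(seed = 75)
  mp <- file.path(dir, "measures.csv")
  writeMeasures(sim$measurements, mp)
  back2 <- readMeasures(mp)
  expect_equal(nrow(back2), nrow(sim$measurements))
  expect_equal(back2$value, sim$measurements$value, tolerance = 1e-12)
  expect_error(writeMeasures(data.frame(x = 1), mp), "lacks columns")

  mf <- file.path(dir, "manifest.json")
  writeRunManifest(mf, seed = 7, threshold = 75, band = c(0.5, 20))
  js <- jsonlite::read_json(mf)
  expect_equal(js$seed, 7)
  expect_equal(js$parameters$threshold, 75)
})
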