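## Cohort simulator: draws per-participant true measures for the two study
## groups (A: elite youth cohort, two sessions; B: lifespan reference cohort,
## one session) and emits either measurement tables directly ("table" mode)
## or full synthetic recordings ("recordings" mode).

.tbl2 <- function(mean, sd) c(mean = mean, sd = sd)

#' Cohort simulation configuration
#'
#' Defaults emulate the two study cohorts: Group A, n = 58 male adolescents
#' (age 16.24 +/- 0.76 y) scanned twice two days apart with 46 retested, 6
#' excluded for data quality at session 1 and 43 fluent English speakers;
#' Group B, n = 135 across the lifespan (ages 8-83, mean 40.62, sd 16.88),
#' scanned once, with one participant missing the N100 measures. Per-measure
#' population means/SDs default to the observed normative descriptives of
#' the two cohorts. Sessions are drawn bivariate-normal with per-measure
#' test-retest correlation `rho`; the session-2 N400 amplitude is scaled by
#' the habituation factor. Optional linear age slopes (units per year,
#' applied around each group's reference age) default to negative P300/N400
#' amplitude trends only.
#'
#' @param nA,nB group sizes.
#' @param ageA `c(mean, sd)` for Group A ages.
#' @param ageB `c(mean, sd, min, max)` for Group B ages (truncated normal).
#' @param meansA,sdsA,meansB,sdsB named numeric over [bvsMeasures()].
#' @param retestN number of Group A participants scanned twice.
#' @param qualityExcludedA Group A participants excluded at session 1
#'   (rejection fraction > 0.25).
#' @param fluentA number of fluent English speakers in Group A.
#' @param missingN100B Group B participants with missing N100 measures.
#' @param rho named per-measure test-retest correlation in `[-1, 1]`.
#' @param habituation session-2 N400 amplitude multiplier in `(0, 1]`.
#' @param ageSlopes named per-measure linear age slope (unit/year).
#' @param stimulus tone/word-pair sequence settings used in recordings mode.
#' @param noise a [noiseConfig()] used in recordings mode.
#' @return list with class `"cohortConfig"`.
#' @export
cohortConfig <- function(nA = 58, nB = 135,
                         ageA = c(mean = 16.24, sd = 0.76),
                         ageB = c(mean = 40.62, sd = 16.88, min = 8, max = 83),
                         meansA = c(n100_amplitude = 9.48, n100_latency = 109.46,
                                    p300_amplitude = 9.53, p300_latency = 279.04,
                                    n400_amplitude = 6.26, n400_latency = 438.26),
                         sdsA = c(n100_amplitude = 3.52, n100_latency = 15.44,
                                  p300_amplitude = 4.32, p300_latency = 38.78,
                                  n400_amplitude = 2.40, n400_latency = 58.95),
                         meansB = c(n100_amplitude = 9.98, n100_latency = 102.96,
                                    p300_amplitude = 10.14, p300_latency = 281.57,
                                    n400_amplitude = 4.99, n400_latency = 456.24),
                         sdsB = c(n100_amplitude = 4.28, n100_latency = 11.09,
                                  p300_amplitude = 4.38, p300_latency = 51.36,
                                  n400_amplitude = 2.28, n400_latency = 69.18),
                         retestN = 46, qualityExcludedA = 6, fluentA = 43,
                         missingN100B = 1,
                         rho = c(n100_amplitude = 0.60, n100_latency = 0.70,
                                 p300_amplitude = 0.60, p300_latency = 0.65,
                                 n400_amplitude = 0.45, n400_latency = 0.70),
                         habituation = 0.815,
                         ageSlopes = c(n100_amplitude = 0, n100_latency = 0,
                                       p300_amplitude = -0.05, p300_latency = 0,
                                       n400_amplitude = -0.04, n400_latency = 0),
                         stimulus = list(nTones = 600, isi = 0.5,
                                         deviantFraction = 0.2,
                                         nPairs = 60, congruentFraction = 0.5,
                                         soa = 0.9, pairPeriod = 2.2),
                         noise = noiseConfig()) {
  m <- bvsMeasures()
  for (v in list(meansA, sdsA, meansB, sdsB, rho, ageSlopes))
    if (!all(m %in% names(v)))
      stop("per-measure vectors must be named over bvsMeasures()")
  if (any(c(sdsA[m], sdsB[m]) <= 0)) stop("measure SDs must be > 0")
  if (any(abs(rho[m]) > 1)) stop("|rho| must be <= 1")
  if (habituation <= 0 || habituation > 1)
    stop("habituation factor must be in (0, 1]")
  if (retestN > nA || qualityExcludedA > nA || fluentA > nA)
    stop("Group A subset counts cannot exceed nA")
  structure(list(nA = nA, nB = nB, ageA = ageA, ageB = ageB,
                 meansA = meansA[m], sdsA = sdsA[m],
                 meansB = meansB[m], sdsB = sdsB[m],
                 retestN = retestN, qualityExcludedA = qualityExcludedA,
                 fluentA = fluentA, missingN100B = missingN100B,
                 rho = rho[m], habituation = habituation,
                 ageSlopes = ageSlopes[m], stimulus = stimulus, noise = noise),
            class = "cohortConfig")
}

#' Read a cohort configuration from YAML or JSON
#'
#' Top-level keys map onto the arguments of [cohortConfig()]; omitted keys
#' keep their defaults. Named numeric vectors are given as mappings.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `cohortConfig`.
#' @export
readCohortConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- list()
  fm <- formals(cohortConfig)
  for (k in names(raw)) {
    if (!k %in% names(fm)) stop("unknown cohort config key: ", k)
    v <- raw[[k]]
    args[[k]] <- if (is.list(v) && !k %in% c("stimulus", "noise"))
      unlist(v) else v
  }
  if ("noise" %in% names(args)) args$noise <- do.call(noiseConfig, args$noise)
  do.call(cohortConfig, args)
}

## truncated-normal draw by rejection (bounds far from the mean are cheap)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

## Draw the true measures for one group. Returns a list of per-participant
## rows: ages plus a 6 x nSessions matrix of true values.
.drawGroupTruth <- function(n, ages, means, sds, rho, slopes, refAge,
                            habituation, nSessions, templates) {
  m <- bvsMeasures()
  vals <- array(NA_real_, c(n, length(m), nSessions),
                dimnames = list(NULL, m, NULL))
  for (j in seq_along(m)) {
    r <- rho[m[j]]
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    base <- means[m[j]] + slopes[m[j]] * (ages - refAge)
    vals[, j, 1] <- base + sds[m[j]] * z1
    if (nSessions > 1) vals[, j, 2] <- base + sds[m[j]] * z2
  }
  if (nSessions > 1)
    vals[, "n400_amplitude", 2] <- vals[, "n400_amplitude", 2] * habituation
  ## keep truths physical and recoverable: amplitudes positive, latencies
  ## inside their detection windows
  win <- templates$windows
  winOf <- c(n100_latency = "n100", p300_latency = "p300", n400_latency = "n400")
  for (s in seq_len(nSessions)) {
    for (a in c("n100_amplitude", "p300_amplitude", "n400_amplitude"))
      vals[, a, s] <- pmax(vals[, a, s], 0.3)
    for (l in names(winOf)) {
      w <- win[[winOf[l]]]
      vals[, l, s] <- pmin(pmax(vals[, l, s], w[1] + 4), w[2] - 4)
    }
  }
  vals
}

#' Simulate a two-cohort brain vital signs study
#'
#' Draws ground-truth measures for both groups under [cohortConfig()] and
#' returns either the measurement tables directly (`mode = "table"`, cheap,
#' for statistics) or full synthetic recordings per participant-session
#' (`mode = "recordings"`, for end-to-end pipeline runs).
#'
#' In table mode the measurement table reproduces the study's missingness
#' structure: quality-excluded Group A participants (rejection fraction
#' > 0.25, values withheld), N400 withheld for non-fluent participants, and
#' missing N100 rows in Group B. The `truth` table always records every
#' drawn value.
#'
#' @param config a [cohortConfig()].
#' @param seed RNG seed.
#' @param mode `"table"` or `"recordings"`.
#' @param templates an [erpTemplates()] bundle.
#' @return list with elements `measurements` (long data.frame:
#'   participant_id, group, age, sex, session, measure, value, unit, qc,
#'   rejection_fraction; absent in recordings mode), `truth` (same shape,
#'   drawn true values), and in recordings mode `recordings` (list of
#'   `list(recording, profile, session)`).
#' @export
simulateCohort <- function(config = cohortConfig(), seed = NULL,
                           mode = c("table", "recordings"),
                           templates = erpTemplates()) {
  mode <- match.arg(mode)
  cfg <- config
  withSeed(seed, {
    idsA <- sprintf("A%02d", seq_len(cfg$nA))
    idsB <- sprintf("B%03d", seq_len(cfg$nB))
    agesA <- rtruncnorm(cfg$nA, cfg$ageA["mean"], cfg$ageA["sd"], 14, 19)
    agesB <- rtruncnorm(cfg$nB, cfg$ageB["mean"], cfg$ageB["sd"],
                        cfg$ageB["min"], cfg$ageB["max"])
    sexB <- sample(rep(c("male", "female"), length.out = cfg$nB))

    ## role assignment within Group A (retested / excluded / fluent), built
    ## so that the retested subset is drawn from the session-1 included set
    ## and the fluent counts match at both sessions
    perm <- sample.int(cfg$nA)
    nRe <- cfg$retestN; nEx <- cfg$qualityExcludedA
    nonFl <- cfg$nA - cfg$fluentA
    retested <- excluded <- fluent <- logical(cfg$nA)
    retested[perm[seq_len(nRe)]] <- TRUE
    excluded[perm[cfg$nA - seq_len(nEx) + 1L]] <- TRUE  # never retested
    ## spread non-fluency: one excluded and one included-only slot first,
    ## remainder among the retested (reproduces the default study margins:
    ## session-1 N400 n = 38, session-2 N400 n = 33)
    nfEx <- min(1L, nonFl, nEx)
    nfIncOnly <- min(1L, nonFl - nfEx, cfg$nA - nRe - nEx)
    nfRe <- min(nonFl - nfEx - nfIncOnly, nRe)
    nfIdx <- c(perm[seq_len(nfRe)],
               perm[nRe + seq_len(nfIncOnly)],
               perm[cfg$nA - seq_len(nfEx) + 1L])
    fluent[] <- TRUE; fluent[nfIdx] <- FALSE

    truthA <- .drawGroupTruth(cfg$nA, agesA, cfg$meansA, cfg$sdsA, cfg$rho,
                              cfg$ageSlopes, cfg$ageA["mean"],
                              cfg$habituation, 2L, templates)
    truthB <- .drawGroupTruth(cfg$nB, agesB, cfg$meansB, cfg$sdsB, cfg$rho,
                              cfg$ageSlopes, cfg$ageB["mean"],
                              cfg$habituation, 1L, templates)
    missN100 <- if (cfg$missingN100B > 0)
      sample.int(cfg$nB, cfg$missingN100B) else integer(0)

    rejFrac <- function(n, excluded) {
      excluded <- rep_len(excluded, n)
      ifelse(excluded, runif(n, 0.26, 0.45), runif(n, 0, 0.20))
    }
    rfA1 <- rejFrac(cfg$nA, excluded)
    rfA2 <- rejFrac(cfg$nA, FALSE)
    rfB <- rejFrac(cfg$nB, FALSE)

    longRow <- function(id, group, age, sex, session, vals, qc, rf) {
      data.frame(participant_id = id, group = group, age = age, sex = sex,
                 session = session, measure = bvsMeasures(),
                 value = as.numeric(vals), unit = unname(measureUnits()),
                 qc = qc, rejection_fraction = rf, stringsAsFactors = FALSE)
    }
    truth <- list(); meas <- list()
    for (i in seq_len(cfg$nA)) {
      for (s in 1:2) {
        if (s == 2L && !retested[i]) next
        v <- truthA[i, , s]
        qc <- if (s == 1L && excluded[i]) "excluded_quality"
              else if (!fluent[i]) "n400_missing_language" else "included"
        rf <- if (s == 1L) rfA1[i] else rfA2[i]
        truth[[length(truth) + 1L]] <-
          longRow(idsA[i], "A", agesA[i], "male", s, v, qc, rf)
        mv <- v
        if (qc == "excluded_quality") mv[] <- NA_real_
        if (!fluent[i]) mv[c("n400_amplitude", "n400_latency")] <- NA_real_
        meas[[length(meas) + 1L]] <-
          longRow(idsA[i], "A", agesA[i], "male", s, mv, qc, rf)
      }
    }
    for (i in seq_len(cfg$nB)) {
      v <- truthB[i, , 1]
      truth[[length(truth) + 1L]] <-
        longRow(idsB[i], "B", agesB[i], sexB[i], 1L, v, "included", rfB[i])
      mv <- v
      if (i %in% missN100) mv[c("n100_amplitude", "n100_latency")] <- NA_real_
      meas[[length(meas) + 1L]] <-
        longRow(idsB[i], "B", agesB[i], sexB[i], 1L, mv, "included", rfB[i])
    }
    truth <- do.call(rbind, truth)
    meas <- do.call(rbind, meas)

    if (mode == "table")
      return(list(measurements = meas, truth = truth))

    ## recordings mode: synthesize waveforms whose templates carry the drawn
    ## truths (latencies snap to the sample grid; the truth table is updated
    ## to the snapped values via attr(recording, "truth"))
    recs <- list()
    st <- cfg$stimulus
    mkProfile <- function(id, group, age, sex, fl, v)
      participantProfile(id, group, age, sex, fluent = fl,
                         amplitudes = c(n100 = unname(v["n100_amplitude"]),
                                        p300 = unname(v["p300_amplitude"]),
                                        n400 = unname(v["n400_amplitude"])),
                         latencies = c(n100 = unname(v["n100_latency"]),
                                       p300 = unname(v["p300_latency"]),
                                       n400 = unname(v["n400_latency"])),
                         habituation = 1, templates = templates)
    synthOne <- function(profile, session, seed2) {
      tones <- generateToneSequence(st$nTones, st$deviantFraction, st$isi,
                                    seed = seed2)
      words <- generateWordPairSequence(st$nPairs, st$congruentFraction,
                                        seed = seed2 + 1L,
                                        soa = st$soa, pairPeriod = st$pairPeriod)
      synthesizeRecording(profile, tones, words, noise = cfg$noise,
                          session = 1L, seed = seed2 + 2L,
                          templates = templates)
    }
    drawSeed <- function() as.integer(floor(runif(1, 1, 2^30)))
    for (i in seq_len(cfg$nA)) {
      for (s in 1:2) {
        if (s == 2L && !retested[i]) next
        p <- mkProfile(idsA[i], "A", agesA[i], "male", fluent[i], truthA[i, , s])
        rec <- synthOne(p, s, drawSeed())
        sel <- truth$participant_id == idsA[i] & truth$session == s
        truth$value[sel] <- as.numeric(attr(rec, "truth"))
        recs[[length(recs) + 1L]] <-
          list(recording = rec, profile = p, session = s)
      }
    }
    for (i in seq_len(cfg$nB)) {
      p <- mkProfile(idsB[i], "B", agesB[i], sexB[i], TRUE, truthB[i, , 1])
      rec <- synthOne(p, 1L, drawSeed())
      sel <- truth$participant_id == idsB[i]
      truth$value[sel] <- as.numeric(attr(rec, "truth"))
      recs[[length(recs) + 1L]] <-
        list(recording = rec, profile = p, session = 1L)
    }
    list(recordings = recs, truth = truth)
  })
}

#' Pivot a long measurement table to one row per participant-session
#'
#' @param measurements long table as emitted by [simulateCohort()] or
#'   [readMeasures()].
#' @param session keep only this session (`NULL` keeps all).
#' @param dropExcluded drop `excluded_quality` rows (default TRUE).
#' @return wide data.frame with columns participant_id, group, age, sex,
#'   session and the six measures.
#' @export
measuresWide <- function(measurements, session = NULL, dropExcluded = TRUE) {
  d <- measurements
  if (!is.null(session)) d <- d[d$session %in% session, ]
  if (dropExcluded && "qc" %in% names(d)) d <- d[d$qc != "excluded_quality", ]
  key <- interaction(d$participant_id, d$session, drop = TRUE)
  first <- !duplicated(key)
  out <- d[first, c("participant_id", "group", "age", "sex", "session")]
  for (m in bvsMeasures())
    out[[m]] <- d$value[d$measure == m][match(key[first],
                                              key[d$measure == m])]
  rownames(out) <- NULL
  out
}
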