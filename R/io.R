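## Plain-text serialization: recordings as a columnar CSV plus a marker
## sidecar, measurement sets as the long-format CSV dialect shared by the
## whole package, and a JSON run manifest for reproducibility.

#' Write / read a recording as delimited text
#'
#' The data file has one column per channel (uV) and a leading
#' `# sample_rate_hz:` comment; the marker sidecar has columns
#' `onset_sample`, `kind`, `condition`, `word`.
#'
#' @param recording a [RawRecording-class].
#' @param dataPath CSV path for the samples.
#' @param markerPath CSV path for the markers (default: derived from
#'   `dataPath` by appending `_markers`).
#' @return `writeRecording`: paths, invisibly. `readRecording`: a
#'   [RawRecording-class].
#' @export
writeRecording <- function(recording, dataPath,
                           markerPath = sub("(\\.[A-Za-z]+)?$",
                                            "_markers.csv", dataPath)) {
  con <- file(dataPath, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", sampleRate(recording)), con)
  write.csv(as.data.frame(t(eegData(recording))), con, row.names = FALSE)
  ev <- events(markers(recording))
  ev$onset_sample <- round(ev$onset * sampleRate(recording))
  write.csv(ev[, c("onset_sample", "kind", "condition", "word")], markerPath,
            row.names = FALSE)
  invisible(c(data = dataPath, markers = markerPath))
}

#' @rdname writeRecording
#' @export
readRecording <- function(dataPath,
                          markerPath = sub("(\\.[A-Za-z]+)?$",
                                           "_markers.csv", dataPath)) {
  first <- readLines(dataPath, n = 1L)
  fs <- as.numeric(sub(".*sample_rate_hz:\\s*", "", first))
  if (!is.finite(fs)) stop("data file lacks the sample_rate_hz header")
  d <- read.csv(dataPath, comment.char = "#", check.names = FALSE)
  ev <- read.csv(markerPath, stringsAsFactors = FALSE)
  ev$onset <- ev$onset_sample / fs
  RawRecording(t(as.matrix(d)), sampleRate = fs,
               markers = StimulusSequence(
                 ev[, c("onset", "kind", "condition", "word")]))
}

#' Convert ErpMeasurementSet objects to the long table dialect
#'
#' @param sets list of [ErpMeasurementSet-class] objects.
#' @param meta optional data.frame keyed by `participant_id` carrying
#'   `group`, `age`, `sex` (defaults to NA).
#' @return long data.frame: participant_id, group, age, sex, session,
#'   measure, value, unit, qc, rejection_fraction.
#' @export
measurementsToLong <- function(sets, meta = NULL) {
  rows <- lapply(sets, function(s) {
    info <- list(group = NA_character_, age = NA_real_, sex = NA_character_)
    if (!is.null(meta)) {
      hit <- meta[meta$participant_id == s@participantId, , drop = FALSE]
      if (nrow(hit))
        for (k in intersect(names(info), names(hit))) info[[k]] <- hit[[k]][1]
    }
    data.frame(participant_id = s@participantId, group = info$group,
               age = info$age, sex = info$sex, session = s@session,
               measure = bvsMeasures(), value = as.numeric(s@measures),
               unit = unname(measureUnits()), qc = s@qc,
               rejection_fraction = s@rejectionFraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a long measurement table
#'
#' Fixed header: participant_id, group, age, sex, session, measure, value,
#' unit (plus qc and rejection_fraction when present).
#'
#' @param measurements long data.frame.
#' @param path CSV path.
#' @return `writeMeasures`: the path, invisibly. `readMeasures`: the table.
#' @export
writeMeasures <- function(measurements, path) {
  need <- c("participant_id", "group", "age", "sex", "session", "measure",
            "value", "unit")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasures
#' @export
readMeasures <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "age", "sex", "session", "measure",
            "value", "unit")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("measurement file lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Write a JSON run manifest
#'
#' Records the package version, timestamp, seed and any parameters passed,
#' so a processing run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param seed the seed used (or `NULL`).
#' @param ... named parameters to record.
#' @return the path, invisibly.
#' @export
writeRunManifest <- function(path, seed = NULL, ...) {
  manifest <- list(package = "brainvitals",
                   version = as.character(packageVersion("brainvitals")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   r_version = R.version.string,
                   seed = seed, parameters = list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
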