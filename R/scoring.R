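## Standardized 0-100 scoring of the six measures against a reference
## distribution: z-value against the reference mean/SD, linearly mapped so
## that mu - 3*sigma .. mu + 3*sigma spans the scale, clipped at the ends.
## Larger amplitudes and faster (smaller) latencies score higher.

#' Build a reference distribution from a measurement collection
#'
#' Per-measure sample mean, sample SD (denominator n-1) and n over included,
#' non-missing values; `excluded_quality` rows are not used.
#'
#' @param measurements long measurement table (see [simulateCohort()]), or a
#'   list of [ErpMeasurementSet-class] objects.
#' @return a [ReferenceDistribution-class].
#' @export
buildReference <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- measurementsToLong(measurements)
  d <- measurements
  if ("qc" %in% names(d)) d <- d[d$qc != "excluded_quality", ]
  units <- measureUnits()
  rows <- lapply(bvsMeasures(), function(m) {
    v <- d$value[d$measure == m]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop(sprintf("need at least 2 values to build a reference for %s", m))
    data.frame(measure = m, mean = mean(v), sd = sd(v), n = length(v),
               unit = unname(units[m]), stringsAsFactors = FALSE)
  })
  ReferenceDistribution(do.call(rbind, rows))
}

#' Standardize one measurement to a 0-100 score
#'
#' Amplitude scores increase with the measurement,
#' `100 * clip((x - (mu - 3 sigma)) / (6 sigma), 0, 1)`; latency scores
#' decrease, `100 * clip(((mu + 3 sigma) - x) / (6 sigma), 0, 1)`. Hence an
#' amplitude more than three reference SDs above the mean scores 100, a
#' latency more than three SDs above the mean scores 0, and `x = mu` scores
#' 50 for either kind.
#'
#' @param x the measurement (uV or ms).
#' @param kind `"amplitude"` or `"latency"`.
#' @param mu,sigma reference mean and SD (`sigma > 0`).
#' @return the score in `[0, 100]`; `attr(, "z")` carries the z-value.
#' @export
#' @examples
#' standardizeScore(14, "amplitude", mu = 10, sigma = 1)   # 100
#' standardizeScore(10, "latency", mu = 10, sigma = 2)     # 50
standardizeScore <- function(x, kind = c("amplitude", "latency"), mu, sigma) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("sigma must be > 0")
  z <- (x - mu) / sigma
  frac <- if (kind == "amplitude") (z + 3) / 6 else (3 - z) / 6
  score <- 100 * pmin(pmax(frac, 0), 1)
  attr(score, "z") <- z
  score
}

#' Standardize a measurement set into a radar profile
#'
#' Applies [standardizeScore()] to each of the six measures against the
#' reference; missing measures yield missing scores (rendered as gaps).
#'
#' @param measures an [ErpMeasurementSet-class] or a named numeric vector
#'   over [bvsMeasures()].
#' @param reference a [ReferenceDistribution-class] covering all six
#'   measures.
#' @param label profile label for plotting.
#' @return a [StandardizedProfile-class].
#' @export
radarProfile <- function(measures, reference, label = "") {
  v <- if (is(measures, "ErpMeasurementSet")) measures(measures) else
    measures[bvsMeasures()]
  s <- refStats(reference)
  if (!all(bvsMeasures() %in% s$measure))
    stop("reference must cover all six measures")
  kinds <- measureKinds()
  sc <- z <- setNames(rep(NA_real_, 6L), bvsMeasures())
  for (m in bvsMeasures()) {
    if (!is.finite(v[m])) next
    row <- s[s$measure == m, ]
    r <- standardizeScore(v[[m]], kinds[[m]], row$mean, row$sd)
    sc[m] <- as.numeric(r)
    z[m] <- attr(r, "z")
  }
  new("StandardizedProfile", scores = sc, z = z, label = label)
}

#' Serialize / read a reference distribution
#'
#' CSV (columns measure, mean, sd, n, unit) or JSON, chosen by extension.
#'
#' @param reference a [ReferenceDistribution-class].
#' @param path output path (`.csv` or `.json`).
#' @return `writeReference`: the path, invisibly. `readReference`: a
#'   [ReferenceDistribution-class].
#' @export
writeReference <- function(reference, path) {
  s <- refStats(reference)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(s, path, dataframe = "rows", digits = NA)
  else write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReference
#' @export
readReference <- function(path) {
  s <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else read.csv(path, stringsAsFactors = FALSE)
  ReferenceDistribution(s)
}
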