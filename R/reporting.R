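## Reporting: descriptive statistics, radar / violin / waveform figures.
## Every figure's numeric content is also written as CSV — figures are
## views, never the only record.

#' Descriptive statistics per group, session and measure
#'
#' n, mean, SD (n-1), median, IQR (75th - 25th percentile, linear
#' interpolation), range, min and max per group-session-measure cell.
#' Empty cells are omitted with a message.
#'
#' @param measurements long measurement table; `excluded_quality` rows are
#'   dropped.
#' @return data.frame, one row per cell.
#' @export
descriptiveTable <- function(measurements) {
  d <- measurements
  if ("qc" %in% names(d)) d <- d[d$qc != "excluded_quality", ]
  cells <- unique(d[, c("group", "session")])
  cells <- cells[order(cells$group, cells$session), ]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    for (m in bvsMeasures()) {
      v <- d$value[d$group == cells$group[i] & d$session == cells$session[i] &
                     d$measure == m]
      v <- v[is.finite(v)]
      if (!length(v)) {
        message(sprintf("empty cell: group %s session %s %s — omitted",
                        cells$group[i], cells$session[i], m))
        next
      }
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = cells$group[i], session = cells$session[i], measure = m,
        n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA,
        median = q[2], iqr = q[3] - q[1], range = max(v) - min(v),
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cartesian polygon coordinates of a radar profile
#'
#' The six axes in [bvsMeasures()] order, clockwise from the top; scores on
#' `[0, 100]` map to radius. Missing scores become `NA` coordinates (gaps).
#'
#' @param profile a [StandardizedProfile-class].
#' @return data.frame: measure, score, angle (radians), x, y.
#' @export
radarCoordinates <- function(profile) {
  sc <- scores(profile)
  k <- length(sc)
  angle <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k   # clockwise from top
  data.frame(measure = names(sc), score = unname(sc), angle = angle,
             x = unname(sc) * cos(angle), y = unname(sc) * sin(angle),
             stringsAsFactors = FALSE)
}

.writeFigureCsv <- function(df, out) {
  csv <- sub("\\.[A-Za-z]+$", ".csv", out)
  if (identical(csv, out)) csv <- paste0(out, ".csv")
  write.csv(df, csv, row.names = FALSE)
  csv
}

#' Render one or more radar profiles
#'
#' Closed polygons over the six standardized axes; multiple profiles
#' overlay. The polygon coordinates are also written as a CSV next to the
#' image.
#'
#' @param profiles a [StandardizedProfile-class] or list of them.
#' @param out image path (`.png`/`.pdf`); `NULL` skips writing.
#' @param width,height inches.
#' @return the ggplot object, invisibly; `attr(, "csv")` is the CSV path
#'   when written.
#' @export
renderRadar <- function(profiles, out = NULL, width = 5, height = 5) {
  if (is(profiles, "StandardizedProfile")) profiles <- list(profiles)
  coords <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    cc <- radarCoordinates(profiles[[i]])
    lb <- profiles[[i]]@label
    cc$profile <- if (length(lb) && nzchar(lb)) lb else paste0("profile", i)
    cc
  }))
  closed <- do.call(rbind, lapply(split(coords, coords$profile),
                                  function(d) rbind(d, d[1, ])))
  gg <- ggplot2::ggplot(closed,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$profile,
                                     colour = .data$profile)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(-110, 110), ylim = c(-110, 110)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Brain vital signs profile (0-100)",
                  x = NULL, y = NULL)
  if (!is.null(out)) {
    ggplot2::ggsave(out, gg, width = width, height = height, dpi = 150)
    attr(gg, "csv") <- .writeFigureCsv(coords, out)
  }
  invisible(gg)
}

#' Render violin plots of measure distributions
#'
#' One violin per group-session within each measure panel, with mean /
#' min / max hashes. The plotted values are also written as CSV.
#'
#' @param measurements long measurement table.
#' @param out image path or `NULL`.
#' @param width,height inches.
#' @return the ggplot object, invisibly.
#' @export
renderViolin <- function(measurements, out = NULL, width = 8, height = 6) {
  d <- measurements
  if ("qc" %in% names(d)) d <- d[d$qc != "excluded_quality", ]
  d <- d[is.finite(d$value), ]
  d$cell <- paste0(d$group, "-T", d$session)
  singles <- stats::ave(d$value, d$cell, d$measure, FUN = length) == 1
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$value,
                                        fill = .data$cell)) +
    ggplot2::geom_violin(data = d[!singles, ], scale = "width", trim = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95, size = 6) +
    ggplot2::stat_summary(fun = min, geom = "point", shape = 95, size = 4) +
    ggplot2::stat_summary(fun = max, geom = "point", shape = 95, size = 4) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = "value")
  if (!is.null(out)) {
    ggplot2::ggsave(out, gg, width = width, height = height, dpi = 150)
    attr(gg, "csv") <- .writeFigureCsv(
      d[, c("group", "session", "measure", "value")], out)
  }
  invisible(gg)
}

#' Average waveforms as a long data.frame
#'
#' @param waveforms list of [AverageWaveform-class] objects (e.g. from
#'   `attr(processRecording(...), "waveforms")`).
#' @return data.frame: condition, electrode, time_ms, value, n_epochs.
#' @export
waveformTable <- function(waveforms) {
  do.call(rbind, lapply(waveforms, function(w) {
    data.frame(condition = w@condition, electrode = w@electrode,
               time_ms = .waveTimes(w), value = w@samples,
               n_epochs = w@nEpochsIncluded, stringsAsFactors = FALSE)
  }))
}

#' Render condition-average (or grand-average) waveform overlays
#'
#' Overlays the condition averages per electrode with a stimulus-onset
#' marker at 0 ms; the plotted arrays are also written as CSV.
#'
#' @param waveforms list of [AverageWaveform-class] objects or a data.frame
#'   from [waveformTable()].
#' @param out image path or `NULL`.
#' @param width,height inches.
#' @return the ggplot object, invisibly.
#' @export
renderWaveforms <- function(waveforms, out = NULL, width = 8, height = 5) {
  d <- if (is.data.frame(waveforms)) waveforms else waveformTable(waveforms)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                        colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~electrode, ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)")
  if (!is.null(out)) {
    ggplot2::ggsave(out, gg, width = width, height = height, dpi = 150)
    attr(gg, "csv") <- .writeFigureCsv(d, out)
  }
  invisible(gg)
}
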