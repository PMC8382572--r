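## Test-retest reliability, implemented from mean squares: one-way ANOVA
## across sessions, Cronbach's alpha (k = 2 items), and the single-measures
## absolute-agreement intraclass correlation ICC(A,1) with its F-based
## confidence interval and p-value (McGraw & Wong convention).

## listwise-complete session pairs
completePairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' One-way ANOVA between two sessions
#'
#' Treats session 1 and session 2 as two independent groups:
#' `F = MS_between / MS_within` with df `(1, 2n - 2)`. (The paired design
#' makes this a conservative between-sessions comparison; it mirrors how
#' retest tables are conventionally reported.)
#'
#' @param x,y session-1 and session-2 values (pairs with a missing side are
#'   dropped listwise).
#' @return list with `F`, `p`, `df` (length 2), `n`. A degenerate
#'   zero-variance split yields `F = NA` (flagged via `degenerate`).
#' @export
anovaOneWay <- function(x, y) {
  p <- completePairs(x, y)
  if (p$n < 2L) stop("need at least 2 complete pairs")
  g <- c(p$x, p$y)
  grand <- mean(g)
  msb <- p$n * ((mean(p$x) - grand)^2 + (mean(p$y) - grand)^2) / 1
  msw <- (sum((p$x - mean(p$x))^2) + sum((p$y - mean(p$y))^2)) / (2 * p$n - 2)
  if (msw == 0) {
    degenerate <- TRUE
    Fv <- if (msb == 0) NA_real_ else Inf
    pv <- if (msb == 0) NA_real_ else 0
  } else {
    degenerate <- FALSE
    Fv <- msb / msw
    pv <- pf(Fv, 1, 2 * p$n - 2, lower.tail = FALSE)
  }
  list(F = Fv, p = pv, df = c(1, 2 * p$n - 2), n = p$n,
       degenerate = degenerate)
}

#' Cronbach's alpha for two repeated measurements
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with `k = 2`, item
#' variances and the variance of the summed score computed with denominator
#' `n - 1`.
#'
#' @inheritParams anovaOneWay
#' @return the alpha coefficient (`NA` when the total variance is zero).
#' @export
cronbachAlpha <- function(x, y) {
  p <- completePairs(x, y)
  if (p$n < 2L) stop("need at least 2 complete pairs")
  vtot <- var(p$x + p$y)
  if (vtot == 0) return(NA_real_)
  2 * (1 - (var(p$x) + var(p$y)) / vtot)
}

#' ICC(A,1): two-way, single measures, absolute agreement
#'
#' From the two-way subjects x sessions mean squares (`MS_R` rows, `MS_C`
#' columns, `MS_E` error):
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`,
#' with `k = 2` sessions. The confidence interval uses the F-based
#' absolute-agreement procedure with Satterthwaite degrees of freedom; the
#' p-value tests ICC = 0 via `F = MS_R / MS_E` on `(n-1, (n-1)(k-1))` df.
#' The same arithmetic applies whether sessions are modeled as fixed
#' ("two-way mixed") or random; the distinction affects interpretation only.
#'
#' @inheritParams anovaOneWay
#' @param ciLevel confidence level (default 0.95).
#' @return list with `icc`, `ciLow`, `ciHigh`, `p`, `F`, the mean squares
#'   and `n`.
#' @export
iccAbsoluteSingle <- function(x, y, ciLevel = 0.95) {
  pr <- completePairs(x, y)
  n <- pr$n
  if (n < 3L) stop("need at least 3 complete pairs")
  k <- 2
  dat <- cbind(pr$x, pr$y)
  rowM <- rowMeans(dat); colM <- colMeans(dat); grand <- mean(dat)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || !is.finite(denom))
    return(list(icc = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                p = NA_real_, F = NA_real_, msr = msr, msc = msc, mse = mse,
                n = n, degenerate = TRUE))
  icc <- (msr - mse) / denom

  alpha <- 1 - ciLevel
  ## Satterthwaite df for the column/error mixture in the CI bound
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fL <- qf(1 - alpha / 2, n - 1, v)
  fU <- qf(1 - alpha / 2, v, n - 1)
  ciLow <- n * (msr - fL * mse) /
    (fL * (k * msc + (k * n - k - n) * mse) + n * msr)
  ciHigh <- n * (fU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fU * msr)

  if (mse > 0) {
    Fv <- msr / mse
    pv <- pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    Fv <- Inf; pv <- 0
  }
  list(icc = icc, ciLow = ciLow, ciHigh = ciHigh, p = pv, F = Fv,
       msr = msr, msc = msc, mse = mse, n = n, degenerate = FALSE)
}

#' Test-retest reliability table over all six measures
#'
#' Computes [anovaOneWay()], [cronbachAlpha()] and [iccAbsoluteSingle()] per
#' measure from a long measurement table containing sessions 1 and 2
#' (listwise-complete pairs per measure; `excluded_quality` rows dropped).
#'
#' @param measurements long measurement table.
#' @param ciLevel ICC confidence level.
#' @return data.frame, one row per measure: n, anova_F, anova_p,
#'   cronbach_alpha, icc, icc_ci_low, icc_ci_high, icc_p.
#' @export
reliabilityTable <- function(measurements, ciLevel = 0.95) {
  w1 <- measuresWide(measurements, session = 1)
  w2 <- measuresWide(measurements, session = 2)
  common <- intersect(w1$participant_id, w2$participant_id)
  rows <- lapply(bvsMeasures(), function(m) {
    x <- w1[[m]][match(common, w1$participant_id)]
    y <- w2[[m]][match(common, w2$participant_id)]
    pr <- completePairs(x, y)
    a <- anovaOneWay(pr$x, pr$y)
    icc <- iccAbsoluteSingle(pr$x, pr$y, ciLevel = ciLevel)
    data.frame(measure = m, n = pr$n, anova_F = a$F, anova_p = a$p,
               cronbach_alpha = cronbachAlpha(pr$x, pr$y),
               icc = icc$icc, icc_ci_low = icc$ciLow,
               icc_ci_high = icc$ciHigh, icc_p = icc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
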