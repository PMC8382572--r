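## Group comparison with age as covariate: MANCOVA (Wilks' lambda from
## hypothesis/error cross-product matrices with Rao's F approximation),
## univariate follow-ups, covariate-adjusted estimated marginal means, and
## per-group age regressions with binned predictions.

## design matrix: intercept, centered-or-raw age, group dummy (A = reference)
.designMatrix <- function(d) {
  g <- factor(d$group, levels = c("A", "B"))
  X <- cbind(`(Intercept)` = 1, age = d$age, groupB = as.numeric(g == "B"))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (is only one group present?)")
  X
}

## complete cases across the six responses + age + group
.mancovaData <- function(data) {
  need <- c(bvsMeasures(), "age", "group")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, need]), , drop = FALSE]
  if (!all(c("A", "B") %in% d$group)) stop("both groups must be present")
  d
}

#' Multivariate analysis of covariance over the six measures
#'
#' Fits the multivariate linear model `Y ~ age + group` on listwise-complete
#' rows, and for each term computes the hypothesis (H) and error (E)
#' cross-product matrices, Wilks' lambda = det(E)/det(H + E), Rao's F
#' approximation, and partial eta squared = 1 - lambda^(1/s) (= 1 - lambda
#' for these single-df terms). Hypothesis df is reported as p x q (six for a
#' single-df term over six responses), the SPSS convention.
#'
#' @param data wide table with the six measure columns plus `age` and
#'   `group` (levels `"A"`/`"B"`; A is the reference).
#' @return data.frame, one row per term (intercept, age, group):
#'   wilks_lambda, F, df_hypothesis, df_error, p, partial_eta_squared, n.
#' @export
fitMancova <- function(data) {
  d <- .mancovaData(data)
  Y <- as.matrix(d[, bvsMeasures()])
  X <- .designMatrix(d)
  n <- nrow(Y); p <- ncol(Y); r <- ncol(X)
  if (n <= r + p)
    stop("too few complete cases for a 6-response model")
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y) - t(B) %*% crossprod(X) %*% B
  if (abs(det(E)) < 1e-300)
    stop("error cross-product matrix is singular (degenerate responses)")
  dfe <- n - r

  rows <- lapply(seq_len(r), function(j) {
    L <- matrix(0, 1, r); L[1, j] <- 1
    LB <- L %*% B
    H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
    lambda <- det(E) / det(E + H)
    q <- 1                      # single-df hypothesis
    s <- min(p, q)
    ## Rao's approximation (exact for s = 1)
    t_ <- 1
    w <- dfe - (p - q + 1) / 2
    df1 <- p * q
    df2 <- w * t_ - p * q / 2 + 1
    Fv <- ((1 - lambda^(1 / t_)) / lambda^(1 / t_)) * (df2 / df1)
    data.frame(term = c("(Intercept)" = "intercept", age = "age",
                        groupB = "group")[colnames(X)[j]],
               wilks_lambda = lambda, F = Fv, df_hypothesis = df1,
               df_error = df2, p = pf(Fv, df1, df2, lower.tail = FALSE),
               partial_eta_squared = 1 - lambda^(1 / s), n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate ANCOVA follow-up for one measure
#'
#' Linear model `measure ~ age + group` on the same complete-case filter as
#' the multivariate test (or per-measure complete cases when
#' `caseFilter = "per-measure"`), with partial (Type III) F tests per term
#' and the corrected-model F.
#'
#' @param data wide table (see [fitMancova()]).
#' @param measure one of [bvsMeasures()].
#' @param caseFilter `"multivariate"` (listwise across all six measures,
#'   default, matching the MANCOVA case set) or `"per-measure"`.
#' @return list with `model` (the `lm` fit), `correctedModel` (F, df, p),
#'   `age` and `group` (F, df, p each), `n`.
#' @export
univariateAncova <- function(data, measure,
                             caseFilter = c("multivariate", "per-measure")) {
  caseFilter <- match.arg(caseFilter)
  stopifnot(measure %in% bvsMeasures())
  d <- if (caseFilter == "multivariate") .mancovaData(data) else {
    dd <- data[complete.cases(data[, c(measure, "age", "group")]), ]
    if (!all(c("A", "B") %in% dd$group)) stop("both groups must be present")
    dd
  }
  d$group <- factor(d$group, levels = c("A", "B"))
  fit <- lm(stats::reformulate(c("age", "group"), response = measure),
            data = d)
  an <- stats::drop1(fit, test = "F")      # partial F tests (Type III here)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  term <- function(nm) list(F = an[nm, "F value"],
                            df = c(an[nm, "Df"], fit$df.residual),
                            p = an[nm, "Pr(>F)"])
  list(model = fit,
       correctedModel = list(F = unname(fstat[1]),
                             df = unname(fstat[2:3]),
                             p = pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
       age = term("age"), group = term("group"), n = nrow(d))
}

#' Covariate-adjusted estimated marginal means for one measure
#'
#' Group means predicted at the grand mean of age from the
#' [univariateAncova()] fit; the pairwise difference is reported as B - A
#' with its standard error, t-based 95% CI and p-value (no multiplicity
#' adjustment by default; `adjust = "holm"` applies a Holm correction when
#' called through [mancovaTable()]).
#'
#' @inheritParams univariateAncova
#' @param ciLevel confidence level.
#' @return list with `emmA`, `emmB` (means at the covariate mean),
#'   `difference` (B - A), `se`, `ciLow`, `ciHigh`, `p`, `df`, `n`.
#' @export
estimatedMarginalMeans <- function(data, measure, ciLevel = 0.95,
                                   caseFilter = "multivariate") {
  ua <- univariateAncova(data, measure, caseFilter = caseFilter)
  fit <- ua$model
  cf <- coef(fit)
  ageBar <- mean(fit$model$age)
  emmA <- unname(cf["(Intercept)"] + cf["age"] * ageBar)
  emmB <- emmA + unname(cf["groupB"])
  diffBA <- unname(cf["groupB"])       # dummy coding: the group coefficient
  se <- sqrt(stats::vcov(fit)["groupB", "groupB"])
  dfres <- fit$df.residual
  tcrit <- qt(1 - (1 - ciLevel) / 2, dfres)
  tval <- diffBA / se
  list(emmA = emmA, emmB = emmB, difference = diffBA, se = se,
       ciLow = diffBA - tcrit * se, ciHigh = diffBA + tcrit * se,
       p = 2 * pt(abs(tval), dfres, lower.tail = FALSE),
       df = dfres, n = ua$n)
}

#' Full group-comparison table
#'
#' The multivariate tests, the per-measure univariate follow-ups and the
#' estimated marginal mean differences, assembled as three data.frames.
#'
#' @inheritParams fitMancova
#' @param adjust `"none"` (default, mirroring conventional reporting) or
#'   `"holm"` for the six univariate/EMM p-values.
#' @return list with `multivariate`, `univariate`, `emm` data.frames and the
#'   achieved complete-case `n`.
#' @export
mancovaTable <- function(data, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  mv <- fitMancova(data)
  uni <- lapply(bvsMeasures(), function(m) {
    ua <- univariateAncova(data, m)
    data.frame(measure = m,
               corrected_F = ua$correctedModel$F, corrected_p = ua$correctedModel$p,
               age_F = ua$age$F, age_p = ua$age$p,
               group_F = ua$group$F, group_p = ua$group$p,
               stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  emm <- lapply(bvsMeasures(), function(m) {
    e <- estimatedMarginalMeans(data, m)
    data.frame(measure = m, difference_BA = e$difference, se = e$se,
               ci_low = e$ciLow, ci_high = e$ciHigh, p = e$p,
               stringsAsFactors = FALSE)
  })
  emm <- do.call(rbind, emm)
  if (adjust == "holm") {
    uni$group_p <- stats::p.adjust(uni$group_p, "holm")
    emm$p <- stats::p.adjust(emm$p, "holm")
  }
  rownames(uni) <- rownames(emm) <- NULL
  list(multivariate = mv, univariate = uni, emm = emm, n = mv$n[1])
}

#' Per-group age regression with binned predictions
#'
#' Ordinary least squares of a measure on age within each group, with
#' model-mean predictions and 95% confidence intervals at the midpoints of
#' decade age bins, plus R squared. Bins with no cases in a group are
#' skipped.
#'
#' @param data wide table with `age`, `group` and the measure column.
#' @param measure one of [bvsMeasures()].
#' @param binWidth age bin width in years (default 10).
#' @param ciLevel confidence level for the prediction-mean intervals.
#' @return list with per-group elements: `fit`, `r_squared`, `slope`,
#'   `predictions` (data.frame: bin_lo, bin_hi, midpoint, n, fit, ci_low,
#'   ci_high).
#' @export
ageRegression <- function(data, measure, binWidth = 10, ciLevel = 0.95) {
  stopifnot(measure %in% bvsMeasures())
  d <- data[complete.cases(data[, c(measure, "age", "group")]), ]
  out <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, ]
    if (nrow(dg) < 3L) stop("need at least 3 cases per group")
    fit <- lm(stats::reformulate("age", response = measure), data = dg)
    lo <- floor(min(dg$age) / binWidth) * binWidth
    hi <- ceiling(max(dg$age) / binWidth) * binWidth
    edges <- seq(lo, max(hi, lo + binWidth), by = binWidth)
    preds <- list()
    for (b in seq_len(length(edges) - 1L)) {
      inBin <- dg$age >= edges[b] & dg$age < edges[b + 1L]
      if (!any(inBin)) next
      mid <- (edges[b] + edges[b + 1L]) / 2
      pr <- predict(fit, newdata = data.frame(age = mid),
                    interval = "confidence", level = ciLevel)
      preds[[length(preds) + 1L]] <-
        data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L], midpoint = mid,
                   n = sum(inBin), fit = pr[1, "fit"],
                   ci_low = pr[1, "lwr"], ci_high = pr[1, "upr"])
    }
    out[[g]] <- list(fit = fit, r_squared = summary(fit)$r.squared,
                     slope = unname(coef(fit)["age"]),
                     predictions = do.call(rbind, preds))
  }
  out
}
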