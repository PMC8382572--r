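test_that("Wilks lambda, F and partial eta squared are internally consistent", {
  d <- simWideTable(seed = 51)
  mv <- fitMancova(d)
  expect_equal(mv$term, c("intercept", "age", "group"))
  expect_true(all(mv$wilks_lambda > 0 & mv$wilks_lambda <= 1))
  # single-df hypothesis: partial eta^2 = 1 - lambda and the F identity holds
  expect_equal(mv$partial_eta_squared, 1 - mv$wilks_lambda)
  expect_equal(mv$F, (1 - mv$wilks_lambda) / mv$wilks_lambda *
                 mv$df_error / mv$df_hypothesis)
})

test_that("lambda is invariant under nonsingular linear maps of the responses", {
  d <- simWideTable(seed = 52)
  base <- fitMancova(d)
  set.seed(52)
  A <- matrix(rnorm(36), 6)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(36), 6)
  Y2 <- as.matrix(d[, bvsMeasures()]) %*% t(A)
  d2 <- d
  d2[, bvsMeasures()] <- Y2
  trans <- fitMancova(d2)
  expect_equal(trans$wilks_lambda, base$wilks_lambda, tolerance = 1e-8)
})

test_that("degenerate responses raise an error naming the problem", {
  d <- simWideTable(seed = 53)
  for (m in bvsMeasures()) d[[m]] <- 7
  expect_error(fitMancova(d), "singular|rank")
  expect_error(fitMancova(simWideTable(seed = 53)[1:8, ]), "too few|both groups")
})

test_that("MANCOVA matches car::Manova (type III Wilks) on random datasets", {
  skip_if_not_installed("car")
  set.seed(54)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    d <- simWideTable(seed = 1000 + i, nA = n %/% 2, nB = n - n %/% 2,
                      diff = runif(1, -5, 5), ageSlope = runif(1, -0.2, 0.2))
    mine <- fitMancova(d)
    Y <- as.matrix(d[, bvsMeasures()])
    dd <- d; dd$group <- factor(dd$group)
    s <- summary(car::Manova(lm(Y ~ age + group, data = dd), type = 3,
                             test.statistic = "Wilks"), multivariate = TRUE)
    for (tm in c("(Intercept)", "age", "group")) {
      H <- s$multivariate.tests[[tm]]$SSPH
      E <- s$multivariate.tests[[tm]]$SSPE
      lam <- det(E) / det(H + E)
      key <- if (tm == "(Intercept)") "intercept" else tm
      expect_equal(mine$wilks_lambda[mine$term == key], lam,
                   tolerance = 1e-8)
    }
    # the group term (last, so sequential = partial) also matches stats::manova
    sw <- summary(stats::manova(Y ~ age + group, data = dd),
                  test = "Wilks")$stats
    expect_equal(mine$wilks_lambda[mine$term == "group"],
                 unname(sw["group", "Wilks"]), tolerance = 1e-8)
  }
})

test_that("univariate follow-ups match car type III F tests and EMMs match emmeans", {
  skip_if_not_installed("car")
  skip_if_not_installed("emmeans")
  set.seed(55)
  for (i in 1:10) {
    d <- simWideTable(seed = 2000 + i, diff = runif(1, -5, 5),
                      ageSlope = runif(1, -0.2, 0.2))
    m <- sample(bvsMeasures(), 1)
    ua <- univariateAncova(d, m)
    dd <- d; dd$group <- factor(dd$group)
    fit <- lm(stats::reformulate(c("age", "group"), m), data = dd)
    a3 <- car::Anova(fit, type = 3)
    expect_equal(ua$age$F, a3["age", "F value"], tolerance = 1e-8)
    expect_equal(ua$group$F, a3["group", "F value"], tolerance = 1e-8)

    e <- estimatedMarginalMeans(d, m)
    pr <- as.data.frame(pairs(emmeans::emmeans(fit, "group"),
                              reverse = TRUE), infer = TRUE)
    expect_equal(e$difference, pr$estimate, tolerance = 1e-8)
    expect_equal(e$se, pr$SE, tolerance = 1e-8)
    expect_equal(e$ciLow, pr$lower.CL, tolerance = 1e-8)
    expect_equal(e$p, pr$p.value, tolerance = 1e-8)
  }
})

test_that("null univariate group F follows its F distribution", {
  pvals <- vapply(seq_len(400), function(i) {
    d <- simWideTable(seed = 10000 + i, nA = 30, nB = 40)
    univariateAncova(d, "n100_latency")$group$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("covariate adjustment removes a pure age confound", {
  set.seed(57)
  nA <- 60; nB <- 60
  age <- c(rnorm(nA, 16, 1), rnorm(nB, 45, 12))
  g <- rep(c("A", "B"), c(nA, nB))
  d <- data.frame(group = g, age = age)
  for (m in bvsMeasures()) d[[m]] <- 200 - 0.8 * age + rnorm(nA + nB, 0, 3)
  unadj <- mean(d$n100_latency[d$group == "B"]) -
    mean(d$n100_latency[d$group == "A"])
  e <- estimatedMarginalMeans(d, "n100_latency")
  expect_gt(abs(unadj), 15)
  expect_lt(abs(e$difference), 3)
})

test_that("the assembled comparison table reports achieved df and optional Holm adjustment", {
  d <- simWideTable(seed = 58, diff = 3)
  tab <- mancovaTable(d)
  expect_equal(tab$n, nrow(d))
  expect_equal(nrow(tab$univariate), 6)
  holm <- mancovaTable(d, adjust = "holm")
  expect_true(all(holm$emm$p >= tab$emm$p - 1e-12))
})

test_that("age regression is exact on a noise-free line and near-null when age is shuffled", {
  d <- simWideTable(seed = 59)
  d$n400_amplitude <- 2 * d$age + 5
  ar <- suppressWarnings(ageRegression(d, "n400_amplitude"))  # perfect fit
  for (g in names(ar)) {
    expect_equal(ar[[g]]$r_squared, 1, tolerance = 1e-12)
    expect_equal(ar[[g]]$slope, 2, tolerance = 1e-10)
    expect_lt(max(ar[[g]]$predictions$ci_high - ar[[g]]$predictions$ci_low),
              1e-8)
  }
  set.seed(59)
  d2 <- simWideTable(seed = 60, nA = 3, nB = 135)
  d2$age[d2$group == "B"] <- sample(d2$age[d2$group == "B"])
  expect_lt(ageRegression(d2, "p300_amplitude")$B$r_squared, 0.05)
  # bin bookkeeping: predictions only for non-empty bins, n sums to group n
  pr <- ageRegression(d2, "p300_amplitude")$B$predictions
  expect_equal(sum(pr$n), 135)
  expect_true(all(pr$n >= 1))
})
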