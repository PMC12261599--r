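## Small deterministic cohort for exact-identity checks.
makeCohort <- function(n = 80, seed = 1) {
  set.seed(seed)
  data.frame(pid = sprintf("P%03d", 1:n), age = runif(n, 22, 94),
             sex = factor(sample(c("Male", "Female"), n, TRUE)),
             race = factor(sample(c("White", "Black", "Other"), n, TRUE,
                                  prob = c(0.7, 0.2, 0.1))),
             edy = rnorm(n, 16, 2.5))
}

test_that("the linear age model is exact on noiseless data", {
  d <- makeCohort()
  d$metric <- 2 - 0.01 * d$age
  fit <- fitLinearAge(d, "metric")
  cf <- fit@coefficients
  expect_equal(cf$estimate[cf$term == "age"], -0.01, tolerance = 1e-10)

  ## OLS equals the closed-form normal equations
  d$metric <- 2 - 0.01 * d$age + 0.3 * (d$sex == "Male") + rnorm(80, 0, 0.1)
  fit2 <- fitLinearAge(d, "metric")
  mf <- fit2@fit
  X <- model.matrix(mf)
  beta <- olsNormalEq(X, d$metric)
  expect_equal(unname(coef(mf)), beta, tolerance = 1e-10)
})

test_that("the quadratic age model identifies curvature via centring", {
  d <- makeCohort(120, seed = 2)
  d$metric <- (d$age - mean(d$age))^2
  fit <- fitQuadraticAge(d, "metric")
  cf <- fit@coefficients
  expect_equal(cf$estimate[cf$term == "I(ageC^2)"], 1, tolerance = 1e-8)
  expect_lt(abs(cf$estimate[cf$term == "ageC"]), 1e-8)

  ## centring is a reparameterisation: fitted values match an uncentred fit
  d$metric <- 1 + 0.02 * d$age - 1e-4 * d$age^2 + rnorm(120, 0, 0.05)
  fitC <- fitQuadraticAge(d, "metric")
  un <- lm(metric ~ age + I(age^2) + sex + race + edy, data = d)
  expect_lt(max(abs(fitted(fitC@fit) - fitted(un))), 1e-10)
})

test_that("the cross-sectional model recovers and adjusts correctly", {
  d <- makeCohort(100, seed = 3)
  d$metric <- rnorm(100, 15, 1)
  cog <- 0.1 - 0.01 * d$age + 0.5 * d$metric
  fit <- fitCrossSectional(d, cog, "metric")
  cf <- fit@coefficients
  expect_equal(cf$estimate[cf$term == "metric"], 0.5, tolerance = 1e-10)

  ## confounding by age: qMRI and cognition both age-driven, no direct link;
  ## the age-adjusted qMRI coefficient is centred on zero
  set.seed(4)
  reps <- replicate(200, {
    d2 <- makeCohort(120, seed = sample.int(1e6, 1))
    d2$metric <- 16 - 0.02 * d2$age + rnorm(120, 0, 0.3)
    cog2 <- 1 - 0.02 * d2$age + rnorm(120, 0, 0.3)
    f <- fitCrossSectional(d2, cog2, "metric")
    f@coefficients$estimate[f@coefficients$term == "metric"]
  })
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("BH-FDR matches hand execution and a brute-force oracle", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r@table$rejected))
  expect_equal(r@table$pAdj, rep(0.05, 5))

  single <- bhFdr(0.03)
  expect_equal(single@table$pAdj, 0.03)

  set.seed(10)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(c(1, 2), 1)
    r <- bhFdr(p, q = 0.05)
    o <- bruteForceBH(p, q = 0.05)
    expect_equal(r@table$pAdj, o$pAdj, tolerance = 1e-12)
    expect_equal(r@table$rejected, o$rejected)
  }

  ## order invariance
  p <- runif(8)
  perm <- sample(8)
  r1 <- bhFdr(p); r2 <- bhFdr(p[perm])
  expect_equal(r2@table$pAdj, r1@table$pAdj[perm])
  expect_error(bhFdr(numeric(0)), "empty")
})

test_that("the longitudinal mixed model recovers its generating effects", {
  spec <- CohortGenSpec(nParticipants = 150, seed = 21, visitMean = 4)
  cc <- generateCohort(spec)
  fit <- fitLongitudinal(cc$cohort, cc$visits, "rostralR2")
  cf <- fit@coefficients
  b <- spec@cognitionBetas
  term3 <- cf[cf$term == "age:rostralR2:time", ]
  expect_lt(abs(term3$estimate - b["qmriTimeAge"]), 3 * term3$se)
  termQT <- cf[cf$term == "rostralR2:time", ]
  expect_lt(abs(termQT$estimate - b["qmriTime"]), 3 * termQT$se)
  expect_equal(fit@varcomp$randomInterceptSd, 0.5, tolerance = 0.2)
  expect_equal(fit@varcomp$residualSd, 0.3, tolerance = 0.1)

  ## zero random-intercept generation is detected as a boundary fit
  spec0 <- CohortGenSpec(nParticipants = 100, randomInterceptSd = 0,
                         seed = 22, visitMean = 4)
  cc0 <- generateCohort(spec0)
  fit0 <- fitLongitudinal(cc0$cohort, cc0$visits, "rostralR2")
  expect_lt(fit0@varcomp$randomInterceptSd, 0.05)
})

test_that("permuting the metric across participants breaks the interaction", {
  set.seed(30)
  ests <- replicate(25, {
    cc <- generateCohort(CohortGenSpec(nParticipants = 120,
                                       seed = sample.int(1e6, 1),
                                       visitMean = 4))
    cc$cohort$rostralR2 <- sample(cc$cohort$rostralR2)
    f <- fitLongitudinal(cc$cohort, cc$visits, "rostralR2")
    cf <- f@coefficients
    cf$estimate[cf$term == "age:rostralR2:time"]
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)) + 1e-4)
})

test_that("slice-level age fits predict flat or rostrally steep profiles", {
  ## flat age effect: identical predictions at 40 and 75
  d <- makeCohort(90, seed = 40)
  d$metric <- 15 + 0.2 * (d$sex == "Male") + rnorm(90, 0, 0.01)
  fitFlat <- fitLinearAge(d, "metric")
  pr <- predictProfileAtAges(list(fitFlat), ages = c(40, 75))
  expect_lt(abs(diff(pr$predicted)), 0.02)

  ## steeper rostral slopes produce a larger age-40 vs age-75 gap rostrally
  slopes <- c(-0.04, -0.03, -0.02, -0.01)   # rostral -> caudal
  fits <- lapply(slopes, function(s) {
    dd <- makeCohort(150, seed = 41)
    dd$metric <- 16 + s * dd$age + rnorm(150, 0, 0.2)
    fitLinearAge(dd, "metric")
  })
  pred <- predictProfileAtAges(fits, ages = c(40, 75))
  gaps <- with(pred, predicted[age == 40] - predicted[age == 75])
  expect_true(all(diff(gaps) < 0))          # gap shrinks towards caudal

  ## prediction at the mean age with reference covariates is the fitted
  ## reference response (definitional)
  mf <- fitFlat@fit
  nd <- data.frame(age = mean(d$age), sex = factor("Female", levels(d$sex)),
                   race = factor(levels(model.frame(mf)$race)[1],
                                 levels(model.frame(mf)$race)),
                   edy = mean(d$edy))
  direct <- predict(mf, nd)
  viaFun <- predictProfileAtAges(list(fitFlat), ages = mean(d$age))
  expect_equal(unname(viaFun$predicted), unname(direct), tolerance = 1e-10)

  ## extrapolation warns
  expect_warning(predictProfileAtAges(list(fitFlat), ages = c(5)), "age range")
})
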