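## Synthetic longitudinal cohort: covariates, per-participant qMRI summaries
## drawn from age models, and visit-level cognition generated from the same
## mixed-model structure the longitudinal analysis fits (fixed effects up to
## the age x qMRI x time interaction, participant random intercept, i.i.d.
## residual). Age and the driving qMRI metric enter the linear predictor
## mean-centred over the realised cohort -- the same convention the fitting
## routine uses -- so fitted coefficients estimate the generating ones
## directly.

#' Generate a synthetic cohort with longitudinal cognition
#'
#' Per participant: age uniform over \code{ageRange} (a uniform over 22--94
#' reproduces the target cohort's age SD of ~21 years), sex and race
#' categorical per the spec probabilities, education Gaussian; each qMRI
#' summary is drawn from its age model (intercept + linear + quadratic on
#' centred age + Gaussian residual). Visit counts are truncated Poisson
#' (minimum 1) and visit times are 0 (the MRI date), -spacing, -2 spacing, ...
#' Per visit, cognition is the mixed-model linear predictor with the spec's
#' betas plus the participant's random intercept and a residual draw. With
#' \code{rawScores = TRUE}, raw instrument scores for the five cognitive
#' domains are derived from the visit's cognition value as a latent ability
#' (monotone transforms plus test noise; TMT scores are completion times in
#' seconds, decreasing in ability).
#'
#' @param spec a \code{\link{CohortGenSpec}}.
#' @param rawScores logical; also emit raw instrument columns.
#' @return list with \code{cohort} (one row per participant: pid, age, sex,
#'   race, edy, one column per qMRI metric) and \code{visits} (one row per
#'   assessment: pid, visit, time, cognition, and optionally raw instrument
#'   columns).
#' @examples
#' cc <- generateCohort(CohortGenSpec(nParticipants = 20))
#' head(cc$visits)
#' @export
generateCohort <- function(spec, rawScores = FALSE) {
  validObject(spec)
  n <- spec@nParticipants
  stopIfNot(n > 0, "non-positive number of participants")
  withSeed(spec@seed, {
    age <- runif(n, spec@ageRange[1], spec@ageRange[2])
    sex <- factor(ifelse(rbinom(n, 1, spec@sexProb) == 1, "Male", "Female"),
                  levels = c("Male", "Female"))
    race <- factor(sample(names(spec@raceProbs), n, replace = TRUE,
                          prob = spec@raceProbs),
                   levels = names(spec@raceProbs))
    edy <- rnorm(n, spec@edyMeanSd[1], spec@edyMeanSd[2])
    ageC <- age - mean(age)
    qmri <- lapply(spec@qmriAgeModel, function(m)
      m$intercept + m$age * ageC + m$age2 * ageC^2 + rnorm(n, 0, m$sd))
    cohort <- data.frame(pid = sprintf("P%03d", seq_len(n)), age = age,
                         sex = sex, race = race, edy = edy,
                         stringsAsFactors = FALSE)
    for (nm in names(qmri)) cohort[[nm]] <- qmri[[nm]]

    ## visit counts: truncated Poisson, minimum 1
    nv <- rpois(n, spec@visitMean)
    while (any(nv < 1)) nv[nv < 1] <- rpois(sum(nv < 1), spec@visitMean)

    b <- spec@cognitionBetas
    driver <- cohort[[spec@cognitionDriver]]
    driverC <- driver - mean(driver)
    u <- rnorm(n, 0, spec@randomInterceptSd)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tt <- -(seq_len(nv[i]) - 1) * spec@visitSpacing
      fixed <- b["intercept"] + b["age"] * ageC[i] +
        b["sex"] * (sex[i] == "Male") +
        b["raceBlack"] * (race[i] == "Black") +
        b["raceOther"] * (race[i] == "Other") +
        b["edy"] * edy[i] +
        b["time"] * tt + b["qmri"] * driverC[i] +
        b["ageTime"] * ageC[i] * tt + b["qmriAge"] * driverC[i] * ageC[i] +
        b["qmriTime"] * driverC[i] * tt +
        b["qmriTimeAge"] * driverC[i] * tt * ageC[i]
      cog <- fixed + u[i] + rnorm(length(tt), 0, spec@residualSd)
      rows[[i]] <- data.frame(pid = cohort$pid[i], visit = seq_along(tt),
                              time = tt, cognition = as.numeric(cog),
                              stringsAsFactors = FALSE)
    }
    visits <- do.call(rbind, rows)
    if (rawScores) visits <- cbind(visits, .rawInstrumentScores(visits$cognition))
  })
  list(cohort = cohort, visits = visits)
}

## Raw instrument scores from a latent ability: monotone increasing in ability
## except the TMT completion times, which decrease (shorter = better).
.rawInstrumentScores <- function(ability) {
  n <- length(ability)
  e <- function(s) rnorm(n, 0, s)
  data.frame(
    cvltImmediate = 50 + 10 * ability + e(2),
    cvltDelay = 12 + 3 * ability + e(1),
    tmtA = exp(3.4 - 0.25 * ability + e(0.05)),
    dsForward = 10 + 2 * ability + e(0.8),
    tmtB = exp(4.2 - 0.30 * ability + e(0.05)),
    dsBackward = 8 + 2 * ability + e(0.8),
    fluencyCategory = 20 + 4 * ability + e(1.5),
    fluencyLetter = 40 + 8 * ability + e(2.5),
    dsst = 45 + 8 * ability + e(2.5))
}
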