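## The four model families linking LC qMRI metrics to age and cognition, plus
## BH-FDR control and the slice-level age predictions. OLS models use
## stats::lm; the longitudinal model is a random-intercept linear mixed model
## fit by REML through lme4, with Satterthwaite p-values from lmerTest. Race
## is dummy-coded with the largest observed category as reference.

.relevelRace <- function(race) {
  race <- as.factor(race)
  ref <- names(sort(table(race), decreasing = TRUE))[1]
  stats::relevel(droplevels(race), ref = ref)
}

.lmToModelFit <- function(fit, family) {
  sm <- summary(fit)$coefficients
  cf <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p = pmin(pmax(sm[, 4], .Machine$double.xmin), 1),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("ModelFit", coefficients = cf, family = family,
      n = as.integer(stats::nobs(fit)), converged = TRUE, varcomp = list(),
      fit = fit)
}

.checkRank <- function(fit) {
  alias <- is.na(coef(fit))
  if (any(alias))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(coef(fit))[alias], collapse = ", "), call. = FALSE)
}

#' Linear age model for a qMRI metric
#'
#' OLS of a qMRI summary on age, adjusting for sex, race and years of
#' education: \code{metric ~ age + sex + race + edy}. The coefficient of
#' interest is the age slope.
#'
#' @param cohort data.frame with columns \code{age}, \code{sex}, \code{race},
#'   \code{edy} and the metric column.
#' @param metric name of the qMRI column.
#' @return A \code{\link{ModelFit}} (family "linear_age").
#' @examples
#' cc <- generateCohort(CohortGenSpec(nParticipants = 60))
#' fitLinearAge(cc$cohort, "lcR2")
#' @export
fitLinearAge <- function(cohort, metric) {
  d <- .modelData(cohort, metric)
  stopIfNot(nrow(d) > 5, "more observations than parameters are required")
  fit <- lm(y ~ age + sex + race + edy, data = d)
  .checkRank(fit)
  .lmToModelFit(fit, "linear_age")
}

#' Quadratic age model for a qMRI metric
#'
#' Adds mean-centred age and its square (centring removes the collinearity
#' between the linear and quadratic terms):
#' \code{metric ~ ageC + I(ageC^2) + sex + race + edy}. The coefficient of
#' interest is the quadratic term.
#'
#' @inheritParams fitLinearAge
#' @return A \code{\link{ModelFit}} (family "quadratic_age").
#' @export
fitQuadraticAge <- function(cohort, metric) {
  d <- .modelData(cohort, metric)
  stopIfNot(nrow(d) > 6, "more observations than parameters are required")
  d$ageC <- d$age - mean(d$age)
  fit <- lm(y ~ ageC + I(ageC^2) + sex + race + edy, data = d)
  .checkRank(fit)
  .lmToModelFit(fit, "quadratic_age")
}

#' Cross-sectional cognition model
#'
#' OLS of a domain z-score at the time of MRI on age, sex, race, education and
#' the qMRI metric: \code{cog ~ age + sex + race + edy + metric}. The
#' coefficient of interest is the qMRI term.
#'
#' @param cohort data.frame with covariates and the metric column.
#' @param cognition numeric vector, the domain z-score at MRI (one per row of
#'   \code{cohort}).
#' @param metric name of the qMRI column.
#' @return A \code{\link{ModelFit}} (family "cross_sectional").
#' @export
fitCrossSectional <- function(cohort, cognition, metric) {
  d <- .modelData(cohort, metric)
  d$cog <- cognition[as.numeric(rownames(d))]
  d <- d[complete.cases(d), ]
  stopIfNot(nrow(d) > 6, "more observations than parameters are required")
  fit <- lm(cog ~ age + sex + race + edy + y, data = d)
  .checkRank(fit)
  mf <- .lmToModelFit(fit, "cross_sectional")
  mf@coefficients$term[mf@coefficients$term == "y"] <- metric
  mf
}

#' Longitudinal mixed model of cognition
#'
#' Random-intercept linear mixed model of longitudinal domain z-scores with
#' fixed effects for age, sex, race, education, time from MRI, the qMRI
#' metric, and the age x qMRI x time interaction with all lower-order terms.
#' The qMRI metric is mean-centred; age is mean-centred as well by default
#' (coefficient-equivalent reparameterisation that stabilises the three-way
#' interaction; disable with \code{centerAge = FALSE}). Fit by REML; p-values
#' use the Satterthwaite approximation. The key terms are qMRI x time (the
#' expected difference in annual cognition change per unit qMRI difference)
#' and qMRI x time x age (its moderation by age).
#'
#' @param cohort participant table (pid, age, sex, race, edy, metric column).
#' @param visits visit table with \code{pid}, \code{time} and the outcome
#'   column.
#' @param metric name of the qMRI column in \code{cohort}.
#' @param outcome name of the outcome column in \code{visits} (default
#'   "cognition").
#' @param centerAge logical, mean-centre age (default TRUE).
#' @param reml logical, REML (default) or ML.
#' @return A \code{\link{ModelFit}} (family "longitudinal") with variance
#'   components in \code{@varcomp}; singular fits are flagged via
#'   \code{@converged} and the status in \code{@varcomp$singular}.
#' @examples
#' cc <- generateCohort(CohortGenSpec(nParticipants = 40))
#' fitLongitudinal(cc$cohort, cc$visits, "rostralR2")
#' @export
fitLongitudinal <- function(cohort, visits, metric, outcome = "cognition",
                            centerAge = TRUE, reml = TRUE) {
  stopIfNot(metric %in% names(cohort), sprintf("no column '%s'", metric))
  d <- merge(visits[, c("pid", "time", outcome)],
             cohort[, c("pid", "age", "sex", "race", "edy", metric)],
             by = "pid")
  names(d)[names(d) == outcome] <- "cog"
  names(d)[names(d) == metric] <- "qmri"
  d <- d[complete.cases(d), ]
  nMulti <- sum(table(d$pid) >= 2)
  if (nMulti < 3)
    stop("need repeated visits for a nontrivial share of participants",
         call. = FALSE)
  d$race <- .relevelRace(d$race)
  d$qmriC <- d$qmri - mean(d$qmri)
  d$ageC <- if (centerAge) d$age - mean(d$age) else d$age
  fit <- lmerTest::lmer(
    cog ~ ageC * qmriC * time + sex + race + edy + (1 | pid),
    data = d, REML = reml,
    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC(
      action = "ignore", tol = 1e-4)))
  sm <- summary(fit)$coefficients
  cf <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"],
                   p = pmin(pmax(sm[, "Pr(>|t|)"], .Machine$double.xmin), 1),
                   row.names = NULL, stringsAsFactors = FALSE)
  ## readable term names
  map <- c("ageC" = "age", "qmriC" = metric, "time" = "time",
           "ageC:qmriC" = paste0("age:", metric),
           "ageC:time" = "age:time",
           "qmriC:time" = paste0(metric, ":time"),
           "ageC:qmriC:time" = paste0("age:", metric, ":time"))
  hit <- cf$term %in% names(map)
  cf$term[hit] <- map[cf$term[hit]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  new("ModelFit", coefficients = cf, family = "longitudinal",
      n = as.integer(stats::nobs(fit)),
      converged = length(fit@optinfo$conv$lme4$messages) == 0,
      varcomp = list(randomInterceptSd = vc$sdcor[vc$grp == "pid"],
                     residualSd = vc$sdcor[vc$grp == "Residual"],
                     singular = singular),
      fit = fit)
}

## Shared covariate preparation: select columns, rename the metric to y,
## relevel race to the largest category, drop incomplete rows.
.modelData <- function(cohort, metric) {
  stopIfNot(metric %in% names(cohort), sprintf("no column '%s'", metric))
  d <- cohort[, c("age", "sex", "race", "edy", metric)]
  names(d)[5] <- "y"
  d$race <- .relevelRace(d$race)
  d[complete.cases(d), ]
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH adjustment: \eqn{p^{adj}_{(i)} = \min_{j \ge i} m\, p_{(j)}/j},
#' capped at 1; tests with adjusted p at or below q are rejected. The family
#' is whatever set of tests is passed in together (in this pipeline:
#' subregion variants x cognitive domains per metric and effect).
#'
#' @param p numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @param family character description of the corrected family.
#' @return A \code{\link{FdrResult}}; its table preserves the input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
bhFdr <- function(p, q = 0.05, family = "unspecified") {
  stopIfNot(length(p) > 0, "empty p-value list")
  stopIfNot(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  pAdj <- p.adjust(p, method = "BH")
  new("FdrResult",
      table = data.frame(p = p, pAdj = pAdj, rejected = pAdj <= q),
      q = q, family = family)
}

#' Predicted metric values at reference ages from per-slice age models
#'
#' Given one linear age model per slice (fits from \code{\link{fitLinearAge}}
#' on slice-level metric summaries), predicts the metric at each requested age
#' with covariates held at reference values: sex and race at their reference
#' levels, education at the estimation-sample mean. Ages outside the fitted
#' age range trigger an extrapolation warning.
#'
#' @param fits list of \code{\link{ModelFit}} objects (family "linear_age"),
#'   one per slice, ordered rostral to caudal.
#' @param ages numeric ages at which to predict (default c(40, 75)).
#' @return data.frame with columns \code{slice} (1-based rostral order),
#'   \code{age}, \code{predicted}.
#' @export
predictProfileAtAges <- function(fits, ages = c(40, 75)) {
  rows <- lapply(seq_along(fits), function(k) {
    fit <- fits[[k]]@fit
    mf <- model.frame(fit)
    rng <- range(mf$age)
    if (any(ages < rng[1] | ages > rng[2]))
      warning(sprintf("slice %d: predicting outside the fitted age range [%g, %g]",
                      k, rng[1], rng[2]))
    nd <- data.frame(age = ages,
                     sex = factor(levels(mf$sex)[1], levels = levels(mf$sex)),
                     race = factor(levels(mf$race)[1], levels = levels(mf$race)),
                     edy = mean(mf$edy))
    data.frame(slice = k, age = ages, predicted = as.numeric(predict(fit, nd)))
  })
  do.call(rbind, rows)
}

#' Coefficient heatmap table across metrics, subregions and domains
#'
#' Convenience builder for the "heatmap" summary: runs a model family for
#' every combination of qMRI column and cognitive domain, extracts the
#' coefficient of interest, and applies BH-FDR within each metric's family
#' (subregion variants x domains).
#'
#' @param cohort participant table.
#' @param visits visit table with domain z-score columns (longitudinal) or a
#'   data.frame of domain z-scores at MRI (cross-sectional).
#' @param metrics named list: family name -> character vector of metric
#'   columns forming one FDR family (e.g.
#'   \code{list(R2 = c("lcR2", "rostralR2", "caudalR2"))}).
#' @param domains character vector of domain column names.
#' @param type "cross_sectional" or "longitudinal".
#' @param term which coefficient to extract for longitudinal fits:
#'   "qmri:time" (default) or "qmri:time:age".
#' @param q FDR level.
#' @return data.frame with metric, domain, estimate, se, p, pAdj, rejected.
#' @export
coefficientTable <- function(cohort, visits, metrics, domains,
                             type = c("cross_sectional", "longitudinal"),
                             term = c("qmri:time", "qmri:time:age"),
                             q = 0.05) {
  type <- match.arg(type); term <- match.arg(term)
  out <- list()
  for (famName in names(metrics)) {
    rows <- list()
    for (m in metrics[[famName]]) for (dm in domains) {
      if (type == "cross_sectional") {
        atMri <- visits[visits$time == 0, c("pid", dm)]
        merged <- merge(cohort["pid"], atMri, by = "pid", all.x = TRUE)
        fit <- fitCrossSectional(cohort, merged[[dm]][match(cohort$pid, merged$pid)], m)
        cf <- fit@coefficients[fit@coefficients$term == m, ]
      } else {
        fit <- fitLongitudinal(cohort, visits, m, outcome = dm)
        wanted <- if (term == "qmri:time") paste0(m, ":time")
                  else paste0("age:", m, ":time")
        cf <- fit@coefficients[fit@coefficients$term == wanted, ]
      }
      rows[[paste(m, dm)]] <- data.frame(metric = m, domain = dm,
                                         estimate = cf$estimate, se = cf$se,
                                         p = cf$p)
    }
    tab <- do.call(rbind, rows)
    fdr <- bhFdr(tab$p, q = q, family = famName)
    tab$pAdj <- fdr@table$pAdj
    tab$rejected <- fdr@table$rejected
    out[[famName]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
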