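## Conversion of raw neuropsychological test scores into the five domain
## z-scores used by the statistical models. Domains and constituents:
##   memory           : CVLT immediate recall, CVLT long-delay recall
##   attention        : TMT part A (transformed), Digit Span forward
##   executive        : TMT part B (transformed), Digit Span backward
##   verbal fluency   : Category fluency, Letter fluency
##   processing speed : TMT part A (transformed), DSST

#' Raw-score column names expected by the cognition pipeline
#' @return character vector of instrument column names.
#' @export
cognitionInstruments <- function() {
  c("cvltImmediate", "cvltDelay", "tmtA", "dsForward", "tmtB", "dsBackward",
    "fluencyCategory", "fluencyLetter", "dsst")
}

#' Baseline z-scoring
#'
#' \eqn{z = (x - \mu_0)/\sigma_0} where the baseline mean and SD are computed
#' across participants' first assessments; the same statistics standardise
#' every later visit.
#'
#' @param x numeric scores.
#' @param baselineMean,baselineSd baseline statistics; \code{baselineSd} must
#'   be > 0.
#' @return numeric z-scores.
#' @examples
#' zscoreBaseline(c(10, 12), 10, 2)
#' @export
zscoreBaseline <- function(x, baselineMean, baselineSd) {
  if (!is.finite(baselineSd) || baselineSd <= 0)
    stop("baseline SD must be > 0", call. = FALSE)
  (x - baselineMean) / baselineSd
}

#' Trail-Making-Test transform
#'
#' Completion times are log-transformed (natural log; the base cancels in
#' z-scoring) and scale-inverted, so that higher transformed scores reflect
#' shorter completion times: returns \eqn{-\log(t)}.
#'
#' @param seconds completion times, > 0.
#' @return transformed scores, strictly decreasing in time.
#' @examples
#' transformTmt(30) > transformTmt(60)
#' @export
transformTmt <- function(seconds) {
  bad <- !is.na(seconds) & (!is.finite(seconds) | seconds <= 0)
  if (any(bad)) stop("TMT times must be > 0", call. = FALSE)
  -log(seconds)
}

#' Domain scores from per-test z-scores
#'
#' Each domain is the mean of its constituent test z-scores. Missing
#' constituents are dropped (the domain is the mean of the available tests)
#' and flagged via the \code{<domain>Complete} columns; a domain with no
#' constituent present is NA with the flag FALSE.
#'
#' @param z data.frame with (a subset of) the columns of
#'   \code{\link{cognitionInstruments}}, already z-scored (TMT columns already
#'   transformed before z-scoring).
#' @return data.frame with columns memory, attention, executive, fluency,
#'   speed and the corresponding \code{*Complete} logical flags.
#' @export
domainScores <- function(z) {
  domains <- list(
    memory = c("cvltImmediate", "cvltDelay"),
    attention = c("tmtA", "dsForward"),
    executive = c("tmtB", "dsBackward"),
    fluency = c("fluencyCategory", "fluencyLetter"),
    speed = c("tmtA", "dsst"))
  n <- nrow(z)
  out <- data.frame(row.names = seq_len(n))
  for (d in names(domains)) {
    cols <- intersect(domains[[d]], names(z))
    if (!length(cols)) {
      out[[d]] <- rep(NA_real_, n)
      out[[paste0(d, "Complete")]] <- rep(FALSE, n)
      next
    }
    m <- as.matrix(z[, cols, drop = FALSE])
    avail <- rowSums(!is.na(m))
    out[[d]] <- ifelse(avail > 0, rowMeans(m, na.rm = TRUE), NA_real_)
    out[[paste0(d, "Complete")]] <- avail == length(domains[[d]])
  }
  out
}

#' Full cognition preparation pipeline
#'
#' From a longitudinal visit table with raw instrument scores to domain
#' z-scores: TMT columns are transformed via \code{\link{transformTmt}}, each
#' instrument is z-scored against the mean and SD of participants' baseline
#' (first) assessments, and domain scores are averaged per
#' \code{\link{domainScores}}.
#'
#' @param visits data.frame with columns \code{pid}, \code{time} (years from
#'   MRI, 0 = scan date) and the raw instrument columns of
#'   \code{\link{cognitionInstruments}} (missing instruments are allowed).
#' @return the input with added z-score columns (\code{z.<instrument>}) and
#'   the five domain columns plus completeness flags.
#' @export
prepCognition <- function(visits) {
  stopIfNot(all(c("pid", "time") %in% names(visits)),
            "visits needs pid and time columns")
  inst <- intersect(cognitionInstruments(), names(visits))
  stopIfNot(length(inst) > 0, "no instrument columns found")
  work <- visits
  for (cl in intersect(c("tmtA", "tmtB"), inst))
    work[[cl]] <- transformTmt(work[[cl]])
  ## baseline = each participant's first assessment
  ord <- order(work$pid, work$time)
  firstIdx <- ord[!duplicated(work$pid[ord])]
  zcols <- list()
  for (cl in inst) {
    b <- work[[cl]][firstIdx]
    mu <- mean(b, na.rm = TRUE); s <- sd(b, na.rm = TRUE)
    zcols[[cl]] <- zscoreBaseline(work[[cl]], mu, s)
  }
  zdf <- as.data.frame(zcols)
  names(zdf) <- inst
  dom <- domainScores(zdf)
  zout <- zdf
  names(zout) <- paste0("z.", inst)
  cbind(visits, zout, dom)
}
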