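## Sample quality gating and cohort evaluability summaries.
##
## A run is GOOD when it meets all three recommended targets (total DNA in
## molecules > 150 kbp above 1500 Gbp, map rate above 70%, effective coverage
## above 300x). Otherwise it is still EVALUABLE when the map rate and coverage
## fall into one of two rescue bands: map rate in [40,50)% with coverage
## > 150x, or map rate >= 50% with coverage > 100x. Everything else is
## NOT_EVALUABLE. The upper band is open-ended in map rate: a sample mapping
## above 70% but short of 300x coverage is classed EVALUABLE when coverage
## clears 100x, since a better map rate cannot make a sample worse.

#' Default quality thresholds
#'
#' @return named list of thresholds: \code{goodDNA} (Gbp), \code{goodMap} (%),
#'   \code{goodCov} (x), \code{lowMapMin}/\code{lowMapMax} (%) and
#'   \code{lowCov} (x) for the low rescue band, \code{midMap} (%) and
#'   \code{midCov} (x) for the upper band. Strict inequalities are used for
#'   every ">" bound; the low map-rate band is the half-open interval
#'   [lowMapMin, lowMapMax).
#' @export
qcThresholds <- function() {
  list(goodDNA = 1500, goodMap = 70, goodCov = 300,
       lowMapMin = 40, lowMapMax = 50, lowCov = 150,
       midMap = 50, midCov = 100)
}

#' Classify per-sample quality into GOOD / EVALUABLE / NOT_EVALUABLE
#'
#' @param totalDNAGbp gigabase-pairs of molecules > 150 kbp.
#' @param mapRatePct molecule map rate, percent in [0, 100].
#' @param effectiveCoverage effective fold-coverage, >= 0.
#' @param thresholds threshold list as returned by \code{\link{qcThresholds}}.
#' @return list with \code{tier} (one of \code{"GOOD"}, \code{"EVALUABLE"},
#'   \code{"NOT_EVALUABLE"}) and \code{rules}, the names of the band(s) that
#'   fired.
#' @examples
#' classifyQuality(1600, 75, 350)$tier   # "GOOD"
#' classifyQuality(1200, 45, 160)$tier   # "EVALUABLE" (low band)
#' classifyQuality(1200, 45, 120)$tier   # "NOT_EVALUABLE"
#' @export
classifyQuality <- function(totalDNAGbp, mapRatePct, effectiveCoverage,
                            thresholds = qcThresholds()) {
  stopifnot(length(totalDNAGbp) == 1, length(mapRatePct) == 1,
            length(effectiveCoverage) == 1)
  if (is.na(totalDNAGbp) || is.na(mapRatePct) || is.na(effectiveCoverage))
    stop("QC metrics must not be missing")
  if (totalDNAGbp < 0 || effectiveCoverage < 0 ||
      mapRatePct < 0 || mapRatePct > 100)
    stop("QC metric out of range")
  th <- thresholds
  rules <- character()
  if (totalDNAGbp > th$goodDNA && mapRatePct > th$goodMap &&
      effectiveCoverage > th$goodCov) {
    return(list(tier = "GOOD", rules = "recommended_thresholds"))
  }
  lowBand <- mapRatePct >= th$lowMapMin && mapRatePct < th$lowMapMax &&
    effectiveCoverage > th$lowCov
  midBand <- mapRatePct >= th$midMap && effectiveCoverage > th$midCov
  if (lowBand) rules <- c(rules, "map_40_50_cov_gt150")
  if (midBand) rules <- c(rules, "map_ge50_cov_gt100")
  if (lowBand || midBand) return(list(tier = "EVALUABLE", rules = rules))
  list(tier = "NOT_EVALUABLE", rules = character())
}

#' Classify a QC metric table
#'
#' Vectorized wrapper around \code{\link{classifyQuality}}.
#'
#' @param qc data.frame as returned by \code{\link{readQCTable}}.
#' @param thresholds see \code{\link{qcThresholds}}.
#' @return the input with added columns \code{tier} and \code{rules}.
#' @export
classifyQualityTable <- function(qc, thresholds = qcThresholds()) {
  res <- lapply(seq_len(nrow(qc)), function(i)
    classifyQuality(qc$total_dna_gbp[i], qc$map_rate_pct[i],
                    qc$effective_coverage[i], thresholds))
  qc$tier <- vapply(res, `[[`, "", "tier")
  qc$rules <- vapply(res, function(r) paste(r$rules, collapse = ";"), "")
  qc
}

#' Summarize cohort evaluability per group and overall
#'
#' @param group character vector of tissue-group labels, one per case.
#' @param evaluable logical vector, one per case.
#' @return data.frame with one row per group plus an \code{"overall"} row:
#'   \code{group, n_evaluable, n_total, rate_pct} (percent, one decimal as
#'   conventionally reported).
#' @examples
#' summarizeEvaluability(rep("bone", 6), c(TRUE, TRUE, rep(FALSE, 4)))
#' @export
summarizeEvaluability <- function(group, evaluable) {
  if (length(group) == 0) stop("empty cohort")
  if (length(group) != length(evaluable))
    stop("group and evaluable must have the same length")
  evaluable <- as.logical(evaluable)
  if (anyNA(evaluable)) stop("evaluable flags must not be missing")
  tot <- table(group)
  ev <- tapply(evaluable, group, sum)
  out <- data.frame(group = names(tot),
                    n_evaluable = as.integer(ev[names(tot)]),
                    n_total = as.integer(tot),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(group = "overall",
                               n_evaluable = sum(evaluable),
                               n_total = length(evaluable)))
  out$rate_pct <- round(100 * out$n_evaluable / out$n_total, 1)
  rownames(out) <- NULL
  out
}
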