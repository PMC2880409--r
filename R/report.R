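# Operating-point selection and the per-residue prediction report.
#
# The deployed classifier carries the ROC calibration of its own fivefold
# cross-validation. A user requests a desired sensitivity or specificity;
# the output threshold t is read off the calibration curve. A residue with
# classifier output o is called '+' iff o >= t (ties to positive). Its
# confidence ranks o within the calibration score distributions: for a
# positive call, confidence = 1 - sn(o), the fraction of calibration
# positives scoring strictly below o; for a negative call, 1 - sp(o), the
# fraction of calibration negatives scoring at or above o. The overview
# shows the floor of 10 x confidence as a digit 0-9 per residue.

#' Choose an output threshold from a requested sensitivity or specificity
#'
#' For a requested specificity the smallest threshold whose estimated
#' specificity reaches the level is taken (the conservative side); for a
#' requested sensitivity, the largest threshold whose estimated sensitivity
#' reaches it. Step lookup on the calibration staircase, no interpolation.
#'
#' @param roc a \linkS4class{ROCCalibration} (typically the deployed
#'   model's cross-validated calibration).
#' @param kind \code{"sensitivity"} or \code{"specificity"}: which measure
#'   the level constrains.
#' @param level requested level in [0, 1].
#' @return list (operating point): \code{threshold}, \code{kind},
#'   \code{level}, \code{estSensitivity}, \code{estSpecificity},
#'   \code{saturated} (TRUE when only a sentinel extreme satisfies the
#'   request).
#' @export
selectThreshold <- function(roc, kind = c("sensitivity", "specificity"),
                            level) {
  kind <- match.arg(kind)
  stopifnot(is(roc, "ROCCalibration"))
  if (!is.numeric(level) || level < 0 || level > 1)
    stop("level must lie in [0, 1]")
  p <- rocPointsTable(roc)
  if (kind == "specificity") {
    ok <- which(p$specificity >= level)  # upper tail: spec rises with t
    row <- p[min(ok), ]
  } else {
    ok <- which(p$sensitivity >= level)  # lower tail: sens falls with t
    row <- p[max(ok), ]
  }
  list(threshold = row$threshold, kind = kind, level = level,
       estSensitivity = row$sensitivity, estSpecificity = row$specificity,
       saturated = !is.finite(row$threshold))
}

#' Confidence of a prediction from the calibration score distributions
#'
#' @param o classifier output(s), numeric vector.
#' @param t decision threshold.
#' @param roc a \linkS4class{ROCCalibration} carrying the empirical score
#'   distributions of calibration positives and negatives.
#' @return confidence values in [0, 1]: for o >= t the fraction of
#'   calibration positives with output < o; otherwise the fraction of
#'   calibration negatives with output >= o.
#' @export
predictionConfidence <- function(o, t, roc) {
  stopifnot(is(roc, "ROCCalibration"))
  if (length(roc@posScores) == 0L || length(roc@negScores) == 0L)
    stop("calibration lacks score distributions")
  vapply(o, function(oi) {
    if (oi >= t) mean(roc@posScores < oi) else mean(roc@negScores >= oi)
  }, numeric(1))
}

#' Confidence level digit
#'
#' The floor of 10 x confidence, clamped to 9 at confidence 1.
#'
#' @param confidence numeric vector in [0, 1].
#' @return integer vector in 0..9.
#' @examples
#' confidenceLevel(c(0, 0.7252, 1))  # 0 7 9
#' @export
confidenceLevel <- function(confidence) {
  if (any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]")
  pmin(as.integer(floor(10 * confidence)), 9L)
}

#' Predict binding residues of a query sequence
#'
#' Full prediction pipeline: encode the query in prediction mode (every
#' residue gets a window, termini padded), score with the calibrated
#' classifier, select the operating point from the requested sensitivity or
#' specificity, and attach per-residue calls, confidences and levels.
#'
#' @param query the query sequence: a character string or a
#'   \linkS4class{LabeledSequence}.
#' @param model a calibrated \linkS4class{BindingClassifier}.
#' @param kind \code{"sensitivity"} or \code{"specificity"}.
#' @param level requested level in [0, 1] (default specificity 0.95).
#' @param pssm optional \linkS4class{PSSMProfile} for the query.
#' @param conservation optional \linkS4class{ConservationProfile}.
#' @param table feature table.
#' @return data.frame with columns position, residue, output, call ('+' or
#'   '-'), confidence, level; the operating point is attached as attribute
#'   \code{"operatingPoint"}.
#' @export
predictResidues <- function(query, model, kind = "specificity",
                            level = 0.95, pssm = NULL, conservation = NULL,
                            table = featureTable()) {
  stopifnot(is(model, "BindingClassifier"))
  if (is.null(model@calibration))
    stop("model has no ROC calibration; train with calibrateClassifier()")
  seqchr <- if (is(query, "LabeledSequence")) seqString(query) else
    toupper(query)
  inst <- encodeInstances(query, pssm = pssm, conservation = conservation,
                          window = model@window,
                          featureGroups = model@featureGroups,
                          mode = "prediction", table = table)
  o <- decisionValues(model, inst)
  op <- selectThreshold(model@calibration, kind, level)
  conf <- predictionConfidence(o, op$threshold, model@calibration)
  out <- data.frame(
    position = inst@position,
    residue = strsplit(seqchr, "")[[1]],
    output = o,
    call = ifelse(o >= op$threshold, "+", "-"),
    confidence = conf,
    level = confidenceLevel(conf),
    stringsAsFactors = FALSE)
  attr(out, "operatingPoint") <- op
  out
}

#' Render the per-residue prediction report
#'
#' Emits (a) a summary of the requested level and the counterpart estimate
#' from the calibration curve, (b) an overview in wrapped blocks of three
#' aligned lines -- sequence, '+'/'-' calls, 0-9 confidence-level digits --
#' and (c) a tab-separated detail table (position, residue, output, call,
#' confidence, level).
#'
#' @param predictions a prediction data.frame from
#'   \code{\link{predictResidues}} (with its operating-point attribute).
#' @param width residues per overview block (default 60).
#' @return character vector of report lines.
#' @export
renderReport <- function(predictions, width = 60L) {
  op <- attr(predictions, "operatingPoint")
  if (is.null(op))
    stop("predictions carry no operating point; use predictResidues()")
  n <- nrow(predictions)
  if (!identical(predictions$position, seq_len(n)))
    stop("predictions must cover every residue position exactly once")
  counterpart <- if (op$kind == "specificity")
    c("sensitivity", sprintf("%.2f%%", 100 * op$estSensitivity))
  else
    c("specificity", sprintf("%.2f%%", 100 * op$estSpecificity))
  lines <- c(
    "nabind binding-residue prediction",
    sprintf("Requested %s: %.2f%%", op$kind, 100 * op$level),
    sprintf("Estimated %s: %s", counterpart[1], counterpart[2]),
    sprintf("Output threshold: %.6g%s", op$threshold,
            if (op$saturated) " (saturated)" else ""),
    sprintf("Predicted binding residues: %d of %d",
            sum(predictions$call == "+"), n),
    "", "Overview:")
  seqchr <- paste(predictions$residue, collapse = "")
  calls <- paste(predictions$call, collapse = "")
  levs <- paste(predictions$level, collapse = "")
  starts <- seq.int(1L, n, by = width)
  for (s in starts) {
    e <- min(s + width - 1L, n)
    lines <- c(lines,
               sprintf("%6d %s %d", s, substr(seqchr, s, e), e),
               sprintf("       %s", substr(calls, s, e)),
               sprintf("       %s", substr(levs, s, e)))
  }
  lines <- c(lines, "", "Detail:",
             paste(c("position", "residue", "output", "call", "confidence",
                     "level"), collapse = "\t"),
             sprintf("%d\t%s\t%.6f\t%s\t%.4f\t%d",
                     predictions$position, predictions$residue,
                     predictions$output, predictions$call,
                     predictions$confidence, predictions$level))
  lines
}

#' Parse the detail table back out of a rendered report
#'
#' @param lines a report as returned by \code{\link{renderReport}} (or read
#'   from a report file).
#' @return data.frame with the detail-table columns.
#' @export
parseReportDetail <- function(lines) {
  hdr <- which(lines == "Detail:")
  if (length(hdr) != 1L)
    stop("not a nabind report: missing Detail section")
  body <- lines[(hdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  df$call <- as.character(df$call)
  df
}
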