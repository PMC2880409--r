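#' @import methods
NULL

#' LabeledSequence: a protein sequence with per-residue binding labels
#'
#' Holds a one-letter amino-acid sequence together with a per-residue label
#' track in \{+1, -1\} (+1 = nucleic-acid-binding residue) and the provenance
#' of the labels (structure and chain identifiers, or \code{"synthetic"}).
#'
#' @slot id character(1) sequence identifier.
#' @slot sequence character(1) one-letter amino-acid string.
#' @slot labels numeric vector of +1/-1, one per residue.
#' @slot source character(1) provenance, e.g. \code{"1abc_A"} or
#'   \code{"synthetic"}.
#'
#' @exportClass LabeledSequence
setClass("LabeledSequence",
  representation(
    id = "character",
    sequence = "character",
    labels = "numeric",
    source = "character"
  )
)

setValidity("LabeledSequence", function(object) {
  msg <- NULL
  if (length(object@sequence) != 1L)
    msg <- c(msg, "'sequence' must be a single string")
  if (nchar(object@sequence) != length(object@labels))
    msg <- c(msg, "length(labels) must equal nchar(sequence)")
  if (!all(object@labels %in% c(1, -1)))
    msg <- c(msg, "labels must be +1 or -1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LabeledSequence
#'
#' @param id sequence identifier.
#' @param sequence one-letter amino-acid string.
#' @param labels numeric vector of +1/-1, one per residue.
#' @param source provenance string.
#' @return a \linkS4class{LabeledSequence}.
#' @examples
#' LabeledSequence("toy", "ARNDK", c(-1, 1, -1, -1, 1))
#' @export
LabeledSequence <- function(id, sequence, labels, source = "synthetic") {
  new("LabeledSequence", id = as.character(id), sequence = toupper(sequence),
      labels = as.numeric(labels), source = as.character(source))
}

setMethod("show", "LabeledSequence", function(object) {
  n <- nchar(object@sequence)
  cat("LabeledSequence '", object@id, "' (", object@source, ")\n", sep = "")
  cat("  ", n, " residues, ", sum(object@labels == 1), " binding (",
      sprintf("%.1f%%", 100 * mean(object@labels == 1)), ")\n", sep = "")
})

#' PSSMProfile: per-position substitution scores from an iterative search
#'
#' A position-specific scoring matrix: one row per query position, 20 integer
#' log-odds substitution scores per row, in the column order emitted by
#' PSI-BLAST (\code{ARNDCQEGHILKMFPSTWYV}).
#'
#' @slot id character(1) query identifier.
#' @slot scores numeric matrix, n positions x 20 residues.
#' @slot residues character vector, the query residue at each position.
#'
#' @exportClass PSSMProfile
setClass("PSSMProfile",
  representation(
    id = "character",
    scores = "matrix",
    residues = "character"
  )
)

setValidity("PSSMProfile", function(object) {
  msg <- NULL
  if (ncol(object@scores) != 20L)
    msg <- c(msg, "scores must have exactly 20 columns")
  if (nrow(object@scores) != length(object@residues))
    msg <- c(msg, "one residue per score row required")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PSSMProfile", function(object) {
  cat("PSSMProfile '", object@id, "': ", nrow(object@scores),
      " positions x 20 scores\n", sep = "")
})

#' ConservationProfile: column statistics of biochemical features
#'
#' Per query position, the mean and population standard deviation of each
#' biochemical feature (H = hydrophobicity, K = side-chain pKa, M = molecular
#' mass) over the residues aligned to that position (query plus homologues).
#' Six raw numbers per position; scaled variants share the per-feature bounds
#' of the underlying feature table so that means are commensurate with
#' single-residue features.
#'
#' @slot id character(1) query identifier.
#' @slot stats numeric matrix, n positions x 6 columns
#'   (H_mean, H_sd, K_mean, K_sd, M_mean, M_sd), raw feature units.
#' @slot nobs integer vector, observations per column (query included).
#'
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(
    id = "character",
    stats = "matrix",
    nobs = "integer"
  )
)

setValidity("ConservationProfile", function(object) {
  msg <- NULL
  if (ncol(object@stats) != 6L)
    msg <- c(msg, "stats must have 6 columns (mean, sd per H, K, M)")
  if (nrow(object@stats) != length(object@nobs))
    msg <- c(msg, "one observation count per position required")
  sds <- object@stats[, c(2L, 4L, 6L), drop = FALSE]
  if (length(sds) && any(sds < -1e-12, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be non-negative")
  if (any(object@nobs < 1L))
    msg <- c(msg, "every column needs at least one observation")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile '", object@id, "': ", nrow(object@stats),
      " positions; median observations/column = ",
      stats::median(object@nobs), "\n", sep = "")
})

#' InstanceSet: windowed, encoded residue instances
#'
#' A dense matrix of fixed-length window encodings, one row per target
#' residue, with labels in \{+1, -1\} (NA in prediction mode), the source
#' sequence and target position of each row, and the encoding descriptor
#' (window size and active feature groups) that a classifier must match at
#' prediction time.
#'
#' @slot x numeric matrix of encoded instances, values in [0, 1].
#' @slot y numeric vector of +1/-1 labels (NA allowed in prediction mode).
#' @slot seqid character vector, source sequence id per instance.
#' @slot position integer vector, target residue position per instance.
#' @slot window integer(1) window size (odd).
#' @slot featureGroups character vector, subset of
#'   \code{c("hkm", "descriptors", "pssm")}.
#'
#' @exportClass InstanceSet
setClass("InstanceSet",
  representation(
    x = "matrix",
    y = "numeric",
    seqid = "character",
    position = "integer",
    window = "integer",
    featureGroups = "character"
  )
)

setValidity("InstanceSet", function(object) {
  msg <- NULL
  n <- nrow(object@x)
  if (length(object@y) != n || length(object@seqid) != n ||
      length(object@position) != n)
    msg <- c(msg, "y, seqid and position must have one entry per row of x")
  ok <- object@y[!is.na(object@y)]
  if (!all(ok %in% c(1, -1)))
    msg <- c(msg, "labels must be +1, -1 or NA")
  if (length(object@window) != 1L || object@window < 1L ||
      object@window %% 2L == 0L)
    msg <- c(msg, "window must be a single odd positive integer")
  if (!all(object@featureGroups %in% c("hkm", "descriptors", "pssm")))
    msg <- c(msg, "featureGroups must be among hkm/descriptors/pssm")
  expected <- object@window * blockWidth(object@featureGroups)
  if (n > 0L && ncol(object@x) != expected)
    msg <- c(msg, sprintf("x has %d columns; descriptor implies %d",
                          ncol(object@x), expected))
  if (n > 0L && (min(object@x) < -1e-9 || max(object@x) > 1 + 1e-9))
    msg <- c(msg, "encoded values must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "InstanceSet", function(object) {
  cat("InstanceSet: ", nrow(object@x), " instances x ", ncol(object@x),
      " features (w = ", object@window, "; groups: ",
      paste(object@featureGroups, collapse = "+"), ")\n", sep = "")
  if (!all(is.na(object@y)))
    cat("  positives: ", sum(object@y == 1, na.rm = TRUE), " (",
        sprintf("%.1f%%", 100 * mean(object@y == 1, na.rm = TRUE)),
        ")\n", sep = "")
})

#' ROCCalibration: threshold table, AUC and calibration score distributions
#'
#' The receiver operating characteristic of a classifier obtained by sweeping
#' its output threshold: per threshold the true positive rate (sensitivity)
#' and false positive rate (1 - specificity); the trapezoidal area under the
#' curve; and the empirical score distributions of calibration positives and
#' negatives, kept for operating-point selection and confidence scoring.
#'
#' @slot points data.frame with columns threshold, tpr, fpr, sensitivity,
#'   specificity, ordered by increasing threshold.
#' @slot auc numeric(1) area under the curve.
#' @slot posScores numeric vector, classifier outputs of calibration positives.
#' @slot negScores numeric vector, outputs of calibration negatives.
#'
#' @exportClass ROCCalibration
setClass("ROCCalibration",
  representation(
    points = "data.frame",
    auc = "numeric",
    posScores = "numeric",
    negScores = "numeric"
  )
)

setValidity("ROCCalibration", function(object) {
  msg <- NULL
  p <- object@points
  need <- c("threshold", "tpr", "fpr", "sensitivity", "specificity")
  if (!all(need %in% names(p)))
    msg <- c(msg, "points must have threshold/tpr/fpr/sensitivity/specificity")
  else {
    if (is.unsorted(p$threshold))
      msg <- c(msg, "thresholds must be increasing")
    if (any(diff(p$tpr) > 1e-12) || any(diff(p$fpr) > 1e-12))
      msg <- c(msg, "tpr and fpr must be non-increasing in threshold")
  }
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(object@posScores) == 0L || length(object@negScores) == 0L)
    msg <- c(msg, "both score distributions must be non-empty")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ROCCalibration", function(object) {
  cat("ROCCalibration: ", nrow(object@points), " thresholds, AUC = ",
      sprintf("%.4f", object@auc), " (", length(object@posScores), " pos / ",
      length(object@negScores), " neg calibration scores)\n", sep = "")
})

#' BindingClassifier: a trained RBF-kernel max-margin model
#'
#' Wraps a fitted support-vector machine together with its kernel parameters,
#' the encoding descriptor it was trained under (checked at prediction time),
#' an optional cross-validated \linkS4class{ROCCalibration}, and training
#' metadata.
#'
#' @slot fit the fitted svm object.
#' @slot params list with gamma, C and classWeightRatio.
#' @slot window integer(1) window size of the training encoding.
#' @slot featureGroups character vector of the training encoding.
#' @slot calibration the cross-validated ROC calibration, or NULL.
#' @slot meta list of training metadata (n instances, seed, date, data hash).
#'
#' @exportClass BindingClassifier
setClass("BindingClassifier",
  representation(
    fit = "ANY",
    params = "list",
    window = "integer",
    featureGroups = "character",
    calibration = "ANY",
    meta = "list"
  )
)

setValidity("BindingClassifier", function(object) {
  msg <- NULL
  p <- object@params
  if (!is.numeric(p$gamma) || p$gamma <= 0)
    msg <- c(msg, "gamma must be positive")
  if (!is.numeric(p$C) || p$C <= 0)
    msg <- c(msg, "C must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "BindingClassifier", function(object) {
  cat("BindingClassifier: RBF kernel, gamma = ", object@params$gamma,
      ", C = ", object@params$C, "\n", sep = "")
  cat("  encoding: w = ", object@window, ", groups: ",
      paste(object@featureGroups, collapse = "+"), "\n", sep = "")
  if (!is.null(object@calibration))
    cat("  calibrated: AUC = ", sprintf("%.4f", object@calibration@auc),
        "\n", sep = "")
})
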