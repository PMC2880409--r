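# Classifier evaluation: confusion counts, the balanced performance
# measures (accuracy, sensitivity, specificity, strength = the average of
# sensitivity and specificity, Matthews correlation), ROC curves by
# threshold sweep, trapezoidal AUC, and fivefold cross-validation with
# pooled test predictions.

#' Confusion counts at a threshold
#'
#' An instance is called positive iff its score is at least the threshold
#' (ties to positive).
#'
#' @param labels numeric vector of +1/-1 reference labels.
#' @param scores numeric vector of classifier outputs, same length.
#' @param threshold decision threshold.
#' @return named numeric(4): TP, TN, FP, FN.
#' @examples
#' confusionCounts(c(1, 1, -1, -1), c(0.9, 0.2, 0.8, 0.1), 0.5)
#' @export
confusionCounts <- function(labels, scores, threshold) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (length(labels) == 0L)
    stop("empty evaluation: no instances")
  if (!all(labels %in% c(1, -1)))
    stop("labels must be +1 or -1")
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1), TN = sum(!pred & labels == -1),
    FP = sum(pred & labels == -1), FN = sum(!pred & labels == 1))
}

#' Accuracy, sensitivity, specificity and strength from confusion counts
#'
#' accuracy = (TP + TN) / N; sensitivity = TP / (TP + FN); specificity =
#' TN / (TN + FP); strength = (sensitivity + specificity) / 2. A zero
#' denominator yields the value 0 and sets the \code{degenerate} flag
#' rather than failing mid-sweep.
#'
#' @param counts named vector with TP, TN, FP, FN (see
#'   \code{\link{confusionCounts}}).
#' @return list with accuracy, sensitivity, specificity, strength,
#'   degenerate.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0)
    stop("empty evaluation: zero instances in confusion counts")
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  list(accuracy = (tp + tn) / total, sensitivity = sens,
       specificity = spec, strength = (sens + spec) / 2,
       degenerate = degenerate)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); any zero
#' factor in the denominator gives 0 by convention.
#'
#' @param counts named vector with TP, TN, FP, FN.
#' @return numeric in [-1, 1].
#' @export
matthewsCC <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over every distinct score (tied scores
#' grouped) plus the two sentinel extremes, recording the true positive
#' rate (sensitivity) against the false positive rate (1 - specificity) at
#' each threshold, with the prediction rule score >= threshold. The
#' calibration also keeps the empirical score distributions of positives
#' and negatives for confidence scoring.
#'
#' @param labels numeric vector of +1/-1 labels (both classes required).
#' @param scores numeric vector of classifier outputs.
#' @return a \linkS4class{ROCCalibration}.
#' @export
rocPoints <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("undefined ROC: both classes must be present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sp <- sort(pos)
  sn <- sort(neg)
  # #(x >= t) = n - #(x < t), vectorized over thresholds
  tp <- length(sp) - findInterval(thr, sp, left.open = TRUE)
  fp <- length(sn) - findInterval(thr, sn, left.open = TRUE)
  tpr <- tp / length(sp)
  fpr <- fp / length(sn)
  pts <- data.frame(threshold = thr, tpr = tpr, fpr = fpr,
                    sensitivity = tpr, specificity = 1 - fpr)
  roc <- new("ROCCalibration", points = pts, auc = 0,
             posScores = pos, negScores = neg)
  roc@auc <- aucTrapezoid(roc)
  validObject(roc)
  roc
}

#' Trapezoidal area under the ROC curve
#'
#' Integrates the staircase over FPR in [0, 1]; with tied scores grouped
#' this equals the tie-corrected Mann-Whitney statistic divided by
#' (n+ * n-): the probability that a random positive outscores a random
#' negative, ties counted half.
#'
#' @param roc a \linkS4class{ROCCalibration}.
#' @return numeric in [0, 1].
#' @export
aucTrapezoid <- function(roc) {
  p <- roc@points[order(roc@points$fpr, roc@points$tpr), ]
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Stratified k-fold cross-validation of the binding classifier
#'
#' Positive and negative instances are distributed randomly into k folds
#' (stratified, so each fold keeps the dataset's class balance). Each fold
#' is scored by the model trained on the other k - 1 folds, and the test
#' predictions of all folds are pooled for metric and ROC computation.
#' Optionally folds can be formed at the sequence level so overlapping
#' windows of one sequence never straddle folds.
#'
#' @param instances an \linkS4class{InstanceSet} with both classes, each
#'   with at least k members.
#' @param gamma,C,classWeightRatio kernel / solver parameters (see
#'   \code{\link{trainClassifier}}).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param groupBySequence if TRUE, whole sequences are assigned to folds.
#' @return list with \code{labels}, \code{scores} (pooled, in instance
#'   order), \code{fold} (assignment), and \code{params}.
#' @export
crossValidate <- function(instances, gamma = 0.1, C = 1,
                          classWeightRatio = 1, k = 5L, seed = 1L,
                          groupBySequence = FALSE) {
  stopifnot(is(instances, "InstanceSet"))
  y <- instanceLabels(instances)
  if (any(is.na(y)))
    stop("cross-validation needs labelled instances")
  n <- length(y)
  k <- as.integer(k)
  set.seed(as.integer(seed))
  if (groupBySequence) {
    ids <- unique(instances@seqid)
    if (length(ids) < k)
      stop("fewer sequences than folds")
    gf <- sample(rep_len(seq_len(k), length(ids)))
    fold <- gf[match(instances@seqid, ids)]
  } else {
    if (sum(y == 1) < k || sum(y == -1) < k)
      stop("each class needs at least k = ", k, " instances")
    fold <- integer(n)
    for (cls in c(1, -1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  x <- instanceMatrix(instances)
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    trainSet <- new("InstanceSet", x = x[!test, , drop = FALSE],
                    y = y[!test], seqid = instances@seqid[!test],
                    position = instances@position[!test],
                    window = instances@window,
                    featureGroups = instances@featureGroups)
    model <- trainClassifier(trainSet, gamma = gamma, C = C,
                             classWeightRatio = classWeightRatio,
                             seed = seed)
    scores[test] <- decisionValues(model, x[test, , drop = FALSE])
  }
  list(labels = y, scores = scores, fold = fold,
       params = list(gamma = gamma, C = C,
                     classWeightRatio = classWeightRatio, k = k,
                     seed = as.integer(seed)))
}

#' Train a classifier and attach its cross-validated ROC calibration
#'
#' Runs \code{\link{crossValidate}} with the given parameters, builds the
#' pooled \linkS4class{ROCCalibration}, then fits the final model on all
#' instances and stores the calibration in it. The calibration is what
#' operating-point selection and confidence scoring consult at prediction
#' time.
#'
#' @inheritParams crossValidate
#' @return a calibrated \linkS4class{BindingClassifier}.
#' @export
calibrateClassifier <- function(instances, gamma = 0.1, C = 1,
                                classWeightRatio = 1, k = 5L, seed = 1L) {
  cv <- crossValidate(instances, gamma = gamma, C = C,
                      classWeightRatio = classWeightRatio, k = k,
                      seed = seed)
  roc <- rocPoints(cv$labels, cv$scores)
  model <- trainClassifier(instances, gamma = gamma, C = C,
                           classWeightRatio = classWeightRatio, seed = seed)
  model@calibration <- roc
  model
}

#' Evaluation summary at a threshold
#'
#' Convenience wrapper: confusion counts, the four balanced measures, MCC
#' and the ROC AUC of a pooled prediction set.
#'
#' @param labels,scores pooled +1/-1 labels and classifier outputs.
#' @param threshold decision threshold (default 0).
#' @return list with counts, accuracy, sensitivity, specificity, strength,
#'   mcc, auc.
#' @export
evaluationSummary <- function(labels, scores, threshold = 0) {
  counts <- confusionCounts(labels, scores, threshold)
  m <- classificationMetrics(counts)
  list(counts = counts, accuracy = m$accuracy,
       sensitivity = m$sensitivity, specificity = m$specificity,
       strength = m$strength, mcc = matthewsCC(counts),
       auc = rocAUC(rocPoints(labels, scores)))
}
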