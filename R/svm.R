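# RBF-kernel max-margin classification.
#
# The kernel is K(x1, x2) = exp(-gamma * ||x1 - x2||^2): a smaller gamma
# gives a smoother decision boundary, and the regularization factor C trades
# training error against margin width. The quadratic-programming solver
# behind the fit is libsvm (via e1071), used as an off-the-shelf max-margin
# engine behind a thin contract: fit + real-valued decision outputs.

#' The radial basis function kernel
#'
#' @param x1,x2 equal-length numeric vectors.
#' @param gamma non-negative kernel width parameter.
#' @return exp(-gamma * ||x1 - x2||^2), in (0, 1]; 1 iff x1 = x2 when
#'   gamma > 0.
#' @examples
#' rbfKernel(c(0, 0), c(1, 1), gamma = 0.5)  # exp(-1)
#' @export
rbfKernel <- function(x1, x2, gamma) {
  if (length(x1) != length(x2))
    stop("dimension mismatch: vectors of length ", length(x1), " and ",
         length(x2))
  if (gamma < 0)
    stop("gamma must be non-negative")
  exp(-gamma * sum((x1 - x2)^2))
}

svmFeatureMatrix <- function(instances) {
  if (is(instances, "InstanceSet")) instanceMatrix(instances) else
    as.matrix(instances)
}

#' Train the binding-residue classifier
#'
#' Fits an RBF-kernel support vector machine on encoded window instances.
#' The returned model keeps the encoding descriptor of its training set and
#' refuses to score instances encoded differently.
#'
#' @param instances an \linkS4class{InstanceSet} with both classes present.
#' @param gamma RBF kernel width (> 0).
#' @param C regularization factor (> 0).
#' @param classWeightRatio weight of the positive class relative to the
#'   negative (default 1: no reweighting; operating points come from
#'   threshold sweeps instead).
#' @param seed integer seed for the (rarely exercised) stochastic parts of
#'   the solver; recorded in the metadata.
#' @param tolerance solver termination tolerance.
#' @return a \linkS4class{BindingClassifier}.
#' @export
trainClassifier <- function(instances, gamma = 0.1, C = 1,
                            classWeightRatio = 1, seed = 1L,
                            tolerance = 1e-3) {
  stopifnot(is(instances, "InstanceSet"))
  y <- instanceLabels(instances)
  if (any(is.na(y)))
    stop("training instances must be labelled")
  if (length(unique(y)) < 2L)
    stop("single-class input: training needs both positive and negative ",
         "instances")
  x <- instanceMatrix(instances)
  set.seed(as.integer(seed))
  wts <- if (classWeightRatio != 1)
    c("1" = classWeightRatio, "-1" = 1) else NULL
  fit <- e1071::svm(x = x, y = factor(y, levels = c("1", "-1")),
                    scale = FALSE, kernel = "radial", gamma = gamma,
                    cost = C, class.weights = wts, tolerance = tolerance,
                    probability = FALSE, fitted = FALSE, cachesize = 256)
  new("BindingClassifier", fit = fit,
      params = list(gamma = gamma, C = C,
                    classWeightRatio = classWeightRatio),
      window = instances@window, featureGroups = instances@featureGroups,
      calibration = NULL,
      meta = list(nInstances = nrow(x), nPositive = sum(y == 1),
                  seed = as.integer(seed), date = as.character(Sys.Date()),
                  dataHash = signif(sum(x) + sum(y), 12)))
}

#' Real-valued classifier outputs for a batch of instances
#'
#' Higher output means more binding-like; thresholding at t yields hard
#' calls. Scores are oriented so that positive-class instances score high
#' regardless of the solver's internal class ordering, and are invariant to
#' the order of instances in the batch.
#'
#' @param model a \linkS4class{BindingClassifier}.
#' @param instances an \linkS4class{InstanceSet} with the same encoding
#'   descriptor as the training set, or a bare matrix with matching columns.
#' @return numeric vector of decision values, one per instance.
#' @export
decisionValues <- function(model, instances) {
  stopifnot(is(model, "BindingClassifier"))
  if (is(instances, "InstanceSet")) {
    if (instances@window != model@window ||
        !identical(instances@featureGroups, model@featureGroups))
      stop("encoding descriptor mismatch: model trained with w = ",
           model@window, ", groups ",
           paste(model@featureGroups, collapse = "+"))
  }
  x <- svmFeatureMatrix(instances)
  pred <- stats::predict(model@fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  scores <- as.numeric(dv[, 1])
  # libsvm signs the decision value toward the first training class seen;
  # orient so that '+1' is always the high side
  lab <- colnames(dv)[1]
  if (identical(lab, "-1/1")) scores <- -scores
  scores
}

#' Cross-validated grid search over kernel parameters
#'
#' Evaluates every (gamma, C) cell by k-fold cross-validation and returns
#' the cell maximizing the chosen criterion: \code{"strength"} (the average
#' of sensitivity and specificity at threshold 0) or \code{"auc"}. Ties go
#' to the smaller C, then the smaller gamma (preferring stronger
#' regularization and a smoother boundary).
#'
#' @param instances an \linkS4class{InstanceSet}.
#' @param gammaGrid,CGrid numeric vectors of candidate values.
#' @param folds number of cross-validation folds (default 5).
#' @param criterion \code{"strength"} or \code{"auc"}.
#' @param seed integer seed controlling fold assignment.
#' @return list with \code{best} (list: gamma, C, score) and \code{table}
#'   (data.frame of every cell's cross-validated score).
#' @export
gridSearch <- function(instances,
                       gammaGrid = c(0.01, 0.05, 0.1, 0.5, 1),
                       CGrid = c(0.5, 1, 2, 5, 10),
                       folds = 5L, criterion = c("strength", "auc"),
                       seed = 1L) {
  criterion <- match.arg(criterion)
  if (length(gammaGrid) == 0L || length(CGrid) == 0L)
    stop("empty parameter grid")
  grid <- expand.grid(gamma = sort(gammaGrid), C = sort(CGrid))
  grid$score <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cv <- crossValidate(instances, gamma = grid$gamma[r], C = grid$C[r],
                        k = folds, seed = seed)
    grid$score[r] <- if (criterion == "auc") {
      rocAUC(rocPoints(cv$labels, cv$scores))
    } else {
      m <- classificationMetrics(confusionCounts(cv$labels, cv$scores, 0))
      m$strength
    }
  }
  # argmax with documented tie-break: smaller C first, then smaller gamma
  ord <- order(-grid$score, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(best = list(gamma = best$gamma, C = best$C, score = best$score),
       table = grid)
}

#' Persist / restore a trained classifier
#'
#' The archive carries the fitted solver state, kernel parameters, encoding
#' descriptor, calibration and metadata, with a format version tag.
#'
#' @param model a \linkS4class{BindingClassifier}.
#' @param path archive path.
#' @return \code{readClassifier} returns the restored
#'   \linkS4class{BindingClassifier}.
#' @export
saveClassifier <- function(model, path) {
  stopifnot(is(model, "BindingClassifier"))
  saveRDS(list(format = "nabind-classifier-1", model = model), path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
readClassifier <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "nabind-classifier-1"))
    stop("not a nabind classifier archive: ", path)
  obj$model
}
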