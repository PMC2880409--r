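test_that("confusion counts partition the instances with ties positive", {
  labs <- c(1, 1, 1, 1, -1, -1, -1, -1, -1)
  scores <- c(1, 1, 1, -1, -1, -1, -1, -1, 1)  # predictions at threshold 0
  cc <- confusionCounts(labs, scores, 0)
  expect_equal(unname(cc[c("TP", "FN", "TN", "FP")]), c(3, 1, 4, 1))
  expect_equal(sum(cc), 9)
  # saturated case
  cc2 <- confusionCounts(rep(1, 4), rep(2, 4), 0)
  expect_equal(unname(cc2), c(4, 0, 0, 0))
  # threshold above every score
  cc3 <- confusionCounts(labs, scores, 10)
  expect_equal(unname(cc3[c("TP", "FP")]), c(0, 0))
  expect_error(confusionCounts(1, c(1, 2), 0), "equal length")
})

test_that("the balanced measures follow their defining ratios", {
  cc <- c(TP = 3, TN = 4, FP = 1, FN = 1)
  m <- classificationMetrics(cc)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$strength, 0.775)
  expect_equal(m$accuracy, 7 / 9)
  expect_false(m$degenerate)
  # perfect classifier
  p <- classificationMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(p[c("accuracy", "sensitivity", "specificity",
                          "strength")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 strength = 1))
  # zero denominator: value 0 plus the degeneracy flag, no exception
  d <- classificationMetrics(c(TP = 0, TN = 3, FP = 1, FN = 0))
  expect_equal(d$sensitivity, 0)
  expect_true(d$degenerate)
})

test_that("MCC matches direct arithmetic and its extremes", {
  expect_equal(matthewsCC(c(TP = 5, TN = 7, FP = 0, FN = 0)), 1.0)
  expect_equal(matthewsCC(c(TP = 0, TN = 0, FP = 5, FN = 7)), -1.0)
  expect_equal(matthewsCC(c(TP = 3, TN = 4, FP = 1, FN = 1)), 11 / 20)
  set.seed(6)
  for (rep in 1:100) {
    cc <- c(TP = sample(0:30, 1), TN = sample(0:30, 1),
            FP = sample(0:30, 1), FN = sample(0:30, 1))
    if (sum(cc) == 0) next
    expect_equal(matthewsCC(cc),
                 mccOracle(cc[["TP"]], cc[["TN"]], cc[["FP"]], cc[["FN"]]))
  }
})

test_that("ROC endpoints, perfect separation and tie handling are right", {
  perfect <- rocPoints(c(1, 1, -1, -1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(rocAUC(perfect), 1.0)
  p <- rocPointsTable(perfect)
  expect_equal(p$tpr[1], 1); expect_equal(p$fpr[1], 1)      # threshold -Inf
  expect_equal(p$tpr[nrow(p)], 0); expect_equal(p$fpr[nrow(p)], 0)
  expect_true(any(p$fpr == 0 & p$tpr == 1))                  # passes (0, 1)

  flat <- rocPoints(c(1, -1, 1, -1), rep(0.5, 4))
  expect_equal(rocAUC(flat), 0.5)

  mixed <- rocPoints(c(1, 1, -1, -1), c(0.8, 0.3, 0.5, 0.1))
  expect_equal(rocAUC(mixed), 0.75)  # 3 of 4 concordant pairs

  expect_error(rocPoints(c(1, 1), c(0.5, 0.2)), "undefined ROC")
})

test_that("trapezoidal AUC equals the concordant-pair oracle with ties", {
  set.seed(99)
  for (rep in 1:40) {
    npos <- sample(2:25, 1); nneg <- sample(2:25, 1)
    # coarse grid forces plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), npos + nneg, replace = TRUE)
    labels <- rep(c(1, -1), c(npos, nneg))
    roc <- rocPoints(labels, scores)
    expect_equal(rocAUC(roc), aucPairwiseOracle(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("threshold sweeps are monotone and strength is the midpoint", {
  set.seed(21)
  labels <- rep(c(1, -1), c(30, 170))
  scores <- rnorm(200) + 0.8 * (labels == 1)
  roc <- rocPointsTable(rocPoints(labels, scores))
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  for (t in sample(scores, 25)) {
    m <- classificationMetrics(confusionCounts(labels, scores, t))
    expect_equal(m$strength, (m$sensitivity + m$specificity) / 2)
  }
  # metrics are invariant under instance permutation
  perm <- sample(200)
  expect_equal(
    classificationMetrics(confusionCounts(labels[perm], scores[perm], 0.3)),
    classificationMetrics(confusionCounts(labels, scores, 0.3)))
  expect_equal(rocAUC(rocPoints(labels[perm], scores[perm])),
               rocAUC(rocPoints(labels, scores)))
})

test_that("stratified five-fold partitioning is balanced and deterministic", {
  toy <- separableToySet(nPerClass = 50, seed = 31)
  cv <- crossValidate(toy, gamma = 0.5, C = 1, k = 5, seed = 17)
  expect_length(cv$scores, 100)
  expect_equal(as.integer(table(cv$fold)), rep(20L, 5))
  # stratification keeps the class balance in every fold
  for (f in 1:5)
    expect_equal(sum(cv$labels[cv$fold == f] == 1), 10)
  cv2 <- crossValidate(toy, gamma = 0.5, C = 1, k = 5, seed = 17)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$scores, cv2$scores)
  # separable data: pooled AUC is essentially perfect
  expect_gte(rocAUC(rocPoints(cv$labels, cv$scores)), 0.99)
  expect_error(crossValidate(separableToySet(nPerClass = 3), k = 5),
               "at least k")
})

test_that("sequence-grouped folding keeps windows of a sequence together", {
  ds <- synthDataset(synthSpec(nSequences = 10, length = 40, seed = 12))
  inst <- encodeDataset(ds, window = 5, featureGroups = "hkm")
  cv <- crossValidate(inst, gamma = 0.1, C = 1, k = 5, seed = 3,
                      groupBySequence = TRUE)
  for (id in unique(inst@seqid))
    expect_length(unique(cv$fold[inst@seqid == id]), 1)
})
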