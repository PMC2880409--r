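test_that("the RBF kernel matches its closed form", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2), 0.7), 1.0)
  expect_equal(rbfKernel(c(0, 0), c(3, 4), 0), 1.0)
  expect_equal(rbfKernel(c(0, 0), c(1, 1), 0.5), exp(-1), tolerance = 1e-12)
  expect_equal(rbfKernel(c(0, 0), c(1, 1), 0.5), 0.3679, tolerance = 1e-4)
  # symmetry
  x <- runif(5); y <- runif(5)
  expect_equal(rbfKernel(x, y, 0.3), rbfKernel(y, x, 0.3))
  expect_error(rbfKernel(1:3, 1:4, 1), "dimension")
  expect_error(rbfKernel(1:3, 2:4, -1), "non-negative")
})

test_that("kernel matrices are symmetric positive semi-definite", {
  set.seed(3)
  for (gamma in c(0.05, 0.5, 2)) {
    x <- matrix(runif(30 * 4), 30)
    K <- outer(seq_len(30), seq_len(30),
               Vectorize(function(i, j) rbfKernel(x[i, ], x[j, ], gamma)))
    expect_equal(K, t(K))
    expect_true(all(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-8))
  }
})

test_that("a separable toy problem is fit perfectly and orientation is right", {
  toy <- separableToySet()
  model <- trainClassifier(toy, gamma = 0.5, C = 10, seed = 1)
  scores <- decisionValues(model, toy)
  y <- instanceLabels(toy)
  # every positive scores above every negative
  expect_gt(min(scores[y == 1]), max(scores[y == -1]))
  expect_equal(unname(confusionCounts(y, scores, 0)[c("FP", "FN")]),
               c(0, 0))
})

test_that("flipping the labels negates the score ordering", {
  toy <- separableToySet(seed = 5)
  flipped <- new("InstanceSet", x = instanceMatrix(toy),
                 y = -instanceLabels(toy), seqid = toy@seqid,
                 position = toy@position, window = 1L,
                 featureGroups = "hkm")
  s1 <- decisionValues(trainClassifier(toy, 0.5, 5), toy)
  s2 <- decisionValues(trainClassifier(flipped, 0.5, 5), toy)
  expect_equal(order(s1), order(-s2))
})

test_that("scores are stateless in batch order and under duplication", {
  toy <- separableToySet(seed = 2)
  model <- trainClassifier(toy, gamma = 0.5, C = 2)
  x <- instanceMatrix(toy)
  s <- decisionValues(model, x)
  perm <- sample(nrow(x))
  expect_equal(decisionValues(model, x[perm, ]), s[perm])
  expect_equal(decisionValues(model, x[rep(1:5, 3), ]),
               rep(s[1:5], 3))
})

test_that("training a duplicated dataset leaves the boundary unchanged", {
  toy <- separableToySet(seed = 7)
  dup <- bindInstanceSets(toy, toy)
  m1 <- trainClassifier(toy, gamma = 0.5, C = 2)
  m2 <- trainClassifier(dup, gamma = 0.5, C = 2)
  probe <- matrix(runif(60), ncol = 3)
  expect_equal(decisionValues(m1, probe), decisionValues(m2, probe),
               tolerance = 1e-2)
})

test_that("single-class input and unlabeled instances are refused", {
  toy <- separableToySet()
  onlyPos <- new("InstanceSet", x = instanceMatrix(toy)[1:20, ],
                 y = rep(1, 20), seqid = toy@seqid[1:20],
                 position = toy@position[1:20], window = 1L,
                 featureGroups = "hkm")
  expect_error(trainClassifier(onlyPos, 0.5, 1), "single-class")
})

test_that("prediction refuses a mismatched encoding descriptor", {
  toy <- separableToySet()
  model <- trainClassifier(toy, 0.5, 1)
  other <- new("InstanceSet", x = matrix(runif(45), ncol = 9),
               y = rep(c(1, -1), c(3, 2)), seqid = rep("z", 5),
               position = 1:5, window = 3L, featureGroups = "hkm")
  expect_error(decisionValues(model, other), "descriptor mismatch")
})

test_that("grid search returns the argmax with the documented tie-break", {
  toy <- separableToySet(nPerClass = 15, seed = 4)
  single <- gridSearch(toy, gammaGrid = 0.5, CGrid = 2, folds = 3,
                       criterion = "auc", seed = 1)
  expect_equal(single$best$gamma, 0.5)
  expect_equal(single$best$C, 2)
  expect_equal(nrow(single$table), 1)

  gs <- gridSearch(toy, gammaGrid = c(0.1, 1), CGrid = c(1, 5), folds = 3,
                   criterion = "auc", seed = 1)
  expect_equal(gs$best$score, max(gs$table$score))
  # separable data: some cell reaches AUC 1
  expect_equal(gs$best$score, 1.0)
  # all four cells tie at 1; the smallest C then smallest gamma must win
  if (all(gs$table$score == 1)) {
    expect_equal(gs$best$C, 1)
    expect_equal(gs$best$gamma, 0.1)
  }
  expect_error(gridSearch(toy, numeric(0), 1), "empty")
})

test_that("classifiers survive the archive round trip", {
  toy <- separableToySet()
  model <- calibrateClassifier(toy, gamma = 0.5, C = 2, k = 3, seed = 2)
  path <- tempfile(fileext = ".rds")
  saveClassifier(model, path)
  back <- readClassifier(path)
  expect_equal(decisionValues(back, toy), decisionValues(model, toy))
  expect_equal(rocAUC(back@calibration), rocAUC(model@calibration))
  saveRDS(list(format = "other"), path)
  expect_error(readClassifier(path), "not a nabind classifier")
})
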