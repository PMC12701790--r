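test_that("AUC matches the brute-force pair-counting oracle", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # swapping one positive/negative score pair drops one of four pairs
  expect_equal(aucScore(c(0.9, 0.3, 0.8, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    s <- rnorm(n)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(aucScore(s, y), aucBrute(s, y))
    # with ties
    st <- round(s, 1)
    expect_equal(aucScore(st, y), aucBrute(st, y))
  }
  expect_error(aucScore(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  s <- rnorm(40); y <- rep(c(TRUE, FALSE), 20)
  a0 <- aucScore(s, y)
  expect_equal(aucScore(exp(s), y), a0)
  expect_equal(aucScore(5 * s - 2, y), a0)
  expect_equal(aucScore(atan(s), y), a0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  s <- rnorm(60); y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  expect_equal(aucScore(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("accuracy by argmax and the evaluation dispatcher work", {
  sc <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(accuracyScore(sc, factor(c("a", "b"))), 1)
  expect_equal(accuracyScore(sc, factor(c("b", "a"))), 0)
  ev <- evaluateScores(sc, factor(c("a", "b")))
  expect_identical(ev$metric, "auc")
  sc3 <- diag(3); colnames(sc3) <- c("a", "b", "c")
  ev3 <- evaluateScores(sc3, factor(c("a", "b", "c")))
  expect_identical(ev3$metric, "accuracy")
  expect_equal(ev3$value, 1)
})

test_that("stratified folds balance classes", {
  y <- factor(rep(c("a", "b"), c(40, 20)))
  f <- stratifiedFolds(y, k = 10, seed = 3)
  expect_true(all(table(f, y)[, "a"] == 4))
  expect_true(all(table(f, y)[, "b"] == 2))
  expect_identical(f, stratifiedFolds(y, k = 10, seed = 3))
})

test_that("[0,1] normalization is train-anchored and unclipped", {
  train <- cbind(c(2, 4), c(7, 7))
  expect_equal(normalize01(train)[, 1], c(0, 1))
  expect_equal(normalize01(train)[, 2], c(0, 0))
  expect_equal(normalize01(train, matrix(c(5, 7), 1))[1, 1], 1.5)
  expect_true(all(normalize01(train) >= 0 & normalize01(train) <= 1))
})

test_that("the grid search selects within the grid and separates a toy set", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 4), 15))
  y <- factor(rep(c("neg", "pos"), each = 15))
  grid <- svmGrid(cost = c(1, 10), gamma = c(0.01, 0.1))
  fit <- fitSvm(x, y, grid = grid, seed = 2)
  expect_true(fit$cost %in% grid$cost)
  expect_true(fit$gamma %in% grid$gamma)
  tr_scores <- svmScores(fit, x)
  expect_equal(accuracyScore(tr_scores, y), 1)
  # one-point grid: that point is selected
  fit1 <- fitSvm(x, y, grid = svmGrid(cost = 3, gamma = 0.05), seed = 2)
  expect_equal(fit1$cost, 3)
  expect_equal(fit1$gamma, 0.05)
})

test_that("the dataset-level SVM protocol never reads the test partition", {
  se <- generateSynthData(30, 24, "mean_shift", effect_size = 1.5, seed = 44)
  grid <- svmGrid(cost = c(1, 100), gamma = c(0.01, 1))
  r1 <- fitSvmOnDataset(se, grid = grid, seed = 5)
  # scramble the test features; training-side selection must be identical
  se2 <- se
  te <- which(se2$split == "test")
  a <- SummarizedExperiment::assay(se2, "features")
  a[, te] <- a[, sample(te), drop = FALSE] * 10 + 3
  SummarizedExperiment::assay(se2, "features") <- a
  r2 <- fitSvmOnDataset(se2, grid = grid, seed = 5)
  expect_identical(r1$fit$cost, r2$fit$cost)
  expect_identical(r1$fit$gamma, r2$fit$gamma)
  expect_identical(r1$fit$cv_scores, r2$fit$cv_scores)
  expect_identical(r1$norm_shift, r2$norm_shift)
  expect_identical(r1$train_scores, r2$train_scores)
})
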