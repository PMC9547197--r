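test_that("parameter count matches the closed form and init is seeded", {
  m <- buildMLP(100, seed = 1)
  # dense: 128 d + 128 + 64*128 + 64 + 16*64 + 16 + 8*16 + 8;
  # batch-norm affine terms: 2 * (128 + 64 + 16)
  dense <- 128 * 100 + 128 + 64 * 128 + 64 + 16 * 64 + 16 + 8 * 16 + 8
  bn <- 2 * (128 + 64 + 16)
  expect_identical(nParams(m), as.integer(dense + bn))
  m2 <- buildMLP(100, seed = 1)
  expect_identical(m@params, m2@params)
  m3 <- buildMLP(100, seed = 2)
  expect_false(identical(m@params, m3@params))
  expect_error(buildMLP(0), "inputDim")
})

test_that("probabilities are in (0,1), batch-independent and row-wise", {
  m <- buildMLP(20, seed = 6)
  set.seed(1)
  x <- matrix(rnorm(200), 10, 20)
  p <- predictProba(m, x)
  expect_true(all(p > 0 & p < 1))
  # evaluation mode: same cell alone or inside a batch
  expect_equal(p[4], predictProba(m, x[4, , drop = FALSE]), tolerance = 1e-6)
  # duplicated cell, duplicated probability
  p2 <- predictProba(m, x[c(1, 1, 2), ])
  expect_identical(p2[1], p2[2])
  expect_error(predictProba(m, x[, 1:7]), "dimension")
})

test_that("training solves a linearly separable toy problem", {
  fx <- toyTrainedModel()
  pVal <- predictProba(fx$model, fx$x[fx$vaIdx, ])
  acc <- mean((pVal >= 0.5) == (fx$y[fx$vaIdx] == 1))
  expect_gte(acc, 0.95)
  # checkpoint rule: reported epoch is the argmin of validation loss
  h <- fx$model@history
  expect_lte(nrow(h), 120)
  expect_identical(fx$model@bestEpoch, h$epoch[which.min(h$val_loss)])
  # monotone response to the positive driver feature on a trained model
  base <- matrix(0, 1, 5)
  hi <- base; hi[1] <- 3
  expect_gt(predictProba(fx$model, hi), predictProba(fx$model, base))
})

test_that("permuted labels cannot beat the chance-level loss bound", {
  set.seed(11)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c(0L, 1L), length.out = n)  # independent of x by construction
  m <- buildMLP(6, seed = 2)
  m <- trainMLP(m, x[1:200, ], y[1:200], x[201:300, ], y[201:300],
                trainConfig(maxEpochs = 60, seed = 3))
  expect_gte(min(m@history$val_loss), 0.9 * log(2))
})

test_that("evaluation metrics match hand-computed values", {
  met <- evaluateClassifier(c(0.9, 0.2, 0.6), c(1, 0, 1))
  expect_identical(met$accuracyHigh, 1)
  expect_identical(met$accuracyLow, 1)
  expect_identical(met$f1Positive, 1)
  expect_identical(met$rocAUC, 1)
  expect_equal(met$meanBCE, -(log(0.9) + log(0.8) + log(0.6)) / 3,
               tolerance = 1e-3)
  # constant 0.5 on balanced labels: loss is exactly ln 2
  expect_equal(evaluateClassifier(rep(0.5, 10),
                                  rep(c(0, 1), 5))$meanBCE, log(2))
  # perfect predictor
  perf <- evaluateClassifier(c(0.99, 0.01, 0.98, 0.02), c(1, 0, 1, 0))
  expect_true(all(unlist(perf[c("accuracyHigh", "accuracyLow", "rocAUC",
                                "f1Positive")]) == 1))
  # single-class labels: AUC undefined, other metrics returned
  expect_warning(one <- evaluateClassifier(c(0.6, 0.7), c(1, 1)),
                 "AUC undefined")
  expect_true(is.na(one$rocAUC))
  expect_identical(one$accuracyHigh, 1)
})

test_that("label/probability complement swaps the class accuracies", {
  set.seed(4)
  p <- runif(40)
  y <- rbinom(40, 1, 0.5)
  a <- evaluateClassifier(p, y)
  b <- evaluateClassifier(1 - p, 1 - y, threshold = 0.5)
  expect_equal(a$accuracyLow, b$accuracyHigh)
  expect_equal(a$rocAUC, b$rocAUC, tolerance = 1e-12)
})

test_that("AUC equals Mann-Whitney pair counting and the pROC reference", {
  set.seed(9)
  for (rep in 1:3) {
    p <- round(runif(30), 2)  # rounded: force ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    auc <- evaluateClassifier(p, y)$rocAUC
    pos <- p[y == 1]
    neg <- p[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(pairs), tolerance = 1e-12)
    # fix pROC's direction: higher probability means the positive class
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(y, p, direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("baselines separate the toy problem and are seed-deterministic", {
  fx <- toyTrainedModel()
  te <- fx$vaIdx  # held-out slice
  bl <- trainBaselines(fx$x[fx$trIdx, ], fx$y[fx$trIdx],
                       fx$x[te, ], fx$y[te], seed = 5)
  expect_gte(bl$forest$accuracyHigh, 0.9)
  expect_gte(bl$boosting$accuracyHigh, 0.9)
  bl2 <- trainBaselines(fx$x[fx$trIdx, ], fx$y[fx$trIdx],
                        fx$x[te, ], fx$y[te], seed = 5)
  expect_identical(bl$forest, bl2$forest)
  expect_identical(bl$boosting, bl2$boosting)
})

test_that("baselines stay near chance on label-permuted data", {
  set.seed(21)
  n <- 240
  x <- matrix(rnorm(n * 8), n, 8)
  y <- rbinom(n, 1, 0.5)
  bl <- trainBaselines(x[1:160, ], y[1:160], x[161:240, ], y[161:240],
                       seed = 2)
  expect_lt(abs(bl$forest$rocAUC - 0.5), 0.1)
  expect_lt(abs(bl$boosting$rocAUC - 0.5), 0.1)
})
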