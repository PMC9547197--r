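#' Classification metrics for the binary glycan phenotype
#'
#' Computes per-class prediction accuracies (recall of the lectin-high and
#' lectin-low classes at the given threshold), mean binary cross-entropy
#' loss in nats, the ROC area under the curve by trapezoidal integration
#' over all distinct predicted probabilities, and the F1 score of the
#' positive (lectin-high) class.
#'
#' @param probabilities predicted probabilities per cell
#' @param labels true 0/1 labels
#' @param threshold decision threshold (default 0.5); a cell is called
#'   positive when its probability is >= threshold
#' @return a named list: \code{accuracyHigh}, \code{accuracyLow},
#'   \code{meanBCE}, \code{rocAUC}, \code{f1Positive}. With a single-class
#'   label vector the AUC is undefined: it is returned as NA with a warning.
#' @examples
#' evaluateClassifier(c(0.9, 0.2, 0.6), c(1, 0, 1))
#' @export
evaluateClassifier <- function(probabilities, labels, threshold = 0.5) {
  .assert(length(probabilities) == length(labels),
          "probabilities and labels must have equal length")
  .assert(all(labels %in% c(0, 1)), "labels must be binary")
  y <- as.integer(labels)
  pred <- as.integer(probabilities >= threshold)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  accHigh <- if (n1 > 0) tp / n1 else NA_real_
  accLow <- if (n0 > 0) sum(pred == 0L & y == 0L) / n0 else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (n1 > 0) tp / n1 else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- if (n1 == 0 || n0 == 0) {
    warning("AUC undefined for a single-class label vector", call. = FALSE)
    NA_real_
  } else {
    rocAuc(probabilities, y)
  }
  list(accuracyHigh = accHigh, accuracyLow = accLow,
       meanBCE = bceLoss(probabilities, y), rocAUC = auc, f1Positive = f1)
}

# trapezoidal ROC AUC over all distinct thresholds; equals the tie-corrected
# Mann-Whitney statistic
rocAuc <- function(p, y) {
  ord <- order(p, decreasing = TRUE)
  p <- p[ord]
  y <- y[ord]
  # cumulative TP/FP at each distinct probability cutoff
  lastOfGroup <- c(diff(p) != 0, TRUE)
  tp <- c(0, cumsum(y == 1L)[lastOfGroup])
  fp <- c(0, cumsum(y == 0L)[lastOfGroup])
  tpr <- tp / max(tp)
  fpr <- fp / max(fp)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Train and score the ensemble baselines
#'
#' Fits the two reference ensembles on the same training split as the neural
#' network and scores them on the test split: a bagged-decision-tree
#' ensemble (500 trees, depth limited to 2 via a 4-leaf cap) and an
#' AdaBoost ensemble of decision stumps (300 rounds, learning rate 0.1),
#' implemented in-package.
#'
#' @param xTrain,yTrain training features and 0/1 labels
#' @param xTest,yTest test features and labels
#' @param seed seed for both learners
#' @return list with elements \code{forest} and \code{boosting}, each the
#'   \code{\link{evaluateClassifier}} metrics on the test set, plus
#'   \code{forestProb}/\code{boostingProb} with the test probabilities
#' @export
trainBaselines <- function(xTrain, yTrain, xTest, yTest, seed = 1) {
  .assert(nrow(xTrain) == length(yTrain), "training sizes must agree")
  .assert(all(yTrain %in% c(0, 1)) && all(yTest %in% c(0, 1)),
          "labels must be binary")
  rfProb <- withr::with_seed(childSeed(seed, 1L), {
    rf <- randomForest::randomForest(
      x = xTrain, y = factor(yTrain, levels = c(0, 1)),
      ntree = 500, maxnodes = 4)
    predict(rf, xTest, type = "prob")[, "1"]
  })
  bst <- adaboostFit(xTrain, yTrain, nRounds = 300, learningRate = 0.1)
  boostProb <- adaboostPredict(bst, xTest)
  list(forest = evaluateClassifier(rfProb, yTest),
       boosting = evaluateClassifier(boostProb, yTest),
       forestProb = rfProb, boostingProb = boostProb)
}
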