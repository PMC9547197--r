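# Discrete AdaBoost (SAMME) with decision stumps and learning-rate
# shrinkage. Written in-package: no installed R package provides AdaBoost,
# and the gradient-boosting alternatives optimize a different loss with a
# markedly different inductive bias.
#
# Per round, the best weighted stump over all features and thresholds is
# found from per-feature presorted orders with cumulative weighted class
# sums, so a round costs one pass over the n x p matrix.

adaboostFit <- function(x, y01, nRounds = 300, learningRate = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  y <- ifelse(y01 == 1, 1, -1)
  ord <- apply(x, 2, order)                # sorted row index per feature
  xs <- matrix(x[cbind(as.vector(ord), rep(seq_len(p), each = n))], n, p)
  # positions where a threshold between sorted neighbours is meaningful
  validSplit <- rbind(xs[-1, , drop = FALSE] != xs[-n, , drop = FALSE],
                      FALSE)[seq_len(n - 1), , drop = FALSE]
  w <- rep(1 / n, n)
  stumps <- vector("list", nRounds)
  for (m in seq_len(nRounds)) {
    sPos <- matrix((w * (y == 1))[ord], n, p)
    sNeg <- matrix((w * (y == -1))[ord], n, p)
    cumPos <- apply(sPos, 2, cumsum)
    cumNeg <- apply(sNeg, 2, cumsum)
    # polarity +1: predict +1 above the threshold;
    # error = P(y=+1, below) + P(y=-1, above); weights sum to 1, so the
    # opposite polarity errs 1 - errPlus
    errPlus <- cumPos[seq_len(n - 1), , drop = FALSE] +
      (matrix(cumNeg[n, ], n - 1, p, byrow = TRUE) -
         cumNeg[seq_len(n - 1), , drop = FALSE])
    errMinus <- 1 - errPlus
    errPlus[!validSplit] <- Inf
    errMinus[!validSplit] <- Inf
    bestPlus <- which.min(errPlus)
    bestMinus <- which.min(errMinus)
    if (errPlus[bestPlus] <= errMinus[bestMinus]) {
      best <- bestPlus
      polarity <- 1
      err <- errPlus[bestPlus]
    } else {
      best <- bestMinus
      polarity <- -1
      err <- errMinus[bestMinus]
    }
    k <- (best - 1) %% (n - 1) + 1
    j <- (best - 1) %/% (n - 1) + 1
    thr <- (xs[k, j] + xs[k + 1, j]) / 2
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learningRate * log((1 - err) / err)
    h <- ifelse(x[, j] > thr, polarity, -polarity)
    stumps[[m]] <- list(feature = j, threshold = thr, polarity = polarity,
                        alpha = alpha)
    w <- w * exp(alpha * (h != y))
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, p = p), class = "adaboostStumps")
}

# decision function F(x) = sum_m alpha_m h_m(x); pseudo-probability via the
# logistic of 2F (margins are not calibrated probabilities, matching the
# characteristically high cross-entropy of AdaBoost ensembles)
adaboostPredict <- function(fit, x) {
  x <- as.matrix(x)
  f <- numeric(nrow(x))
  for (s in fit$stumps)
    f <- f + s$alpha * ifelse(x[, s$feature] > s$threshold,
                              s$polarity, -s$polarity)
  1 / (1 + exp(-2 * f))
}
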