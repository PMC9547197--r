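BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Build the feed-forward glycan-phenotype classifier
#'
#' Architecture: four hidden dense layers of 128, 64, 16 and 8 units. Hidden
#' layers 1-3 are each followed by a leaky rectifier (negative slope 0.01),
#' dropout (probabilities 0.4, 0.4, 0.2) and batch normalization; hidden
#' layer 4 feeds a parameter-free mean readout followed by a sigmoid, giving
#' the predicted probability of the lectin-high phenotype. Weights and
#' biases are initialized from the
#' fan-in-scaled uniform U(-1/sqrt(fan_in), 1/sqrt(fan_in)), deterministic
#' given \code{seed}.
#'
#' @param inputDim number of input genes (>= 1)
#' @param seed initialization seed
#' @param geneIds optional feature names, recorded for downstream rankings
#' @return an untrained \linkS4class{MLPClassifier}
#' @examples
#' m <- buildMLP(inputDim = 100, seed = 1)
#' nParams(m)  # 22344 dense + 416 batch-norm terms
#' @export
buildMLP <- function(inputDim, seed = 1, geneIds = NULL) {
  .assert(inputDim >= 1, "inputDim must be >= 1")
  hidden <- c(128L, 64L, 16L, 8L)
  dims <- c(as.integer(inputDim), hidden)
  params <- withr::with_seed(as.integer(seed), {
    W <- vector("list", 4L)
    b <- vector("list", 4L)
    for (l in 1:4) {
      bound <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -bound, bound),
                       nrow = dims[l], ncol = dims[l + 1L])
      b[[l]] <- runif(dims[l + 1L], -bound, bound)
    }
    list(W = W, b = b,
         gamma = lapply(hidden[1:3], function(h) rep(1, h)),
         beta = lapply(hidden[1:3], function(h) rep(0, h)),
         runMean = lapply(hidden[1:3], function(h) rep(0, h)),
         runVar = lapply(hidden[1:3], function(h) rep(1, h)))
  })
  new("MLPClassifier",
      inputDim = as.integer(inputDim), hiddenSizes = hidden,
      dropoutProbs = c(0.4, 0.4, 0.2), negativeSlope = 0.01,
      params = params, trained = FALSE,
      history = data.frame(), bestEpoch = NA_integer_,
      geneIds = if (is.null(geneIds)) character() else as.character(geneIds),
      seed = as.integer(seed))
}

setMethod("nParams", "MLPClassifier", function(object) {
  p <- object@params
  as.integer(sum(lengths(p$W)) + sum(lengths(p$b)) +
               sum(lengths(p$gamma)) + sum(lengths(p$beta)))
})

# ---- inference-mode layer stack -------------------------------------------
# The trained network, with dropout removed and batch normalization folded
# (using running statistics) into elementwise affine layers, as a list of
# primitive layers: affine (W, b), act (lrelu/sigmoid/identity), diag
# (elementwise scale + shift). One code path serves prediction, permutation
# importance and attribution.

asLayerStack <- function(model) {
  p <- model@params
  stack <- list()
  for (l in 1:3) {
    scale <- p$gamma[[l]] / sqrt(p$runVar[[l]] + BN_EPS)
    stack <- c(stack, list(
      list(type = "affine", W = p$W[[l]], b = p$b[[l]]),
      list(type = "act", f = "lrelu", slope = model@negativeSlope),
      list(type = "diag", scale = scale,
           shift = p$beta[[l]] - p$runMean[[l]] * scale)
    ))
  }
  c(stack, list(
    list(type = "affine", W = p$W[[4]], b = p$b[[4]]),
    list(type = "affine",
         W = matrix(1 / model@hiddenSizes[4], model@hiddenSizes[4], 1),
         b = 0),
    list(type = "act", f = "sigmoid")
  ))
}

applyAct <- function(layer, x) {
  switch(layer$f,
         lrelu = lrelu(x, layer$slope),
         sigmoid = sigmoid(x),
         identity = x,
         stop("unknown activation ", layer$f))
}

actGrad <- function(layer, x) {
  switch(layer$f,
         lrelu = lreluGrad(x, layer$slope),
         sigmoid = { s <- sigmoid(x); s * (1 - s) },
         identity = x * 0 + 1)
}

rowScale <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

applyLayer <- function(layer, x) {
  switch(layer$type,
         affine = x %*% layer$W +
           matrix(layer$b, nrow(x), length(layer$b), byrow = TRUE),
         act = applyAct(layer, x),
         diag = rowScale(x, layer$scale) +
           matrix(layer$shift, nrow(x), length(layer$shift), byrow = TRUE))
}

# forward from layer `from` onward; returns final n x 1 output
stackForwardFrom <- function(stack, x, from = 1L) {
  for (i in seq.int(from, length(stack))) x <- applyLayer(stack[[i]], x)
  x
}

# forward recording every layer input (needed by attribution)
stackForwardAll <- function(stack, x) {
  inputs <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    inputs[[i]] <- x
    x <- applyLayer(stack[[i]], x)
  }
  list(inputs = inputs, output = x)
}

#' @describeIn predictProba evaluation-mode forward pass: dropout off,
#'   batch normalization uses running statistics, so the output of a cell is
#'   independent of batch composition.
#' @export
setMethod("predictProba", "MLPClassifier", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object@inputDim)
    stop("feature dimension ", ncol(newdata), " does not match model (",
         object@inputDim, ")", call. = FALSE)
  as.numeric(stackForwardFrom(asLayerStack(object), newdata))
})

# ---- training -------------------------------------------------------------

# training-mode forward with caches; drop masks already scaled (inverted
# dropout)
.mlpForwardTrain <- function(p, x, dropoutProbs, slope) {
  cache <- list(h0 = x)
  h <- x
  for (l in 1:3) {
    z <- h %*% p$W[[l]] +
      matrix(p$b[[l]], nrow(h), length(p$b[[l]]), byrow = TRUE)
    a <- lrelu(z, slope)
    keep <- 1 - dropoutProbs[l]
    mask <- matrix((runif(length(a)) < keep) / keep, nrow(a), ncol(a))
    d <- a * mask
    mu <- colMeans(d)
    v <- colMeans(d^2) - mu^2          # biased batch variance
    invStd <- 1 / sqrt(v + BN_EPS)
    xhat <- rowScale(sweep(d, 2, mu, "-"), invStd)
    h <- rowScale(xhat, p$gamma[[l]]) +
      matrix(p$beta[[l]], nrow(xhat), ncol(xhat), byrow = TRUE)
    cache[[paste0("L", l)]] <- list(z = z, mask = mask, d = d, mu = mu,
                                    v = v, invStd = invStd, xhat = xhat,
                                    hin = cache[[if (l == 1) "h0" else
                                                 paste0("hout", l - 1)]])
    cache[[paste0("hout", l)]] <- h
  }
  z4 <- h %*% p$W[[4]] +
    matrix(p$b[[4]], nrow(h), length(p$b[[4]]), byrow = TRUE)
  prob <- sigmoid(rowMeans(z4))
  cache$z4 <- z4
  cache$prob <- prob
  cache
}

.mlpBackward <- function(p, cache, y, dropoutProbs, slope) {
  n <- length(y)
  # BCE through sigmoid(mean(z4)): dL/dz4 = (p - y) / (8 n) per head
  k <- ncol(cache$z4)
  dz4 <- matrix((cache$prob - y) / (k * n), n, k)
  g <- list(W = vector("list", 4), b = vector("list", 4),
            gamma = vector("list", 3), beta = vector("list", 3))
  g$W[[4]] <- crossprod(cache$hout3, dz4)
  g$b[[4]] <- colSums(dz4)
  dh <- dz4 %*% t(p$W[[4]])
  for (l in 3:1) {
    cc <- cache[[paste0("L", l)]]
    m <- nrow(cc$xhat)
    g$gamma[[l]] <- colSums(dh * cc$xhat)
    g$beta[[l]] <- colSums(dh)
    dxhat <- rowScale(dh, p$gamma[[l]])
    dd <- rowScale(
      dxhat - matrix(colMeans(dxhat), m, ncol(dxhat), byrow = TRUE) -
        cc$xhat * matrix(colMeans(dxhat * cc$xhat), m, ncol(dxhat),
                         byrow = TRUE),
      cc$invStd)
    da <- dd * cc$mask
    dz <- da * lreluGrad(cc$z, slope)
    g$W[[l]] <- crossprod(cc$hin, dz)
    g$b[[l]] <- colSums(dz)
    if (l > 1) dh <- dz %*% t(p$W[[l]])
  }
  g
}

.adamInit <- function(p) {
  zero <- function(x) lapply(x, function(e) e * 0)
  list(m = list(W = zero(p$W), b = zero(p$b), gamma = zero(p$gamma),
                beta = zero(p$beta)),
       v = list(W = zero(p$W), b = zero(p$b), gamma = zero(p$gamma),
                beta = zero(p$beta)),
       t = 0)
}

.adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (grp in c("W", "b", "gamma", "beta")) {
    for (i in seq_along(g[[grp]])) {
      gr <- g[[grp]][[i]]
      state$m[[grp]][[i]] <- beta1 * state$m[[grp]][[i]] + (1 - beta1) * gr
      state$v[[grp]][[i]] <- beta2 * state$v[[grp]][[i]] +
        (1 - beta2) * gr^2
      p[[grp]][[i]] <- p[[grp]][[i]] -
        lr * (state$m[[grp]][[i]] / corr1) /
          (sqrt(state$v[[grp]][[i]] / corr2) + eps)
    }
  }
  list(p = p, state = state)
}

#' Train the classifier with BCE loss and cosine-annealed Adam
#'
#' Mini-batch training (batch size 128 by default) with binary cross-entropy
#' loss, Adam at an initial learning rate of 1e-4 with decoupled weight
#' decay on the dense weights, and a cosine-annealing schedule spanning the
#' epoch budget. Dropout and batch normalization are active only during
#' optimization. After every epoch the validation loss is computed in
#' evaluation mode; the returned model is the checkpoint with minimal
#' validation loss, with its batch-norm statistics re-estimated dropout-free
#' on the training set (the layer order puts dropout before batch norm, so
#' statistics accumulated during optimization are inflated relative to
#' inference-mode activations).
#'
#' @param model an untrained \linkS4class{MLPClassifier}
#' @param xTrain,yTrain training features (cells x genes) and 0/1 labels
#' @param xVal,yVal validation features and labels
#' @param config a \linkS4class{TrainConfig}
#' @return the trained model, with \code{@history} holding per-epoch
#'   train/validation losses and \code{@bestEpoch} the checkpoint epoch
#' @export
trainMLP <- function(model, xTrain, yTrain, xVal, yVal,
                     config = trainConfig()) {
  stopifnot(is(model, "MLPClassifier"), is(config, "TrainConfig"))
  xTrain <- as.matrix(xTrain)
  xVal <- as.matrix(xVal)
  .assert(nrow(xTrain) >= 1, "training set must be nonempty")
  .assert(ncol(xTrain) == model@inputDim && ncol(xVal) == model@inputDim,
          "feature dimensions must match the model")
  .assert(all(yTrain %in% c(0, 1)) && all(yVal %in% c(0, 1)),
          "labels must be binary")
  p <- model@params
  adam <- .adamInit(p)
  best <- list(loss = Inf, params = p, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric())
  nTr <- nrow(xTrain)
  withr::with_seed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      lr <- config@learningRate *
        0.5 * (1 + cos(pi * (epoch - 1) / config@maxEpochs))
      perm <- sample.int(nTr)
      starts <- seq.int(1L, nTr, by = config@batchSize)
      epochLoss <- 0
      for (s0 in starts) {
        idx <- perm[seq.int(s0, min(s0 + config@batchSize - 1L, nTr))]
        xb <- xTrain[idx, , drop = FALSE]
        yb <- yTrain[idx]
        cache <- .mlpForwardTrain(p, xb, model@dropoutProbs,
                                  model@negativeSlope)
        loss <- bceLoss(cache$prob, yb)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        epochLoss <- epochLoss + loss * length(idx)
        # update batch-norm running statistics
        m <- length(idx)
        for (l in 1:3) {
          cc <- cache[[paste0("L", l)]]
          vUnb <- if (m > 1) cc$v * m / (m - 1) else cc$v
          p$runMean[[l]] <- (1 - BN_MOMENTUM) * p$runMean[[l]] +
            BN_MOMENTUM * cc$mu
          p$runVar[[l]] <- (1 - BN_MOMENTUM) * p$runVar[[l]] +
            BN_MOMENTUM * vUnb
        }
        g <- .mlpBackward(p, cache, yb, model@dropoutProbs,
                          model@negativeSlope)
        upd <- .adamStep(p, g, adam, lr)
        if (config@weightDecay > 0)  # decoupled, on dense weights only
          for (l in 1:4)
            upd$p$W[[l]] <- upd$p$W[[l]] * (1 - lr * config@weightDecay)
        # keep running stats (not touched by Adam)
        upd$p$runMean <- p$runMean
        upd$p$runVar <- p$runVar
        p <- upd$p
        adam <- upd$state
      }
      model@params <- p
      valLoss <- bceLoss(predictProba(model, xVal), yVal)
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = epochLoss / nTr,
                                     val_loss = valLoss))
      if (valLoss < best$loss)
        best <- list(loss = valLoss, params = p, epoch = epoch)
    }
  })
  model@params <- best$params
  # batch-norm statistics were accumulated on dropout-inflated activations
  # (dropout precedes batch norm); re-estimate population statistics with
  # dropout off so inference-mode normalization matches inference-mode
  # activations
  model@params <- .recomputeBNStats(model@params, xTrain,
                                    model@negativeSlope)
  model@trained <- TRUE
  model@history <- hist
  model@bestEpoch <- as.integer(best$epoch)
  model
}

# one dropout-free pass over `x`, replacing the running batch-norm
# statistics with the population statistics of each normalized layer input
.recomputeBNStats <- function(p, x, slope) {
  h <- x
  for (l in 1:3) {
    z <- h %*% p$W[[l]] +
      matrix(p$b[[l]], nrow(h), length(p$b[[l]]), byrow = TRUE)
    d <- lrelu(z, slope)
    mu <- colMeans(d)
    v <- colMeans(d^2) - mu^2
    p$runMean[[l]] <- mu
    p$runVar[[l]] <- v
    h <- rowScale(sweep(d, 2, mu, "-"), p$gamma[[l]] / sqrt(v + BN_EPS)) +
      matrix(p$beta[[l]], nrow(d), length(p$beta[[l]]), byrow = TRUE)
  }
  p
}
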