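test_that("linear rule recovers the closed form for an affine model", {
  # f(x) = w . x + b with identity activation: phi_i = w_i (x_i - r_i)
  w <- c(2, -1, 0.5)
  stack <- list(list(type = "affine", W = matrix(w, 3, 1), b = 0.3),
                list(type = "act", f = "identity"))
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("c1", c("a", "b", "c")))
  r <- matrix(c(0, 1, -1), 1, 3)
  at <- deepAttribution(stack, x, r)
  expect_equal(as.numeric(shapValues(at)), w * (as.numeric(x) - as.numeric(r)))
  # explain cell equal to the background: zero attribution everywhere
  at0 <- deepAttribution(stack, r, r)
  expect_true(all(shapValues(at0) == 0))
})

test_that("attribution satisfies local accuracy on a trained model", {
  fx <- toyTrainedModel()
  ex <- fx$x[1:40, ]
  bg <- fx$x[fx$trIdx[1:25], ]
  at <- deepAttribution(fx$model, ex, bg)
  f <- predictProba(fx$model, ex)
  expect_lt(max(abs(rowSums(shapValues(at)) - (f - baseValue(at)))), 1e-4)
  expect_equal(baseValue(at), mean(predictProba(fx$model, bg)),
               tolerance = 1e-12)
})

test_that("a gene with all-zero input weights gets exactly zero phi", {
  fx <- toyTrainedModel()
  m <- fx$model
  m@params$W[[1]][3, ] <- 0
  at <- deepAttribution(m, fx$x[1:20, ], fx$x[21:30, ])
  expect_true(all(shapValues(at)[, 3] == 0))
})

test_that("deep attribution tracks the sampling and exhaustive oracles", {
  stack <- randomSmallStack(31)
  set.seed(32)
  bg <- matrix(rnorm(5 * 8), 5, 8)
  ex <- matrix(rnorm(20 * 8), 20, 8)
  deep <- shapValues(deepAttribution(stack, ex, bg))
  exact <- t(vapply(seq_len(20), function(i) exactShapley(stack, ex[i, ], bg),
                    numeric(8)))
  expect_gte(cor(as.numeric(deep), as.numeric(exact)), 0.95)
  # sampling oracle agrees with enumeration within Monte-Carlo error
  samp <- samplingShapley(stack, ex[1, ], bg, nDraws = 4000, seed = 7)
  expect_lt(max(abs(samp - exact[1, ])), 0.01)
  expect_identical(samp, samplingShapley(stack, ex[1, ], bg,
                                         nDraws = 4000, seed = 7))
})

test_that("sampling Shapley is exact for linear models and symmetric", {
  w <- c(1.5, -2, 0.25, 1)
  stack <- list(list(type = "affine", W = matrix(w, 4, 1), b = 0),
                list(type = "act", f = "identity"))
  # with a single reference, every sampled ordering of a linear model
  # yields exactly w_i (x_i - r_i)
  r <- matrix(c(0.2, -0.3, 1, 0), 1, 4)
  x <- c(1, -1, 2, 0.5)
  phi <- samplingShapley(stack, x, r, nDraws = 50, seed = 11)
  expect_equal(phi, w * (x - as.numeric(r)), tolerance = 1e-12)
  # exchangeable features with identical values get equal attribution
  wSym <- c(1, 1)
  stackSym <- list(list(type = "affine", W = matrix(wSym, 2, 1), b = 0),
                   list(type = "act", f = "identity"))
  bgSym <- cbind(c(0, 1, -1), c(0, 1, -1))
  phiSym <- samplingShapley(stackSym, c(2, 2), bgSym, nDraws = 400,
                            seed = 5)
  expect_equal(phiSym[1], phiSym[2], tolerance = 1e-12)
})

test_that("ensemble averaging is idempotent, cancels and stays accurate", {
  fx <- toyTrainedModel()
  ex <- fx$x[1:15, ]
  bg <- fx$x[16:25, ]
  at <- deepAttribution(fx$model, ex, bg)
  expect_equal(shapValues(ensembleAverage(list(at, at, at))),
               shapValues(at))
  neg <- at
  neg@phi <- -neg@phi
  neg@baseValue <- -neg@baseValue
  zero <- at
  zero@phi <- 0 * zero@phi
  zero@baseValue <- 0
  avg <- ensembleAverage(list(at, neg, zero))
  expect_true(all(avg@phi == 0))
  expect_identical(baseValue(avg), 0)
  # averaged attributions keep local accuracy against averaged models
  m2 <- buildMLP(5, seed = 99, geneIds = colnames(fx$x))
  at2 <- deepAttribution(m2, ex, bg)
  avg2 <- ensembleAverage(list(at, at2))
  fBar <- (predictProba(fx$model, ex) + predictProba(m2, ex)) / 2
  expect_lt(max(abs(rowSums(shapValues(avg2)) -
                      (fBar - baseValue(avg2)))), 1e-4)
  # mismatched cells are rejected
  atSub <- deepAttribution(fx$model, ex[1:3, ], bg)
  expect_error(ensembleAverage(list(at, atSub)), "share")
})

test_that("gene ranking sorts by median |phi| with deterministic ties", {
  phi <- cbind(a = c(0.5, -0.5, 0.5), b = c(0.2, 0.2, -0.2),
               c = c(-0.9, 0.9, 0.9), z = c(0, 0, 0))
  at <- new("AttributionMatrix", phi = phi, baseValue = 0.5,
            explainCellIds = c("c1", "c2", "c3"),
            backgroundCellIds = "b1")
  rk <- rankGenes(at)
  expect_identical(rk$gene_id, c("c", "a", "b", "z"))
  expect_identical(rk$rank, 1:4)
  expect_equal(rk$median_abs_shap, c(0.9, 0.5, 0.2, 0))
  expect_equal(rk$percentile, c(25, 50, 75, 100))
  # zero gene ranked last; percentile formula rank / n * 100
  phi400 <- matrix(rnorm(5 * 400), 5, 400,
                   dimnames = list(NULL, sprintf("g%03d", 1:400)))
  rk400 <- rankGenes(new("AttributionMatrix", phi = phi400, baseValue = 0,
                         explainCellIds = as.character(1:5),
                         backgroundCellIds = "b"))
  expect_equal(rk400$percentile[rk400$rank == 4], 1.0)
})

test_that("top fraction uses round-half-away-from-zero set sizes", {
  mk <- function(n) data.frame(gene_id = sprintf("g%05d", 1:n))
  expect_length(topFraction(mk(5160), 0.10), 516)
  expect_length(topFraction(mk(2050), 0.10), 205)
  expect_length(topFraction(mk(2000), 0.10), 200)
  expect_length(topFraction(mk(25), 0.10), 3)   # 2.5 rounds away from zero
  expect_length(topFraction(mk(7), 1.0), 7)
  expect_error(topFraction(mk(10), 0), "fraction")
})

test_that("subtype rankings cap the explained cells and are functional", {
  fx <- toyTrainedModel()
  x <- fx$x[1:60, ]
  rownames(x) <- sprintf("c%02d", 1:60)
  subtypes <- factor(rep(c("A", "B"), each = 30))
  bg <- fx$x[fx$trIdx[1:10], ]
  sr <- subtypeRankings(list(fx$model), x, subtypes, list(bg),
                        cap = 1000, seed = 1)
  expect_named(sr, c("A", "B"))
  # identical cells in both subtypes: identical rankings
  xx <- rbind(x[1:20, ], x[1:20, ])
  rownames(xx) <- sprintf("d%02d", 1:40)
  srSame <- subtypeRankings(list(fx$model), xx,
                            factor(rep(c("A", "B"), each = 20)),
                            list(bg), seed = 2)
  expect_equal(srSame$A$median_abs_shap, srSame$B$median_abs_shap)
  expect_identical(srSame$A$gene_id, srSame$B$gene_id)
  # cap = 1: ranking computed from one cell, median = |phi| of that cell
  sr1 <- subtypeRankings(list(fx$model), x, subtypes, list(bg),
                         cap = 1, seed = 3)
  expect_identical(nrow(sr1$A), 5L)
  # empty subtype skipped with a warning
  expect_warning(
    subtypeRankings(list(fx$model), x,
                    factor(rep("A", 60), levels = c("A", "B")),
                    list(bg), seed = 4),
    "no cells")
})

test_that("the subtype-specificity rule is applied exactly", {
  pm <- rbind(
    gSpec = c(0.5, 40, 50, 60),     # specific to subtype 1
    gFlat = c(1.0, 1.0, 1.0, 1.0),  # shared importance: never specific
    gLow = c(0.5, 0.6, 1.4, 0.7)    # top 2% everywhere but not separated
                                    # (0.9 - 0.5 = 0.4 < 1.25 * 0.436)
  )
  colnames(pm) <- paste0("s", 1:4)
  hits <- specificGenes(pm)
  expect_identical(hits$gene_id, "gSpec")
  expect_identical(hits$subtype, "s1")
  # worked example: mean others 50, sd 10, 50 - 0.5 = 49.5 >= 12.5
  expect_equal(hits$mean_others, 50)
  expect_equal(hits$sd_others, 10)
  expect_error(specificGenes(pm[, 1, drop = FALSE]), "2 subtypes")
})
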