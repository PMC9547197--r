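test_that("ignored and constant features get exactly zero importance", {
  fx <- toyTrainedModel()
  m <- fx$model
  m@params$W[[1]][4, ] <- 0          # model ignores gene 4
  x <- fx$x[1:80, ]
  x[, 5] <- 1.7                      # constant column
  pfi <- permutationImportance(m, x, fx$y[1:80], nPermutations = 5,
                               seed = 2)
  expect_identical(pfi$importance[pfi$gene_id == "g4"], 0)
  expect_identical(pfi$importance[pfi$gene_id == "g5"], 0)
  # the informative feature dominates the ranking
  expect_identical(pfi$gene_id[1], "g1")
  expect_gt(pfi$importance[1], 0)
  expect_error(permutationImportance(m, x, fx$y[1:80],
                                     nPermutations = 0), "nPermutations")
})

test_that("permutation importance is deterministic and order-insensitive", {
  fx <- toyTrainedModel()
  x <- fx$x[1:100, ]
  y <- fx$y[1:100]
  p1 <- permutationImportance(fx$model, x, y, seed = 31)
  p2 <- permutationImportance(fx$model, x, y, seed = 31)
  expect_identical(p1, p2)
  # label-preserving row reordering: same importances up to Monte-Carlo
  # noise of the 25 permutations
  ord <- sample(nrow(x))
  p3 <- permutationImportance(fx$model, x[ord, ], y[ord], seed = 31)
  expect_equal(p1$importance[order(p1$gene_id)],
               p3$importance[order(p3$gene_id)], tolerance = 0.05)
  expect_identical(p1$gene_id[1], p3$gene_id[1])
})

test_that("rank-sum p-values match enumeration and the stats reference", {
  # 3 vs 3 complete separation: two-sided exact p = 2/20
  expect_equal(glycanShap:::rankSumP(c(1, 2, 3, 10, 11, 12),
                                     rep(c(FALSE, TRUE), each = 3)), 0.1)
  set.seed(13)
  for (i in 1:10) {
    n1 <- sample(3:8, 1)
    n0 <- sample(3:8, 1)
    vals <- sample(1:6, n1 + n0, replace = TRUE)  # ties likely
    g1 <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(glycanShap:::rankSumP(vals, g1), enumRankSumP(vals, g1))
  }
  # large-sample path agrees with wilcox.test's corrected normal approx
  for (i in 1:5) {
    vals <- c(rnorm(30), rnorm(25, 0.5))
    g1 <- rep(c(TRUE, FALSE), c(30, 25))
    ref <- suppressWarnings(stats::wilcox.test(vals[g1], vals[!g1],
                                               exact = FALSE))$p.value
    expect_equal(glycanShap:::rankSumP(vals, g1), ref, tolerance = 1e-9)
  }
})

test_that("differential expression filters, tests and adjusts correctly", {
  set.seed(8)
  n <- 40
  labels <- rep(c(1, 0), each = n / 2)
  x <- cbind(
    up = log1p(ifelse(labels == 1, rpois(n, 30), rpois(n, 5))),
    flat = log1p(rpois(n, 10)),
    down = log1p(ifelse(labels == 1, rpois(n, 4), rpois(n, 25)))
  )
  res <- wilcoxonDE(x, labels)
  expect_gt(res$log2_fold_change[1], 0.25)
  expect_lt(res$log2_fold_change[3], -0.25)
  expect_true(res$significant[1] && res$significant[3])
  # below-threshold gene is not tested at all
  expect_true(is.na(res$p_value[2]) && is.na(res$adjusted_p[2]))
  expect_false(res$significant[2])
  # swapping the groups flips the fold change and keeps p
  resSwap <- wilcoxonDE(x, 1 - labels)
  expect_equal(resSwap$log2_fold_change, -res$log2_fold_change,
               tolerance = 1e-12)
  expect_equal(resSwap$p_value, res$p_value)
  expect_true(all(res$adjusted_p >= res$p_value, na.rm = TRUE))
  # identical group means: log2FC 0, filtered
  xc <- cbind(const = rep(c(1, 2), n / 2))
  resC <- wilcoxonDE(xc, labels)
  expect_identical(resC$log2_fold_change, 0)
  expect_false(resC$significant)
  expect_error(wilcoxonDE(x, rep(1, n)), "nonempty")
})

test_that("BH adjustment reproduces worked cases and preserves order", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 6)), rep(1, 6))
  shuffled <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(bhAdjust(shuffled), rep(0.04, 4))
  # monotone non-decreasing on sorted input
  set.seed(2)
  p <- sort(runif(50))
  expect_true(all(diff(bhAdjust(p)) >= -1e-12))
  expect_equal(bhAdjust(p, method = "bonferroni"), pmin(1, p * 50))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("overlap statistics match the set arithmetic", {
  a <- sprintf("g%03d", 1:516)
  b <- sprintf("g%03d", c(1:318, 1000:1198))
  ov <- overlapStats(a, b)
  expect_identical(ov$shared, 318L)
  expect_identical(ov$sizeB, 517L)
  expect_equal(ov$fractionShared, 318 / 517 * 100, tolerance = 1e-12)
  expect_equal(round(ov$fractionShared, 1), 61.5)
  same <- overlapStats(a, a)
  expect_equal(same$fractionShared, 100)
  expect_identical(same$jaccard, 1)
  disj <- overlapStats(a, "other")
  expect_identical(disj$shared, 0L)
  expect_identical(disj$jaccard, 0)
  expect_identical(overlapStats(character(), character())$fractionShared, 0)
})
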