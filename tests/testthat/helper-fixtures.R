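# small in-code fixtures shared across test files; expensive objects are
# built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixtureCached <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

smallConfig <- function(seed = 7, ...) {
  syntheticConfig(nCells = 200, nGenes = 80, nDriversPos = 6,
                  nDriversNeg = 2, seed = seed, ...)
}

# a tiny but genuinely trained model on linearly separable data:
# feature 1 carries the label, the rest are noise
toyTrainedModel <- function() {
  fixtureCached("toyTrainedModel", function() {
    set.seed(5)
    n <- 300
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * 5, sd = 0.3), n, 5)
    x[, 1] <- x[, 1] + 2 * y
    colnames(x) <- paste0("g", 1:5)
    idx <- sample.int(n)
    trIdx <- idx[1:200]
    vaIdx <- idx[201:300]
    m <- buildMLP(5, seed = 3, geneIds = colnames(x))
    m <- trainMLP(m, x[trIdx, ], y[trIdx], x[vaIdx, ], y[vaIdx],
                  trainConfig(maxEpochs = 120, seed = 4))
    list(model = m, x = x, y = y, trIdx = trIdx, vaIdx = vaIdx)
  })
}

# random small layer stack (affine -> lrelu -> affine -> sigmoid) drawn with
# the package's fan-in-scaled uniform initialization
randomSmallStack <- function(seed, d = 8, h = 2) {
  set.seed(seed)
  b1 <- 1 / sqrt(d)
  b2 <- 1 / sqrt(h)
  list(
    list(type = "affine", W = matrix(runif(d * h, -b1, b1), d, h),
         b = runif(h, -b1, b1)),
    list(type = "act", f = "lrelu", slope = 0.01),
    list(type = "affine", W = matrix(runif(h, -b2, b2), h, 1),
         b = runif(1, -b2, b2)),
    list(type = "act", f = "sigmoid")
  )
}

# independent two-sided rank-sum oracle: enumerate group-1 assignments and
# count tail mass directly from the rank-sum distribution
enumRankSumP <- function(values, inGroup1) {
  r <- rank(values)
  n <- length(values)
  n1 <- sum(inGroup1)
  w <- sum(r[inGroup1])
  all1 <- utils::combn(n, n1)
  wAll <- apply(all1, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(wAll <= w), mean(wAll >= w)))
}
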