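#' @importFrom methods new validObject is slot
#' @importFrom stats median rnorm runif rnbinom sd cor quantile p.adjust
#'   pnorm predict
#' @importFrom utils combn head packageVersion
NULL

# Counter-based sub-seed derivation: reproducible regardless of call order.
# Kept below 2^31 - 1 (R integers are 32-bit).
childSeed <- function(seed, counter) {
  stopifnot(length(seed) == 1L, length(counter) == 1L)
  s <- (as.double(seed) %% 2147483647) + 7919 * (as.double(counter) + 1)
  as.integer(s %% 2147483647)
}

# round-half-away-from-zero (base round() is round-half-even); consistent with
# top-10% gene-set sizes 516/5160 and 205/2050
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.checkProportions <- function(p, what = "proportions") {
  .assert(is.numeric(p) && all(p > 0), sprintf("%s must be positive", what))
  .assert(abs(sum(p) - 1) <= 1e-9, sprintf("%s must sum to 1", what))
  invisible(p)
}

# leaky rectifier and its derivative (branch-free: hot path)
lrelu <- function(x, slope = 0.01) pmax(x, 0) + slope * pmin(x, 0)
lreluGrad <- function(x, slope = 0.01) (x > 0) + slope * (x <= 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# mean binary cross-entropy in nats, clamped away from 0/1 for finiteness
bceLoss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
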