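#' Permutation feature importance
#'
#' For each gene, its feature column is randomly shuffled across cells
#' (labels intact), the mean binary cross-entropy loss of the model on the
#' shuffled data is computed, and the procedure is repeated
#' \code{nPermutations} times. The importance of a gene is the mean permuted
#' loss minus the unpermuted loss; a gene the model ignores (all-zero
#' first-layer weights, or a constant column) scores exactly 0.
#'
#' Implementation note: only the first-layer pre-activation changes when one
#' column is shuffled, so the first dense product is computed once and
#' rank-one-updated per gene, making the 25 x n_genes evaluations cheap.
#'
#' @param model a trained \linkS4class{MLPClassifier}
#' @param x cells x genes feature matrix (evaluation set)
#' @param y 0/1 labels
#' @param nPermutations number of shuffles per gene (default 25)
#' @param seed RNG seed; permutations are deterministic given it
#' @return data.frame with columns \code{gene_id},
#'   \code{mean_permuted_loss}, \code{importance}, \code{rank}, ordered by
#'   importance descending (ties by gene id)
#' @export
permutationImportance <- function(model, x, y, nPermutations = 25,
                                  seed = 1) {
  stopifnot(is(model, "MLPClassifier"))
  .assert(nPermutations >= 1, "nPermutations must be >= 1")
  x <- as.matrix(x)
  .assert(all(y %in% c(0, 1)), "labels must be binary")
  .assert(ncol(x) == model@inputDim, "feature dimension mismatch")
  stack <- asLayerStack(model)
  n <- nrow(x)
  W1 <- stack[[1]]$W
  z1 <- x %*% W1 + matrix(stack[[1]]$b, n, ncol(W1), byrow = TRUE)
  origLoss <- bceLoss(as.numeric(stackForwardFrom(stack, z1, from = 2L)), y)
  geneIds <- if (!is.null(colnames(x))) colnames(x)
             else sprintf("feature%d", seq_len(ncol(x)))
  meanLoss <- numeric(ncol(x))
  withr::with_seed(as.integer(seed), {
    for (g in seq_len(ncol(x))) {
      xg <- x[, g]
      if (all(W1[g, ] == 0) || all(xg == xg[1])) {
        # model-invariant or constant feature: every permutation leaves the
        # forward pass (hence the loss) unchanged
        for (t in seq_len(nPermutations)) sample.int(n)  # keep RNG stream
        meanLoss[g] <- origLoss
        next
      }
      # stack the permutations so layers 2+ run once per gene
      delta <- vapply(seq_len(nPermutations),
                      function(t) xg[sample.int(n)] - xg, numeric(n))
      zPerm <- z1[rep(seq_len(n), nPermutations), , drop = FALSE] +
        as.numeric(delta) %o% W1[g, ]
      p <- as.numeric(stackForwardFrom(stack, zPerm, from = 2L))
      losses <- vapply(seq_len(nPermutations), function(t)
        bceLoss(p[seq.int((t - 1L) * n + 1L, t * n)], y), numeric(1))
      meanLoss[g] <- mean(losses)
    }
  })
  imp <- meanLoss - origLoss
  ord <- order(-imp, geneIds)
  data.frame(gene_id = geneIds[ord], mean_permuted_loss = meanLoss[ord],
             importance = imp[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

# two-sided Wilcoxon rank-sum p-value; exact enumeration (tie-safe) when
# both groups are small, otherwise normal approximation with tie correction
# and continuity correction
rankSumP <- function(values, inGroup1, exactMax = 10) {
  n <- length(values)
  n1 <- sum(inGroup1)
  n0 <- n - n1
  .assert(n1 > 0 && n0 > 0, "both groups must be nonempty")
  r <- rank(values)
  w <- sum(r[inGroup1])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exactMax && n0 <= exactMax) {
    sets <- combn(n, n1)
    wAll <- colSums(matrix(r[sets], nrow = n1))
    pLo <- mean(wAll <= w)
    pHi <- mean(wAll >= w)
    return(min(1, 2 * min(pLo, pHi)))
  }
  ties <- table(r)
  sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression with fold-change pre-filter
#'
#' Per gene: the log2 fold change between the lectin-high and lectin-low
#' groups is \code{log2((mean(expm1(high)) + 1) / (mean(expm1(low)) + 1))}
#' (a +1 pseudocount on the de-logged scale). Genes whose absolute log2 fold
#' change falls below \code{logfcThreshold} are not tested (p recorded as
#' NA). Tested genes get a two-sided rank-sum p-value (exact enumeration
#' when both groups have at most 10 cells, otherwise tie-corrected normal
#' approximation) and a multiplicity adjustment via \code{\link{bhAdjust}}.
#' A gene is significant when its adjusted p is below \code{alpha} and it
#' passed the fold-change filter.
#'
#' @param x cells x genes matrix of log-normalized expression
#' @param labels 0/1 group labels (1 = lectin-high)
#' @param logfcThreshold absolute log2 fold-change filter (default 0.25)
#' @param alpha FDR threshold (default 0.05)
#' @param adjustMethod "BH" (default) or "bonferroni"
#' @return data.frame with columns \code{gene_id}, \code{log2_fold_change},
#'   \code{p_value}, \code{adjusted_p}, \code{significant}, in gene order
#' @export
wilcoxonDE <- function(x, labels, logfcThreshold = 0.25, alpha = 0.05,
                       adjustMethod = c("BH", "bonferroni")) {
  adjustMethod <- match.arg(adjustMethod)
  x <- as.matrix(x)
  .assert(all(labels %in% c(0, 1)), "labels must be binary")
  hi <- labels == 1
  lo <- labels == 0
  .assert(any(hi) && any(lo), "both label groups must be nonempty")
  geneIds <- if (!is.null(colnames(x))) colnames(x)
             else sprintf("gene%d", seq_len(ncol(x)))
  meansHi <- colMeans(expm1(x[hi, , drop = FALSE]))
  meansLo <- colMeans(expm1(x[lo, , drop = FALSE]))
  lfc <- log2((meansHi + 1) / (meansLo + 1))
  tested <- abs(lfc) >= logfcThreshold
  p <- rep(NA_real_, ncol(x))
  inG1 <- hi[hi | lo]
  xl <- x[hi | lo, , drop = FALSE]
  for (g in which(tested)) p[g] <- rankSumP(xl[, g], inG1)
  adj <- rep(NA_real_, ncol(x))
  adj[tested] <- bhAdjust(p[tested], method = adjustMethod)
  data.frame(gene_id = geneIds, log2_fold_change = unname(lfc),
             p_value = p, adjusted_p = adj,
             significant = !is.na(adj) & adj < alpha,
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment (\code{p * m / i} with downward
#' monotonicity enforcement and a cap at 1), or Bonferroni; input order is
#' preserved.
#'
#' @param p p-values in [0, 1]
#' @param method "BH" (default) or "bonferroni"
#' @return adjusted p-values in input order
#' @export
bhAdjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  .assert(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

#' Overlap between two gene sets
#'
#' @param setA,setB character vectors of gene identifiers
#' @return list with \code{sizeA}, \code{sizeB}, \code{shared},
#'   \code{fractionShared} (percent of setB also in setA) and
#'   \code{jaccard}; empty-set fractions are 0
#' @examples
#' # 318 of 517 permutation-importance genes shared with the SHAP set
#' overlapStats(paste0("g", 1:516), paste0("g", c(1:318, 600:798)))
#' @export
overlapStats <- function(setA, setB) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  shared <- length(intersect(setA, setB))
  uni <- length(union(setA, setB))
  list(sizeA = length(setA), sizeB = length(setB), shared = shared,
       fractionShared = if (length(setB)) shared / length(setB) * 100 else 0,
       jaccard = if (uni) shared / uni else 0)
}
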