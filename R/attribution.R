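#' Shapley-style attribution by multi-reference DeepLIFT backpropagation
#'
#' Explains the inference-mode model output (the predicted probability of
#' the lectin-high phenotype). For every background reference, multipliers
#' are backpropagated through the layer stack: the linear rule through
#' affine layers (batch normalization folded into an elementwise affine
#' transform using running statistics, dropout treated as identity) and the
#' rescale rule through the leaky-rectifier and sigmoid nonlinearities
#' (contribution ratio \code{(f(z_x) - f(z_r)) / (z_x - z_r)}, falling back
#' to the derivative when the input difference is below 1e-7). Attributions
#' are averaged over all references, so per cell
#' \code{sum(phi) = f(x) - baseValue} (local accuracy), with
#' \code{baseValue} the mean model output over the background set.
#'
#' @param model a trained \linkS4class{MLPClassifier} (or a raw layer stack
#'   as produced internally, for testing primitive rules)
#' @param explain cells x genes matrix of cells to explain
#' @param background cells x genes matrix of background reference cells
#' @return an \linkS4class{AttributionMatrix} with phi in probability units
#' @export
deepAttribution <- function(model, explain, background) {
  stack <- if (is(model, "MLPClassifier")) asLayerStack(model) else model
  explain <- as.matrix(explain)
  background <- as.matrix(background)
  .assert(nrow(background) >= 1, "background must be nonempty")
  .assert(ncol(explain) == ncol(background),
          "explain and background feature dimensions must match")
  n <- nrow(explain)
  fwdX <- stackForwardAll(stack, explain)
  phi <- matrix(0, n, ncol(explain))
  baseSum <- 0
  for (bIdx in seq_len(nrow(background))) {
    r <- background[bIdx, , drop = FALSE]
    fwdR <- stackForwardAll(stack, r)
    baseSum <- baseSum + as.numeric(fwdR$output)
    M <- matrix(1, n, 1)
    for (i in rev(seq_along(stack))) {
      layer <- stack[[i]]
      if (layer$type == "affine") {
        M <- M %*% t(layer$W)
      } else if (layer$type == "diag") {
        M <- rowScale(M, layer$scale)
      } else {  # nonlinearity: rescale rule
        zx <- fwdX$inputs[[i]]
        zr <- fwdR$inputs[[i]]
        dz <- zx - matrix(zr, n, ncol(zx), byrow = TRUE)
        ratio <- (applyAct(layer, zx) -
                    matrix(applyAct(layer, zr), n, ncol(zx), byrow = TRUE))
        small <- abs(dz) < 1e-7
        ratio <- ifelse(small, actGrad(layer, zx), ratio / dz)
        M <- M * ratio
      }
    }
    phi <- phi + M * (explain - matrix(r, n, ncol(explain), byrow = TRUE))
  }
  colnames(phi) <- colnames(explain)
  new("AttributionMatrix",
      phi = phi / nrow(background),
      baseValue = baseSum / nrow(background),
      explainCellIds = if (!is.null(rownames(explain))) rownames(explain)
                       else as.character(seq_len(n)),
      backgroundCellIds = if (!is.null(rownames(background)))
                            rownames(background)
                          else as.character(seq_len(nrow(background))))
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Unbiased sampling estimator of the Shapley values of the value function
#' \code{v(S) = E_background f(x_S, b_notS)}: each draw samples one
#' background reference and one random feature ordering, then walks the
#' ordering, crediting each feature with the change in model output when
#' its value switches from the reference's to the explained cell's.
#' Test oracle for \code{\link{deepAttribution}}.
#'
#' @param model a \linkS4class{MLPClassifier} or raw layer stack
#' @param cell numeric feature vector of the cell to explain
#' @param background background matrix (rows = reference cells)
#' @param nDraws number of sampled orderings (>= 1)
#' @param seed RNG seed (deterministic given seed)
#' @return numeric attribution vector, one entry per feature
#' @export
samplingShapley <- function(model, cell, background, nDraws = 200,
                            seed = 1) {
  stack <- if (is(model, "MLPClassifier")) asLayerStack(model) else model
  background <- as.matrix(background)
  .assert(nrow(background) >= 1, "background must be nonempty")
  .assert(nDraws >= 1, "nDraws must be >= 1")
  d <- length(cell)
  phi <- numeric(d)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(nDraws)) {
      r <- background[sample.int(nrow(background), 1L), ]
      ord <- sample.int(d)
      # rows 1..d+1: reference with the first j-1 features of `ord`
      # switched to the explained cell's values
      grid <- matrix(r, d + 1L, d, byrow = TRUE)
      for (j in seq_len(d))
        grid[seq.int(j + 1L, d + 1L), ord[j]] <- cell[ord[j]]
      f <- as.numeric(stackForwardFrom(stack, grid))
      phi[ord] <- phi[ord] + diff(f)
    }
  })
  phi / nDraws
}

#' Exact Shapley values by exhaustive coalition enumeration
#'
#' Computes the Shapley values of
#' \code{v(S) = E_background f(x_S, b_notS)} exactly by enumerating all
#' 2^d feature coalitions. Only feasible for small d (guarded at 16);
#' used as the ground-truth oracle for the attribution engine.
#'
#' @inheritParams samplingShapley
#' @return numeric attribution vector, one entry per feature
#' @export
exactShapley <- function(model, cell, background) {
  stack <- if (is(model, "MLPClassifier")) asLayerStack(model) else model
  background <- as.matrix(background)
  d <- length(cell)
  .assert(d <= 16, "exhaustive enumeration is limited to <= 16 features")
  nS <- 2L^d
  subsetBits <- matrix(FALSE, nS, d)
  for (i in seq_len(d))
    subsetBits[, i] <- bitwAnd(seq_len(nS) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  v <- numeric(nS)
  for (bIdx in seq_len(nrow(background))) {
    r <- background[bIdx, ]
    grid <- matrix(r, nS, d, byrow = TRUE)
    grid[subsetBits] <- matrix(cell, nS, d, byrow = TRUE)[subsetBits]
    v <- v + as.numeric(stackForwardFrom(stack, grid))
  }
  v <- v / nrow(background)
  sizes <- rowSums(subsetBits)
  # Shapley weight |S|! (d-|S|-1)! / d!; the full set never appears as an
  # "S without i", so give it weight 0 rather than factorial(-1)
  w <- ifelse(sizes == d, 0,
              factorial(sizes) * factorial(pmax(d - 1 - sizes, 0)) /
                factorial(d))
  phi <- numeric(d)
  for (i in seq_len(d)) {
    without <- !subsetBits[, i]
    withI <- which(without) + bitwShiftL(1L, i - 1L)
    phi[i] <- sum(w[without] * (v[withI] - v[without]))
  }
  phi
}

#' Average attributions across replicate models
#'
#' Element-wise mean of the per-cell, per-gene attributions and of the base
#' values of several \linkS4class{AttributionMatrix} objects computed over
#' identical explain cells and gene universes (the three replicate models of
#' the pipeline). The average retains local accuracy with respect to the
#' mean of the models' outputs.
#'
#' @param attributions list of \linkS4class{AttributionMatrix} objects
#' @return the averaged \linkS4class{AttributionMatrix}
#' @export
ensembleAverage <- function(attributions) {
  .assert(length(attributions) >= 1, "need at least one attribution matrix")
  ref <- attributions[[1]]
  for (a in attributions[-1]) {
    if (!identical(a@explainCellIds, ref@explainCellIds) ||
        !identical(colnames(a@phi), colnames(ref@phi)))
      stop("attribution matrices must share explain cells and genes",
           call. = FALSE)
  }
  phi <- Reduce(`+`, lapply(attributions, shapValues)) / length(attributions)
  new("AttributionMatrix", phi = phi,
      baseValue = mean(vapply(attributions, baseValue, numeric(1))),
      explainCellIds = ref@explainCellIds,
      backgroundCellIds = unique(unlist(lapply(attributions,
                                               function(a)
                                                 a@backgroundCellIds))))
}

#' Rank genes by median absolute attribution
#'
#' Global feature importance: per gene, the median of |phi| over the
#' explained cells, sorted descending. Ties are broken by ascending gene
#' identifier for determinism. The percentile is
#' \code{rank / n_genes * 100}.
#'
#' @param attr an \linkS4class{AttributionMatrix} with gene column names
#' @return data.frame with columns \code{gene_id}, \code{median_abs_shap},
#'   \code{rank}, \code{percentile}, ordered by rank
#' @export
rankGenes <- function(attr) {
  phi <- shapValues(attr)
  .assert(nrow(phi) >= 1, "need at least one explained cell")
  .assert(!is.null(colnames(phi)), "attribution matrix must name its genes")
  med <- apply(abs(phi), 2, median)
  ord <- order(-med, colnames(phi))
  n <- ncol(phi)
  data.frame(gene_id = colnames(phi)[ord], median_abs_shap = unname(med[ord]),
             rank = seq_len(n), percentile = seq_len(n) / n * 100,
             stringsAsFactors = FALSE)
}

#' Select the top-ranked fraction of genes ("SHAP genes")
#'
#' @param ranking a gene ranking from \code{\link{rankGenes}}
#' @param fraction fraction in (0, 1]; the set size is
#'   round-half-away-from-zero of \code{fraction * n_genes} (so 10% of 5160
#'   genes is 516)
#' @return character vector of gene identifiers
#' @export
topFraction <- function(ranking, fraction = 0.10) {
  .assert(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  k <- roundHalfUp(fraction * nrow(ranking))
  ranking$gene_id[seq_len(k)]
}

#' Per-subtype gene rankings
#'
#' For each cell subtype, explains up to \code{cap} randomly selected cells
#' of that subtype (all of them when fewer than \code{cap}) with every
#' replicate model, ensemble-averages the attributions and ranks genes.
#'
#' @param models list of trained \linkS4class{MLPClassifier} replicates
#' @param x cells x genes feature matrix with cell row names
#' @param subtypes factor of subtype labels, one per row of \code{x}
#' @param backgrounds list of background matrices, one per model
#' @param cap per-subtype explanation cap (default 1000)
#' @param seed subsampling seed
#' @return named list of gene rankings, one per subtype; empty subtypes are
#'   skipped with a warning
#' @export
subtypeRankings <- function(models, x, subtypes, backgrounds, cap = 1000,
                            seed = 1) {
  .assert(length(models) == length(backgrounds),
          "one background set per model required")
  lv <- if (is.factor(subtypes)) levels(subtypes)
        else levels(factor(subtypes))
  out <- list()
  for (k in seq_along(lv)) {
    idx <- which(subtypes == lv[k])
    if (!length(idx)) {
      warning("subtype ", lv[k], " has no cells; skipped", call. = FALSE)
      next
    }
    if (length(idx) > cap)
      idx <- withr::with_seed(childSeed(seed, k),
                              sample(idx, cap))
    xk <- x[idx, , drop = FALSE]
    attrs <- mapply(function(m, bg) deepAttribution(m, xk, bg),
                    models, backgrounds, SIMPLIFY = FALSE)
    out[[lv[k]]] <- rankGenes(ensembleAverage(attrs))
  }
  out
}

#' Gene-by-subtype percentile matrix
#'
#' @param rankings named list of per-subtype rankings from
#'   \code{\link{subtypeRankings}}
#' @return genes x subtypes matrix of ranking percentiles
#' @export
percentileMatrix <- function(rankings) {
  .assert(length(rankings) >= 1, "need at least one ranking")
  genes <- sort(rankings[[1]]$gene_id)
  mat <- vapply(rankings, function(r) {
    stats::setNames(r$percentile, r$gene_id)[genes]
  }, numeric(length(genes)))
  rownames(mat) <- genes
  mat
}

#' Subtype-specific highly predictive genes
#'
#' A gene is specific to a subtype when its ranking percentile there is (i)
#' within the top \code{topPct} percent and (ii) smaller than the mean of
#' its percentiles in the other subtypes by at least \code{sdMult} sample
#' standard deviations of those other percentiles. A zero-variance,
#' zero-difference row is never specific (the rule requires sd > 0 over the
#' other subtypes, avoiding vacuous flags).
#'
#' @param percentiles genes x subtypes percentile matrix from
#'   \code{\link{percentileMatrix}}
#' @param topPct top-percentile gate (default 2)
#' @param sdMult standard-deviation multiplier (default 1.25)
#' @return data.frame with columns \code{gene_id}, \code{subtype},
#'   \code{percentile}, \code{mean_others}, \code{sd_others}
#' @export
specificGenes <- function(percentiles, topPct = 2.0, sdMult = 1.25) {
  .assert(ncol(percentiles) >= 2,
          "specificity rule requires at least 2 subtypes")
  res <- list()
  for (k in seq_len(ncol(percentiles))) {
    own <- percentiles[, k]
    others <- percentiles[, -k, drop = FALSE]
    mo <- rowMeans(others)
    so <- apply(others, 1, sd)
    hit <- own <= topPct & so > 0 & (mo - own) >= sdMult * so
    if (any(hit))
      res[[length(res) + 1L]] <- data.frame(
        gene_id = rownames(percentiles)[hit],
        subtype = colnames(percentiles)[k],
        percentile = unname(own[hit]), mean_others = unname(mo[hit]),
        sd_others = unname(so[hit]), stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(gene_id = character(), subtype = character(),
                      percentile = numeric(), mean_others = numeric(),
                      sd_others = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
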