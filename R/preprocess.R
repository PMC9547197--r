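#' Centered log-ratio transform of lectin counts
#'
#' Computes \code{ln((x + 1) / g)} where g is the geometric mean of
#' \code{x + 1} across all cells: the standard across-cell CLR used for
#' antibody/lectin tag counts, with a +1 pseudocount because lectin counts
#' contain zeros. Output is exactly mean-centered.
#'
#' @param x nonnegative counts, one per cell (a numeric vector or a
#'   \linkS4class{LectinProfile})
#' @return for a numeric vector, the CLR values; for a
#'   \linkS4class{LectinProfile}, the profile with \code{clrValues} filled in
#' @examples
#' clrTransform(c(0, 1, 3))   # -log(2), 0, log(2)
#' @export
clrTransform <- function(x) {
  if (is(x, "LectinProfile")) {
    x@clrValues <- clrTransform(unname(x@rawCounts))
    names(x@clrValues) <- names(x@rawCounts)
    return(x)
  }
  .assert(is.numeric(x), "counts must be numeric")
  .assert(length(x) >= 2, "CLR needs at least 2 cells")
  .assert(all(x >= 0), "counts must be nonnegative")
  lx <- log(x + 1)
  lx - mean(lx)
}

#' Binarize cells by upper/lower quantile of a lectin signal
#'
#' The \code{floor(fraction * N)} cells with the highest values receive
#' label 1 (lectin-high), the same number with the lowest values label 0
#' (lectin-low); mid-range cells are excluded. Ties are broken by ascending
#' cell-identifier order, making the rule deterministic: under complete
#' ties the lexicographically last identifiers end up labeled 1.
#'
#' @param values numeric signal per cell (CLR lectin values)
#' @param cellIds cell identifiers (defaults to \code{names(values)})
#' @param fraction quantile fraction in (0, 0.5] (default 0.25)
#' @return a data.frame with columns \code{cell_id}, \code{value} and
#'   \code{label} (integer 0/1 or NA for excluded cells), in input order
#' @export
quartileBinarize <- function(values, cellIds = names(values),
                             fraction = 0.25) {
  .assert(fraction > 0 && fraction <= 0.5, "fraction must lie in (0, 0.5]")
  n <- length(values)
  .assert(n >= 4, "need at least 4 cells to binarize")
  .assert(!is.null(cellIds) && length(cellIds) == n,
          "cellIds must be provided and match values in length")
  .assert(!anyDuplicated(cellIds), "cell identifiers must be unique")
  k <- floor(fraction * n)
  ord <- order(values, cellIds)  # ascending value, ties by ascending id
  label <- rep(NA_integer_, n)
  label[ord[seq_len(k)]] <- 0L
  label[ord[seq.int(n - k + 1L, n)]] <- 1L
  data.frame(cell_id = cellIds, value = unname(values), label = label,
             stringsAsFactors = FALSE)
}

#' Randomly partition cells into train/validation/test sets
#'
#' Simple (non-stratified) random partition. The validation and test sets
#' get \code{floor(p * N)} cells each; the remainder goes to the training
#' set, so the default 0.72/0.18/0.10 on N = 1000 yields 720/180/100.
#'
#' @param cellIds cell identifiers
#' @param proportions train/validation/test proportions, positive, summing
#'   to 1
#' @param seed split seed
#' @return a factor with levels train/validation/test, named by cell id, in
#'   input order; deterministic given \code{seed}
#' @export
randomSplit <- function(cellIds, proportions = c(0.72, 0.18, 0.10),
                        seed = 1) {
  .checkProportions(proportions, "split proportions")
  .assert(length(proportions) == 3L, "proportions must be length 3")
  n <- length(cellIds)
  .assert(n >= 3, "need at least 3 cells to split")
  nVal <- floor(proportions[2] * n)
  nTest <- floor(proportions[3] * n)
  nTrain <- n - nVal - nTest
  perm <- withr::with_seed(seed, sample.int(n))
  split <- factor(rep(NA_character_, n),
                  levels = c("train", "validation", "test"))
  split[perm[seq_len(nTrain)]] <- "train"
  split[perm[seq.int(nTrain + 1L, nTrain + nVal)]] <- "validation"
  if (nTest > 0)
    split[perm[seq.int(nTrain + nVal + 1L, n)]] <- "test"
  names(split) <- cellIds
  split
}

#' Build a labeled, split dataset from paired expression + lectin data
#'
#' Fixed pipeline order: CLR-normalize the lectin counts, binarize by
#' quartile, drop mid-range cells, then randomly split the retained cells.
#' Labels are never computed from raw counts directly.
#'
#' @param sce a \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{logcounts} assay, a \code{subtype} colData column and lectin
#'   counts in \code{colData(sce)$phalRaw} (or pass \code{lectin})
#' @param lectin optional \linkS4class{LectinProfile} overriding
#'   \code{sce$phalRaw}
#' @param fraction quartile fraction (default 0.25)
#' @param proportions split proportions (default 0.72/0.18/0.10)
#' @param seed split seed
#' @return a \linkS4class{LabeledDataset}
#' @export
prepareLabeledDataset <- function(sce, lectin = NULL, fraction = 0.25,
                                  proportions = c(0.72, 0.18, 0.10),
                                  seed = 1) {
  raw <- if (!is.null(lectin)) rawCounts(lectin) else sce$phalRaw
  .assert(!is.null(raw), "no lectin counts found (colData phalRaw)")
  .assert(length(raw) == ncol(sce),
          "lectin counts must cover every cell in the expression matrix")
  clr <- clrTransform(unname(raw))
  lab <- quartileBinarize(clr, cellIds = colnames(sce), fraction = fraction)
  keep <- which(!is.na(lab$label))
  split <- randomSplit(lab$cell_id[keep], proportions, seed = seed)
  feats <- t(SummarizedExperiment::assay(sce, "logcounts")[, keep,
                                                           drop = FALSE])
  subtypes <- if (!is.null(sce$subtype)) sce$subtype[keep]
              else factor(rep("all", length(keep)))
  new("LabeledDataset",
      features = as.matrix(feats), labels = lab$label[keep], split = split,
      cellIds = lab$cell_id[keep], clrValues = lab$value[keep],
      excludedCellIds = lab$cell_id[-keep],
      subtypes = droplevels(subtypes))
}

#' Re-draw the train/validation/test split of a labeled dataset
#'
#' Used by the pipeline's replicate models, which share labels but differ in
#' the split seed.
#'
#' @param ld a \linkS4class{LabeledDataset}
#' @param seed new split seed
#' @param proportions split proportions
#' @return the dataset with a fresh split assignment
#' @export
resplitDataset <- function(ld, seed, proportions = c(0.72, 0.18, 0.10)) {
  stopifnot(is(ld, "LabeledDataset"))
  ld@split <- randomSplit(ld@cellIds, proportions, seed = seed)
  ld
}

# convenience extractors used across modules
splitSlice <- function(ld, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  idx <- ld@split == which
  list(x = ld@features[idx, , drop = FALSE], y = ld@labels[idx],
       cellIds = ld@cellIds[idx], subtypes = ld@subtypes[idx])
}
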