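#' Configuration of the synthetic paired transcriptome + lectin generator
#'
#' Holds every tunable of the synthetic-data module: dataset dimensions, the
#' cell-subtype mixture, the planted driver-gene signal, the noise model, and
#' the master seed. Defaults are the package's reference study conditions:
#' 3000 cells, 2000 genes, 9 unequally sized T-cell-like subtypes, 40
#' positive and 10 negative driver genes with a strong planted effect.
#'
#' @slot nCells number of cells
#' @slot nGenes number of genes
#' @slot nSubtypes number of cell subtypes
#' @slot subtypeProportions mixture proportions over subtypes (sums to 1)
#' @slot nDriversPos,nDriversNeg numbers of positive/negative driver genes
#' @slot effectSize dimensionless scale of the planted signal: the driver
#'   coefficients are jointly rescaled so the planted linear lectin score
#'   has this standard deviation over cells
#' @slot subtypeOffsetScale SD of the per-subtype lectin offsets
#' @slot noiseSd SD of the Gaussian noise on the latent lectin score
#' @slot meanLibrarySize mean sequencing library size (counts per cell), used
#'   for both the expression libraries and the lectin NB mean
#' @slot dropoutRate probability that any expression count is zeroed
#' @slot lowAbundanceDrivers if TRUE drivers are sampled from the bottom
#'   expression quartile instead of above-median genes
#' @slot seed master seed; all sub-seeds derive from it
#' @export
setClass("SyntheticConfig",
  representation(
    nCells = "integer", nGenes = "integer", nSubtypes = "integer",
    subtypeProportions = "numeric",
    nDriversPos = "integer", nDriversNeg = "integer",
    effectSize = "numeric", subtypeOffsetScale = "numeric",
    noiseSd = "numeric", meanLibrarySize = "numeric",
    dropoutRate = "numeric", lowAbundanceDrivers = "logical",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nCells < 1L || object@nGenes < 1L || object@nSubtypes < 1L)
    msg <- c(msg, "nCells, nGenes and nSubtypes must be positive")
  if (length(object@subtypeProportions) != object@nSubtypes)
    msg <- c(msg, "subtypeProportions must have one entry per subtype")
  if (any(object@subtypeProportions < 0) ||
      abs(sum(object@subtypeProportions) - 1) > 1e-9)
    msg <- c(msg, "subtypeProportions must be nonnegative and sum to 1")
  if (object@nDriversPos < 0L || object@nDriversNeg < 0L ||
      object@nDriversPos + object@nDriversNeg > object@nGenes)
    msg <- c(msg, "driver counts must be nonnegative and sum to <= nGenes")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (object@noiseSd < 0 || object@subtypeOffsetScale < 0 ||
      object@effectSize < 0)
    msg <- c(msg, "effectSize, subtypeOffsetScale and noiseSd must be >= 0")
  if (object@meanLibrarySize <= 0)
    msg <- c(msg, "meanLibrarySize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nCells,nGenes,nSubtypes dataset dimensions
#' @param subtypeProportions mixture proportions (default: 9 unequal groups)
#' @param nDriversPos,nDriversNeg planted driver counts
#' @param effectSize standard deviation of the planted linear lectin score
#'   (driver coefficients are drawn as signed U(0.5, 1.5) and jointly
#'   rescaled to reach it)
#' @param subtypeOffsetScale SD of subtype offsets on the latent lectin score
#' @param noiseSd SD of per-cell Gaussian noise on the latent lectin score
#' @param meanLibrarySize mean counts per cell
#' @param dropoutRate probability of zeroing an expression count
#' @param lowAbundanceDrivers sample drivers from the bottom expression
#'   quartile (tests the low-abundance-gene argument)
#' @param seed master seed
#' @return a validated \linkS4class{SyntheticConfig}
#' @examples
#' cfg <- syntheticConfig(nCells = 100, nGenes = 50, seed = 7)
#' @export
syntheticConfig <- function(nCells = 3000, nGenes = 2000, nSubtypes = 9,
                            subtypeProportions = c(0.25, 0.18, 0.14, 0.12,
                                                   0.10, 0.08, 0.06, 0.04,
                                                   0.03),
                            nDriversPos = 40, nDriversNeg = 10,
                            effectSize = 1.0, subtypeOffsetScale = 1.2,
                            noiseSd = 0.25, meanLibrarySize = 2000,
                            dropoutRate = 0.3, lowAbundanceDrivers = FALSE,
                            seed = 1) {
  if (nSubtypes != 9 && missing(subtypeProportions))
    subtypeProportions <- rep(1 / nSubtypes, nSubtypes)
  obj <- new("SyntheticConfig",
    nCells = as.integer(nCells), nGenes = as.integer(nGenes),
    nSubtypes = as.integer(nSubtypes),
    subtypeProportions = as.numeric(subtypeProportions),
    nDriversPos = as.integer(nDriversPos),
    nDriversNeg = as.integer(nDriversNeg),
    effectSize = as.numeric(effectSize),
    subtypeOffsetScale = as.numeric(subtypeOffsetScale),
    noiseSd = as.numeric(noiseSd),
    meanLibrarySize = as.numeric(meanLibrarySize),
    dropoutRate = as.numeric(dropoutRate),
    lowAbundanceDrivers = isTRUE(lowAbundanceDrivers),
    seed = as.integer(seed)
  )
  validObject(obj)
  obj
}

#' Planted ground truth of a synthetic dataset
#'
#' Records which genes drive the lectin signal, with what signed
#' coefficients, plus the per-subtype offsets and the generator seed.
#'
#' @slot driverIds driver gene identifiers
#' @slot driverCoefficients signed coefficients, named by driver id
#' @slot subtypeOffsets per-subtype additive offsets, named by subtype
#' @slot seed generator seed
#' @export
setClass("GroundTruthManifest",
  representation(
    driverIds = "character", driverCoefficients = "numeric",
    subtypeOffsets = "numeric", seed = "integer"
  )
)

setValidity("GroundTruthManifest", function(object) {
  if (length(object@driverIds) != length(object@driverCoefficients))
    return("one coefficient per driver id required")
  if (length(object@driverIds) &&
      !identical(names(object@driverCoefficients), object@driverIds))
    return("driverCoefficients must be named by driverIds")
  TRUE
})

#' Per-cell lectin profile
#'
#' Raw lectin (PHA-L) read counts per cell and, once normalized, their
#' centered log-ratio values. \code{clrValues} has length zero until
#' \code{\link{clrTransform}} has been applied.
#'
#' @slot rawCounts nonnegative integer counts, named by cell id
#' @slot clrValues CLR-transformed values (length 0 before normalization)
#' @export
setClass("LectinProfile",
  representation(rawCounts = "numeric", clrValues = "numeric")
)

setValidity("LectinProfile", function(object) {
  if (any(object@rawCounts < 0)) return("rawCounts must be nonnegative")
  if (is.null(names(object@rawCounts))) return("rawCounts must be named")
  if (length(object@clrValues) &&
      length(object@clrValues) != length(object@rawCounts))
    return("clrValues must match rawCounts in length")
  TRUE
})

#' Quartile-labeled, split dataset ready for model training
#'
#' Cells in the top lectin quartile carry label 1 (PHA-L-high), the bottom
#' quartile label 0 (PHA-L-low); mid-range cells are excluded. Retained cells
#' are partitioned into train/validation/test.
#'
#' @slot features retained cells x genes matrix (log-normalized expression)
#' @slot labels integer 0/1 per retained cell
#' @slot split factor with levels train/validation/test
#' @slot cellIds retained cell identifiers
#' @slot clrValues CLR lectin value per retained cell
#' @slot excludedCellIds mid-quartile cells that were dropped
#' @slot subtypes subtype label per retained cell
#' @export
setClass("LabeledDataset",
  representation(
    features = "matrix", labels = "integer", split = "factor",
    cellIds = "character", clrValues = "numeric",
    excludedCellIds = "character", subtypes = "factor"
  )
)

setValidity("LabeledDataset", function(object) {
  n <- length(object@cellIds)
  if (nrow(object@features) != n || length(object@labels) != n ||
      length(object@split) != n || length(object@clrValues) != n)
    return("features, labels, split and clrValues must agree in length")
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must be 0/1")
  if (!identical(levels(object@split), c("train", "validation", "test")))
    return("split levels must be train/validation/test")
  TRUE
})

#' Training hyper-parameters of the neural network classifier
#'
#' @slot batchSize mini-batch size (default 128)
#' @slot learningRate initial learning rate (default 1e-4, Adam)
#' @slot maxEpochs epoch budget; cosine annealing spans it (default 300)
#' @slot weightDecay decoupled weight decay on the dense weights, scaled by
#'   the current learning rate (default 30, i.e. 3e-3 shrinkage per step at
#'   the peak rate)
#' @slot seed seed for shuffling, dropout and initialization fallback
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", learningRate = "numeric",
                 maxEpochs = "integer", weightDecay = "numeric",
                 seed = "integer")
)

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@weightDecay < 0) return("weightDecay must be >= 0")
  TRUE
})

#' @param batchSize,learningRate,maxEpochs,weightDecay,seed see slot
#'   documentation
#' @return a validated \linkS4class{TrainConfig}
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(batchSize = 128, learningRate = 1e-4,
                        maxEpochs = 300, weightDecay = 30, seed = 1) {
  obj <- new("TrainConfig", batchSize = as.integer(batchSize),
             learningRate = as.numeric(learningRate),
             maxEpochs = as.integer(maxEpochs),
             weightDecay = as.numeric(weightDecay),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Feed-forward binary classifier for the glycan phenotype
#'
#' Four hidden layers (128, 64, 16, 8 units); leaky rectifier (slope 0.01),
#' dropout (0.4, 0.4, 0.2) and batch normalization after hidden layers 1-3;
#' after hidden layer 4 the eight pre-activations are averaged
#' (a parameter-free readout) and passed through a sigmoid, giving the
#' predicted probability.
#'
#' @slot inputDim number of input genes
#' @slot hiddenSizes hidden layer widths
#' @slot dropoutProbs dropout probabilities after hidden layers 1-3
#' @slot negativeSlope leaky-rectifier negative slope
#' @slot params list of weights, biases, batch-norm parameters and running
#'   statistics
#' @slot trained TRUE once trainMLP has run
#' @slot history per-epoch train/validation loss data.frame
#' @slot bestEpoch epoch of the returned (best-validation-loss) checkpoint
#' @slot geneIds optional input feature names
#' @slot seed initialization seed
#' @export
setClass("MLPClassifier",
  representation(
    inputDim = "integer", hiddenSizes = "integer", dropoutProbs = "numeric",
    negativeSlope = "numeric", params = "list", trained = "logical",
    history = "data.frame", bestEpoch = "integer", geneIds = "character",
    seed = "integer"
  )
)

setValidity("MLPClassifier", function(object) {
  if (length(object@hiddenSizes) != 4L)
    return("exactly 4 hidden layers required")
  if (length(object@dropoutProbs) != 3L)
    return("dropout applies after hidden layers 1-3 only")
  TRUE
})

#' Per-cell, per-gene Shapley-style attributions
#'
#' \code{phi[c, g]} is the contribution of gene g to the predicted
#' probability of cell c relative to the background expectation
#' (\code{baseValue}); per cell, \code{sum(phi) + baseValue} recovers the
#' model output (local accuracy).
#'
#' @slot phi explained cells x genes attribution matrix (probability units)
#' @slot baseValue mean model output over the background cells
#' @slot explainCellIds,backgroundCellIds cell identifiers
#' @export
setClass("AttributionMatrix",
  representation(
    phi = "matrix", baseValue = "numeric",
    explainCellIds = "character", backgroundCellIds = "character"
  )
)

setValidity("AttributionMatrix", function(object) {
  if (nrow(object@phi) != length(object@explainCellIds))
    return("phi rows must match explainCellIds")
  if (length(object@baseValue) != 1L)
    return("baseValue must be a scalar")
  TRUE
})

#' End-to-end pipeline configuration
#'
#' @slot synthetic a \linkS4class{SyntheticConfig}, or NULL when reading
#'   files (then set \code{paths})
#' @slot paths named list with entries \code{mtxDir} (or \code{matrix},
#'   \code{features}, \code{barcodes}), \code{lectin}, \code{subtypes};
#'   empty for synthetic data
#' @slot labelFraction quartile fraction for label construction (0.25)
#' @slot splitProportions train/validation/test proportions (0.72/0.18/0.10)
#' @slot replicateSeeds split seeds, one model trained per seed (3 by
#'   default)
#' @slot nExplain cells explained by the attribution step (1000)
#' @slot nBackground background reference cells per model (100)
#' @slot subtypeCap per-subtype explanation cap (1000)
#' @slot nPermutations permutation-importance repeats (25)
#' @slot deaLogfcThreshold,deaAlpha differential-expression settings
#' @slot maxEpochs classifier epoch budget
#' @slot topFrac top-ranking fraction defining the SHAP/PFI gene sets (0.10)
#' @slot doSubtypes,doBaselines stage toggles
#' @slot outputDir output directory ("" = do not write files)
#' @export
setClass("PipelineConfig",
  representation(
    synthetic = "ANY", paths = "list", labelFraction = "numeric",
    splitProportions = "numeric", replicateSeeds = "integer",
    nExplain = "integer", nBackground = "integer", subtypeCap = "integer",
    nPermutations = "integer", deaLogfcThreshold = "numeric",
    deaAlpha = "numeric", maxEpochs = "integer", topFrac = "numeric",
    doSubtypes = "logical", doBaselines = "logical", outputDir = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!(is.null(object@synthetic) || is(object@synthetic, "SyntheticConfig")))
    msg <- c(msg, "synthetic must be NULL or a SyntheticConfig")
  if (is.null(object@synthetic) && !length(object@paths))
    msg <- c(msg, "either synthetic or paths must be given")
  if (object@labelFraction <= 0 || object@labelFraction > 0.5)
    msg <- c(msg, "labelFraction must lie in (0, 0.5]")
  if (length(object@splitProportions) != 3L ||
      any(object@splitProportions <= 0) ||
      abs(sum(object@splitProportions) - 1) > 1e-9)
    msg <- c(msg, "splitProportions must be 3 positive values summing to 1")
  if (length(object@replicateSeeds) < 1L)
    msg <- c(msg, "at least one replicate seed required")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param synthetic a \linkS4class{SyntheticConfig} (NULL to read files)
#' @param paths input file paths when \code{synthetic} is NULL
#' @param labelFraction,splitProportions label/split settings
#' @param replicateSeeds split seeds (one trained model each)
#' @param nExplain,nBackground,subtypeCap explainer settings
#' @param nPermutations permutation-importance repeats
#' @param deaLogfcThreshold,deaAlpha differential-expression settings
#' @param maxEpochs classifier epoch budget
#' @param topFrac top-fraction defining SHAP/PFI gene sets
#' @param doSubtypes,doBaselines stage toggles
#' @param outputDir output directory, "" to skip writing
#' @return a validated \linkS4class{PipelineConfig}
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(), paths = list(),
                           labelFraction = 0.25,
                           splitProportions = c(0.72, 0.18, 0.10),
                           replicateSeeds = c(101, 202, 303),
                           nExplain = 1000, nBackground = 100,
                           subtypeCap = 1000, nPermutations = 25,
                           deaLogfcThreshold = 0.25, deaAlpha = 0.05,
                           maxEpochs = 300, topFrac = 0.10,
                           doSubtypes = TRUE, doBaselines = TRUE,
                           outputDir = "") {
  obj <- new("PipelineConfig",
    synthetic = synthetic, paths = paths,
    labelFraction = as.numeric(labelFraction),
    splitProportions = as.numeric(splitProportions),
    replicateSeeds = as.integer(replicateSeeds),
    nExplain = as.integer(nExplain), nBackground = as.integer(nBackground),
    subtypeCap = as.integer(subtypeCap),
    nPermutations = as.integer(nPermutations),
    deaLogfcThreshold = as.numeric(deaLogfcThreshold),
    deaAlpha = as.numeric(deaAlpha), maxEpochs = as.integer(maxEpochs),
    topFrac = as.numeric(topFrac), doSubtypes = isTRUE(doSubtypes),
    doBaselines = isTRUE(doBaselines), outputDir = as.character(outputDir)
  )
  validObject(obj)
  obj
}
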