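#' Predicted probability of the positive (lectin-high) phenotype
#'
#' @param object a trained or untrained \linkS4class{MLPClassifier}
#' @param newdata cells x genes feature matrix
#' @return numeric vector of probabilities in (0, 1), one per row
#' @export
setGeneric("predictProba", function(object, newdata)
  standardGeneric("predictProba"))

#' Number of learnable parameters
#'
#' @param object a model object
#' @return integer parameter count (weights + biases + batch-norm affine
#'   terms)
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' Driver-gene accessors for a ground-truth manifest
#'
#' @param object a \linkS4class{GroundTruthManifest}
#' @return \code{driverIds}: all planted driver gene ids;
#'   \code{driverCoefficients}: their signed coefficients;
#'   \code{strongDrivers}: ids in the upper half of the coefficient
#'   magnitude distribution (|beta| at or above the median |beta|), or
#'   above an explicit \code{cutoff}
#' @export
setGeneric("driverIds", function(object) standardGeneric("driverIds"))

#' @rdname driverIds
#' @export
setGeneric("driverCoefficients", function(object)
  standardGeneric("driverCoefficients"))

#' @rdname driverIds
#' @param cutoff magnitude cutoff defining a strong driver (default: the
#'   median absolute coefficient)
#' @export
setGeneric("strongDrivers", function(object, cutoff)
  standardGeneric("strongDrivers"))

#' Attribution matrix accessors
#'
#' @param object an \linkS4class{AttributionMatrix}
#' @return \code{shapValues}: the cells x genes attribution matrix;
#'   \code{baseValue}: the background expectation of the model output
#' @export
setGeneric("shapValues", function(object) standardGeneric("shapValues"))

#' @rdname shapValues
#' @export
setGeneric("baseValue", function(object) standardGeneric("baseValue"))

#' Lectin profile accessors
#'
#' @param object a \linkS4class{LectinProfile}
#' @return \code{rawCounts}: named per-cell raw counts; \code{clrValues}:
#'   CLR-normalized values (error if not yet normalized)
#' @export
setGeneric("rawCounts", function(object) standardGeneric("rawCounts"))

#' @rdname rawCounts
#' @export
setGeneric("clrValues", function(object) standardGeneric("clrValues"))

setMethod("driverIds", "GroundTruthManifest", function(object)
  object@driverIds)

setMethod("driverCoefficients", "GroundTruthManifest", function(object)
  object@driverCoefficients)

setMethod("strongDrivers", "GroundTruthManifest",
  function(object, cutoff) {
    if (missing(cutoff)) cutoff <- median(abs(object@driverCoefficients))
    object@driverIds[abs(object@driverCoefficients) >= cutoff]
  })

setMethod("shapValues", "AttributionMatrix", function(object) object@phi)

setMethod("baseValue", "AttributionMatrix", function(object)
  object@baseValue)

setMethod("rawCounts", "LectinProfile", function(object) object@rawCounts)

setMethod("clrValues", "LectinProfile", function(object) {
  if (!length(object@clrValues))
    stop("lectin profile has not been CLR-normalized yet", call. = FALSE)
  object@clrValues
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nCells, "cells x", object@nGenes,
      "genes,", object@nSubtypes, "subtypes\n")
  cat("  drivers: ", object@nDriversPos, " positive / ",
      object@nDriversNeg, " negative (effect size ", object@effectSize,
      ")\n", sep = "")
  cat("  noise SD", object@noiseSd, "| subtype offset SD",
      object@subtypeOffsetScale, "| dropout", object@dropoutRate,
      "| seed", object@seed, "\n")
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat("GroundTruthManifest:", length(object@driverIds), "planted drivers (",
      sum(object@driverCoefficients > 0), "positive,",
      sum(object@driverCoefficients < 0), "negative ),",
      length(object@subtypeOffsets), "subtype offsets, seed",
      object@seed, "\n")
})

setMethod("show", "LectinProfile", function(object) {
  cat("LectinProfile:", length(object@rawCounts), "cells; raw count range [",
      min(object@rawCounts), ",", max(object@rawCounts), "];",
      if (length(object@clrValues)) "CLR-normalized" else "raw only", "\n")
})

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", nrow(object@features), "retained cells x",
      ncol(object@features), "genes\n")
  cat("  labels: ", sum(object@labels == 1L), " high / ",
      sum(object@labels == 0L), " low; excluded ",
      length(object@excludedCellIds), " mid-quartile cells\n", sep = "")
  print(table(object@split))
})

setMethod("show", "MLPClassifier", function(object) {
  cat("MLPClassifier:", object@inputDim, "inputs ->",
      paste(object@hiddenSizes, collapse = "-"),
      "-> mean readout -> sigmoid\n")
  cat("  ", nParams(object), " parameters; ",
      if (object@trained) sprintf("trained (best epoch %d)",
                                  object@bestEpoch)
      else "untrained", "\n", sep = "")
})

setMethod("show", "AttributionMatrix", function(object) {
  cat("AttributionMatrix:", nrow(object@phi), "explained cells x",
      ncol(object@phi), "genes;", length(object@backgroundCellIds),
      "background cells; base value",
      format(object@baseValue, digits = 4), "\n")
})
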