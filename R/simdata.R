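#' Generate a synthetic single-cell expression matrix
#'
#' Cells are assigned to subtypes by multinomial sampling of the configured
#' proportions. Counts follow a negative-binomial model with gene-specific
#' baseline abundances (log-normal), gene-specific dispersions drawn
#' log-uniformly from [0.1, 2], subtype-specific log-scale shifts for a 20%
#' marker subset of genes, ten latent co-expression programs (sparse random
#' loadings over 10% of genes each, standard-normal per-cell activities)
#' emulating the modular correlation structure of real transcriptomes, and
#' multiplicative per-cell library-size variation. Counts are then zeroed
#' with probability \code{dropoutRate} (dropout) and delivered
#' log1p-library-normalized (counts / library size x 10000, then log1p).
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{logcounts} assay (genes x cells) and a \code{subtype} colData
#'   column. Deterministic given \code{config@seed}.
#' @examples
#' sce <- generateExpression(syntheticConfig(nCells = 100, nGenes = 50,
#'                                           seed = 7))
#' @export
generateExpression <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  nC <- config@nCells
  nG <- config@nGenes
  withr::with_seed(childSeed(config@seed, 1L), {
    subtype <- sample.int(config@nSubtypes, nC, replace = TRUE,
                          prob = config@subtypeProportions)
    # gene baseline relative abundances, log-normal
    abund <- exp(rnorm(nG, mean = 0, sd = 1.2))
    abund <- abund / sum(abund)
    # subtype-specific shifts for a 20% marker subset (natural-log scale)
    nMark <- max(1L, floor(0.2 * nG))
    markers <- sample.int(nG, nMark)
    shift <- matrix(0, nrow = config@nSubtypes, ncol = nG)
    shift[, markers] <- rnorm(config@nSubtypes * nMark, sd = 0.5)
    # latent co-expression programs: sparse loadings, per-cell activities
    nFac <- 10L
    loadings <- matrix(0, nFac, nG)
    for (f in seq_len(nFac)) {
      gIdx <- sample.int(nG, max(1L, floor(0.1 * nG)))
      loadings[f, gIdx] <- rnorm(length(gIdx), sd = 0.4)
    }
    activity <- matrix(rnorm(nC * nFac), nC, nFac)
    # per-gene dispersion, log-uniform on [0.1, 2]
    disp <- exp(runif(nG, log(0.1), log(2)))
    lib <- config@meanLibrarySize * exp(rnorm(nC, sd = 0.3))
    mu <- (lib * exp(shift[subtype, , drop = FALSE] +
                       activity %*% loadings)) *
      rep(abund, each = nC)
    counts <- matrix(
      rnbinom(nC * nG, mu = as.numeric(mu), size = rep(1 / disp, each = nC)),
      nrow = nC, ncol = nG
    )
    if (config@dropoutRate > 0)
      counts[runif(nC * nG) < config@dropoutRate] <- 0L
  })
  libSize <- rowSums(counts)
  lognorm <- log1p(counts / pmax(libSize, 1) * 1e4)
  geneIds <- sprintf("gene%04d", seq_len(nG))
  cellIds <- sprintf("cell%05d", seq_len(nC))
  dimnames(lognorm) <- list(cellIds, geneIds)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = t(lognorm)),
    colData = S4Vectors::DataFrame(
      subtype = factor(paste0("subtype", subtype),
                       levels = paste0("subtype", seq_len(config@nSubtypes))),
      row.names = cellIds
    )
  )
}

#' Plant driver genes and subtype offsets for the lectin signal
#'
#' Drivers are sampled without replacement from genes with above-median mean
#' expression (or from the bottom quartile when
#' \code{config@lowAbundanceDrivers}), so that planted signal sits where the
#' classifier can see it. Coefficient magnitudes are drawn as
#' \code{U(0.5, 1.5)} with positive sign for the first \code{nDriversPos}
#' drivers and negative for the rest, then jointly rescaled so that the
#' planted linear score \code{sum_g beta_g z_g} has standard deviation
#' \code{effectSize} over the cells — making the planted signal-to-noise
#' ratio reproducible across datasets regardless of how strongly the
#' sampled drivers happen to co-vary. Subtype offsets are
#' N(0, subtypeOffsetScale^2).
#'
#' @param sce expression data from \code{\link{generateExpression}}
#' @param config the \linkS4class{SyntheticConfig} used to generate it
#' @return a \linkS4class{GroundTruthManifest}
#' @export
plantGroundTruth <- function(sce, config) {
  stopifnot(is(config, "SyntheticConfig"))
  nDrv <- config@nDriversPos + config@nDriversNeg
  geneIds <- rownames(sce)
  meanExpr <- Matrix::rowMeans(SummarizedExperiment::assay(sce, "logcounts"))
  withr::with_seed(childSeed(config@seed, 2L), {
    if (nDrv > 0L) {
      pool <- if (config@lowAbundanceDrivers) {
        geneIds[meanExpr <= quantile(meanExpr, 0.25)]
      } else {
        geneIds[meanExpr > median(meanExpr)]
      }
      if (length(pool) < nDrv)
        stop("not enough eligible genes to plant ", nDrv, " drivers",
             call. = FALSE)
      drivers <- sample(pool, nDrv)
      beta <- runif(nDrv, 0.5, 1.5) *
        rep(c(1, -1), c(config@nDriversPos, config@nDriversNeg))
      names(beta) <- drivers
      # rescale so the planted linear score has SD = effectSize
      z <- t(SummarizedExperiment::assay(sce, "logcounts")[drivers, ,
                                                           drop = FALSE])
      z <- scale(z)
      z[is.nan(z)] <- 0
      sdSig <- sd(as.numeric(z %*% beta))
      if (sdSig > 0) beta <- beta * config@effectSize / sdSig
    } else {
      drivers <- character()
      beta <- numeric()
    }
    offsets <- rnorm(config@nSubtypes, sd = config@subtypeOffsetScale)
  })
  names(offsets) <- levels(sce$subtype)
  new("GroundTruthManifest", driverIds = drivers, driverCoefficients = beta,
      subtypeOffsets = offsets, seed = config@seed)
}

#' Generate per-cell lectin counts from planted drivers
#'
#' The latent score of cell c is
#' \code{s_c = sum_g beta_g z_cg + u_subtype(c) + eps_c} with
#' \code{eps ~ N(0, noiseSd^2)} and z the standardized expression of the
#' driver genes. Raw counts are negative-binomial with mean
#' \code{exp(s_c)} rescaled so the mean NB mean equals
#' \code{meanLibrarySize}. Centered scores are clipped at +/-8 before the
#' exponential so that extreme planted effects cannot collapse nearly all NB
#' means to zero.
#'
#' @param sce expression data from \code{\link{generateExpression}}
#' @param truth a \linkS4class{GroundTruthManifest}; every driver must exist
#'   in \code{rownames(sce)}
#' @param config the \linkS4class{SyntheticConfig}
#' @return a \linkS4class{LectinProfile} (raw counts only), cells ordered as
#'   in \code{sce}. Deterministic given \code{config@seed}.
#' @export
generateLectin <- function(sce, truth, config) {
  stopifnot(is(truth, "GroundTruthManifest"), is(config, "SyntheticConfig"))
  missing <- setdiff(truth@driverIds, rownames(sce))
  if (length(missing))
    stop("driver genes absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  score <- latentLectinScore(sce, truth)
  withr::with_seed(childSeed(config@seed, 3L), {
    s <- score + rnorm(ncol(sce), sd = config@noiseSd)
    s <- pmin(pmax(s - mean(s), -8), 8)
    mu <- config@meanLibrarySize * exp(s) / mean(exp(s))
    raw <- rnbinom(ncol(sce), mu = mu, size = 10)
  })
  names(raw) <- colnames(sce)
  new("LectinProfile", rawCounts = raw, clrValues = numeric())
}

# deterministic part of the latent score: planted linear signal + offsets
latentLectinScore <- function(sce, truth) {
  s <- rep(0, ncol(sce))
  if (length(truth@driverIds)) {
    z <- t(SummarizedExperiment::assay(sce, "logcounts")[truth@driverIds, ,
                                                         drop = FALSE])
    z <- scale(z)
    z[is.nan(z)] <- 0  # constant driver column: no signal contribution
    s <- s + as.numeric(z %*% truth@driverCoefficients)
  }
  if (length(truth@subtypeOffsets))
    s <- s + truth@subtypeOffsets[as.character(sce$subtype)]
  unname(s)
}

#' Generate a complete synthetic paired dataset
#'
#' Runs \code{\link{generateExpression}}, \code{\link{plantGroundTruth}} and
#' \code{\link{generateLectin}} with sub-seeds derived from
#' \code{config@seed}, and stores the lectin counts and ground truth inside
#' the returned object.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{logcounts}, colData columns \code{subtype} and \code{phalRaw}
#'   (lectin counts), and \code{metadata()} entries \code{groundTruth} and
#'   \code{config}
#' @examples
#' sce <- generateDataset(syntheticConfig(nCells = 200, nGenes = 80,
#'                                        seed = 3))
#' @export
generateDataset <- function(config) {
  sce <- generateExpression(config)
  truth <- plantGroundTruth(sce, config)
  lectin <- generateLectin(sce, truth, config)
  sce$phalRaw <- rawCounts(lectin)
  S4Vectors::metadata(sce)$groundTruth <- truth
  S4Vectors::metadata(sce)$config <- config
  sce
}
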