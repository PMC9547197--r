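#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), lectin CLR normalization + quartile label construction, one
#' train/validation/test split and one trained neural-network classifier
#' per replicate seed, per-replicate evaluation, Shapley attribution of a
#' shared explanation set per model followed by ensemble averaging and gene
#' ranking, top-fraction gene selection, optional per-subtype rankings and
#' the subtype-specificity rule, permutation feature importance (first
#' replicate's model and test split), Wilcoxon differential expression on
#' the labeled cells, gene-set overlaps, optional ensemble baselines, and
#' ground-truth recovery scoring when a manifest is present. Fully
#' deterministic given the configuration; test-split labels are only read
#' by the evaluation stages.
#'
#' @param config a \linkS4class{PipelineConfig}
#' @param verbose print stage progress
#' @return the analysis report (a nested list); when
#'   \code{config@outputDir} is set, all module outputs and
#'   \code{report.json} are written there
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  say <- function(...) if (verbose) message("[glycanShap] ", ...)
  stages <- list()
  addStage <- function(name, inputs) {
    stages[[length(stages) + 1L]] <<- list(stage = name, inputs = inputs)
  }

  # ---- data ----------------------------------------------------------------
  if (!is.null(config@synthetic)) {
    say("simulating synthetic dataset")
    sce <- generateDataset(config@synthetic)
    truth <- S4Vectors::metadata(sce)$groundTruth
    addStage("simulate", "config")
  } else {
    say("reading input files")
    p <- config@paths
    sce <- if (!is.null(p$mtxDir)) readMatrixTriplet(p$mtxDir)
           else readMatrixTriplet(matrixPath = p$matrix,
                                  featuresPath = p$features,
                                  barcodesPath = p$barcodes)
    lectin <- readLectinCSV(p$lectin)
    .assert(identical(sort(names(rawCounts(lectin))), sort(colnames(sce))),
            "lectin CSV cells must match the expression matrix")
    sce$phalRaw <- rawCounts(lectin)[colnames(sce)]
    if (!is.null(p$subtypes)) {
      st <- readSubtypeTSV(p$subtypes)
      sce$subtype <- st[colnames(sce)]
    } else {
      sce$subtype <- factor(rep("all", ncol(sce)))
    }
    truth <- NULL
    addStage("read", unlist(p, use.names = FALSE))
  }

  # ---- preprocessing -------------------------------------------------------
  say("CLR normalization, quartile labels")
  ld <- prepareLabeledDataset(sce, fraction = config@labelFraction,
                              proportions = config@splitProportions,
                              seed = config@replicateSeeds[1])
  addStage("preprocess", "lectin counts, expression")

  # ---- replicate training --------------------------------------------------
  models <- list()
  replicates <- list()
  datasets <- list()
  for (i in seq_along(config@replicateSeeds)) {
    seed <- config@replicateSeeds[i]
    say("training replicate ", i, " (split seed ", seed, ")")
    ldi <- resplitDataset(ld, seed, config@splitProportions)
    tr <- splitSlice(ldi, "train")
    va <- splitSlice(ldi, "validation")
    te <- splitSlice(ldi, "test")
    model <- buildMLP(ncol(ld@features), seed = childSeed(seed, 11L),
                      geneIds = colnames(ld@features))
    model <- trainMLP(model, tr$x, tr$y, va$x, va$y,
                      trainConfig(maxEpochs = config@maxEpochs,
                                  seed = childSeed(seed, 12L)))
    metrics <- list(
      train = evaluateClassifier(predictProba(model, tr$x), tr$y),
      validation = evaluateClassifier(predictProba(model, va$x), va$y),
      test = evaluateClassifier(predictProba(model, te$x), te$y))
    models[[i]] <- model
    datasets[[i]] <- ldi
    replicates[[i]] <- list(split_seed = seed,
                            best_epoch = model@bestEpoch,
                            metrics = metrics)
    addStage(paste0("train_replicate_", i), "train+validation splits")
    addStage(paste0("evaluate_replicate_", i), "all splits")
  }

  # ---- attribution ---------------------------------------------------------
  say("Shapley attribution (", length(models), " models)")
  nEx <- min(config@nExplain, nrow(ld@features))
  exIdx <- withr::with_seed(childSeed(config@replicateSeeds[1], 21L),
                            sample.int(nrow(ld@features), nEx))
  explainX <- ld@features[exIdx, , drop = FALSE]
  rownames(explainX) <- ld@cellIds[exIdx]
  backgrounds <- lapply(seq_along(models), function(i) {
    tr <- splitSlice(datasets[[i]], "train")
    bIdx <- withr::with_seed(childSeed(config@replicateSeeds[i], 22L),
                             sample.int(nrow(tr$x),
                                        min(config@nBackground,
                                            nrow(tr$x))))
    bg <- tr$x[bIdx, , drop = FALSE]
    rownames(bg) <- tr$cellIds[bIdx]
    bg
  })
  attrs <- mapply(function(m, bg) deepAttribution(m, explainX, bg),
                  models, backgrounds, SIMPLIFY = FALSE)
  attrAvg <- ensembleAverage(attrs)
  # local-accuracy audit: per cell, attributions + base value must recover
  # the mean model output
  fBar <- Reduce(`+`, lapply(models, predictProba,
                             newdata = explainX)) / length(models)
  localAccErr <- max(abs(rowSums(shapValues(attrAvg)) -
                           (fBar - baseValue(attrAvg))))
  ranking <- rankGenes(attrAvg)
  shapGenes <- topFraction(ranking, config@topFrac)
  addStage("attribution", "labeled cells (no test labels)")

  # ---- subtype rankings ----------------------------------------------------
  subtypeResult <- NULL
  specific <- NULL
  if (config@doSubtypes && nlevels(ld@subtypes) >= 2) {
    say("per-subtype rankings")
    sr <- subtypeRankings(models, ld@features, ld@subtypes, backgrounds,
                          cap = config@subtypeCap,
                          seed = childSeed(config@replicateSeeds[1], 23L))
    pm <- percentileMatrix(sr)
    specific <- specificGenes(pm)
    subtypeResult <- sr
    addStage("subtype_attribution", "labeled cells by subtype")
  }

  # ---- permutation importance ---------------------------------------------
  say("permutation feature importance")
  te1 <- splitSlice(datasets[[1]], "test")
  pfi <- permutationImportance(models[[1]], te1$x, te1$y,
                               nPermutations = config@nPermutations,
                               seed = childSeed(config@replicateSeeds[1],
                                                31L))
  pfiGenes <- pfi$gene_id[seq_len(roundHalfUp(config@topFrac * nrow(pfi)))]
  addStage("pfi", "first replicate test split")

  # ---- differential expression --------------------------------------------
  say("differential expression")
  dea <- wilcoxonDE(ld@features, ld@labels,
                    logfcThreshold = config@deaLogfcThreshold,
                    alpha = config@deaAlpha)
  deaGenes <- dea$gene_id[dea$significant]
  addStage("dea", "labeled cells")

  # ---- overlaps ------------------------------------------------------------
  ovPfi <- overlapStats(shapGenes, pfiGenes)
  unionTop <- union(shapGenes, pfiGenes)
  shapRankPos <- match(unionTop, ranking$gene_id)
  pfiRankPos <- match(unionTop, pfi$gene_id)
  ovPfi$spearmanTopUnion <- suppressWarnings(
    cor(shapRankPos, pfiRankPos, method = "spearman"))
  ovDea <- overlapStats(shapGenes, deaGenes)

  # ---- baselines -----------------------------------------------------------
  baselines <- NULL
  if (config@doBaselines) {
    say("ensemble baselines")
    tr1 <- splitSlice(datasets[[1]], "train")
    bl <- trainBaselines(tr1$x, tr1$y, te1$x, te1$y,
                         seed = childSeed(config@replicateSeeds[1], 41L))
    baselines <- list(forest = bl$forest, boosting = bl$boosting)
    addStage("baselines", "first replicate train+test splits")
  }

  # ---- ground-truth recovery ----------------------------------------------
  recovery <- NULL
  if (!is.null(truth) && length(driverIds(truth))) {
    strong <- strongDrivers(truth)
    posDrivers <- driverIds(truth)[driverCoefficients(truth) > 0]
    phi <- shapValues(attrAvg)
    spear <- vapply(posDrivers, function(g)
      suppressWarnings(cor(explainX[, g], phi[, g], method = "spearman")),
      numeric(1))
    recovery <- list(
      n_drivers = length(driverIds(truth)),
      n_strong = length(strong),
      driver_recall_top_fraction =
        mean(driverIds(truth) %in% shapGenes),
      strong_driver_recall_top_fraction = mean(strong %in% shapGenes),
      positive_driver_spearman_mean = mean(spear, na.rm = TRUE),
      positive_driver_spearman_positive_fraction =
        mean(spear > 0, na.rm = TRUE))
  }

  # ---- report --------------------------------------------------------------
  report <- list(
    schema_version = "1.0",
    software = list(package = "glycanShap",
                    version = as.character(packageVersion("glycanShap"))),
    config = .configAsList(config),
    n_cells = ncol(sce), n_genes = nrow(sce),
    n_labeled = nrow(ld@features),
    replicates = replicates,
    attribution = list(
      n_explain = nEx, n_background = config@nBackground,
      base_value = baseValue(attrAvg),
      local_accuracy_max_error = localAccErr,
      top_fraction = config@topFrac,
      n_shap_genes = length(shapGenes),
      shap_genes = shapGenes,
      ranking_head = head(ranking, 20)),
    subtype_specific = if (!is.null(specific))
      list(n_flags = nrow(specific), flags = specific) else NULL,
    pfi = list(n_permutations = config@nPermutations,
               top_genes = pfiGenes, head = head(pfi, 20)),
    dea = list(n_significant = length(deaGenes),
               significant_genes = deaGenes),
    overlaps = list(shap_vs_pfi = ovPfi, shap_vs_dea = ovDea),
    baselines = baselines,
    ground_truth_recovery = recovery,
    stages = stages)

  if (nzchar(config@outputDir)) {
    out <- config@outputDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeLabelsTSV(ld, file.path(out, "labels.tsv"))
    writeRankingTSV(ranking, file.path(out, "shap_ranking.tsv"))
    writeRankingTSV(pfi, file.path(out, "pfi_ranking.tsv"))
    writeRankingTSV(dea, file.path(out, "dea.tsv"))
    if (!is.null(subtypeResult))
      for (nm in names(subtypeResult))
        writeRankingTSV(subtypeResult[[nm]],
                        file.path(out, paste0("shap_ranking_", nm, ".tsv")))
    if (!is.null(specific))
      writeRankingTSV(specific, file.path(out, "subtype_specific.tsv"))
    if (!is.null(truth))
      writeManifestJSON(truth, file.path(out, "ground_truth.json"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
  }
  invisible(report)
}

.configAsList <- function(config) {
  syn <- config@synthetic
  list(
    synthetic = if (is.null(syn)) NULL else list(
      n_cells = syn@nCells, n_genes = syn@nGenes,
      n_subtypes = syn@nSubtypes,
      subtype_proportions = syn@subtypeProportions,
      n_drivers_pos = syn@nDriversPos, n_drivers_neg = syn@nDriversNeg,
      effect_size = syn@effectSize,
      subtype_offset_scale = syn@subtypeOffsetScale,
      noise_sd = syn@noiseSd, mean_library_size = syn@meanLibrarySize,
      dropout_rate = syn@dropoutRate,
      low_abundance_drivers = syn@lowAbundanceDrivers, seed = syn@seed),
    paths = config@paths,
    label_fraction = config@labelFraction,
    split_proportions = config@splitProportions,
    replicate_seeds = config@replicateSeeds,
    n_explain = config@nExplain, n_background = config@nBackground,
    subtype_cap = config@subtypeCap,
    n_permutations = config@nPermutations,
    dea_logfc_threshold = config@deaLogfcThreshold,
    dea_alpha = config@deaAlpha, max_epochs = config@maxEpochs,
    top_frac = config@topFrac)
}

#' Structural validation of a pipeline report
#'
#' Checks a report (or report.json file) against the shipped schema
#' (\code{system.file("schema", "report-schema-1.0.json",
#' package = "glycanShap")}): required top-level fields, replicate metric
#' blocks, and value ranges of the headline metrics.
#'
#' @param report a report list from \code{\link{runPipeline}} or a path to a
#'   report.json
#' @return TRUE invisibly; stops with a message on the first violation
#' @export
validateReport <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  required <- c("schema_version", "software", "config", "replicates",
                "attribution", "pfi", "dea", "overlaps", "stages")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("report is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  .assert(length(report$replicates) >= 1, "no replicate blocks in report")
  for (rep in report$replicates) {
    .assert(all(c("train", "validation", "test") %in%
                  names(rep$metrics)),
            "replicate block lacks train/validation/test metrics")
    for (m in rep$metrics) {
      .assert(m$accuracyHigh >= 0 && m$accuracyHigh <= 1 &&
                m$accuracyLow >= 0 && m$accuracyLow <= 1,
              "accuracies must lie in [0, 1]")
      .assert(m$meanBCE >= 0, "mean BCE must be nonnegative")
    }
  }
  invisible(TRUE)
}
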