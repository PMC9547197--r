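#' Read a Matrix Market triplet (matrix.mtx + features.tsv + barcodes.tsv)
#'
#' Reads the standard 10X-style triplet: a Matrix Market coordinate file
#' with features as rows and cell barcodes as columns, plus line-aligned
#' feature and barcode TSVs. The result is oriented features x cells, as
#' Bioconductor containers expect; round-trips bit-exactly with
#' \code{\link{writeMatrixTriplet}} for integer data.
#'
#' @param dir directory holding \code{matrix.mtx}, \code{features.tsv} and
#'   \code{barcodes.tsv} (override individual paths via \code{matrixPath},
#'   \code{featuresPath}, \code{barcodesPath})
#' @param matrixPath,featuresPath,barcodesPath explicit file paths
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{logcounts} (dense)
#' @export
readMatrixTriplet <- function(dir = NULL,
                              matrixPath = file.path(dir, "matrix.mtx"),
                              featuresPath = file.path(dir, "features.tsv"),
                              barcodesPath = file.path(dir,
                                                       "barcodes.tsv")) {
  for (f in c(matrixPath, featuresPath, barcodesPath))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  m <- as.matrix(Matrix::readMM(matrixPath))
  features <- readLines(featuresPath)
  barcodes <- readLines(barcodesPath)
  if (length(features) != nrow(m))
    stop("features.tsv has ", length(features), " lines but ", matrixPath,
         " has ", nrow(m), " rows", call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop("barcodes.tsv has ", length(barcodes), " lines but ", matrixPath,
         " has ", ncol(m), " columns", call. = FALSE)
  features <- vapply(strsplit(features, "\t"), `[`, character(1), 1L)
  dimnames(m) <- list(features, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = m))
}

#' Write a Matrix Market triplet
#'
#' @param m features x cells matrix (or a SingleCellExperiment, whose
#'   \code{logcounts} assay is written)
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeMatrixTriplet <- function(m, dir) {
  if (is(m, "SingleCellExperiment"))
    m <- SummarizedExperiment::assay(m, "logcounts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write a per-cell lectin count CSV (cell_id, raw_count)
#'
#' @param path CSV path
#' @return \code{readLectinCSV}: a \linkS4class{LectinProfile}
#' @export
readLectinCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("cell_id", "raw_count") %in% names(df)),
          "lectin CSV needs cell_id and raw_count columns")
  new("LectinProfile",
      rawCounts = stats::setNames(as.numeric(df$raw_count), df$cell_id),
      clrValues = numeric())
}

#' @param lectin a \linkS4class{LectinProfile}
#' @rdname readLectinCSV
#' @export
writeLectinCSV <- function(lectin, path) {
  utils::write.csv(
    data.frame(cell_id = names(rawCounts(lectin)),
               raw_count = unname(rawCounts(lectin))),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a per-cell subtype TSV (cell_id, subtype)
#'
#' @param path TSV path
#' @return \code{readSubtypeTSV}: a named factor of subtypes
#' @export
readSubtypeTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("cell_id", "subtype") %in% names(df)),
          "subtype TSV needs cell_id and subtype columns")
  stats::setNames(factor(df$subtype), df$cell_id)
}

#' @param subtypes named factor/character of subtype labels
#' @rdname readSubtypeTSV
#' @export
writeSubtypeTSV <- function(subtypes, path) {
  utils::write.table(
    data.frame(cell_id = names(subtypes),
               subtype = as.character(subtypes)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the labeled-dataset table (cell_id, clr_value, label, split)
#'
#' Excluded mid-quartile cells appear with label "excluded" and no split.
#'
#' @param ld a \linkS4class{LabeledDataset}
#' @param path TSV path
#' @export
writeLabelsTSV <- function(ld, path) {
  df <- data.frame(
    cell_id = c(ld@cellIds, ld@excludedCellIds),
    clr_value = c(ld@clrValues, rep(NA_real_,
                                    length(ld@excludedCellIds))),
    label = c(as.character(ld@labels),
              rep("excluded", length(ld@excludedCellIds))),
    split = c(as.character(ld@split),
              rep("", length(ld@excludedCellIds))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a gene ranking or importance table as TSV
#'
#' @param ranking a data.frame (gene ranking, PFI or DE table)
#' @param path TSV path
#' @export
writeRankingTSV <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param truth a \linkS4class{GroundTruthManifest}
#' @param path JSON path
#' @export
writeManifestJSON <- function(truth, path) {
  jsonlite::write_json(
    list(driver_ids = truth@driverIds,
         driver_coefficients = unname(truth@driverCoefficients),
         subtype_offsets = as.list(truth@subtypeOffsets),
         seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifestJSON
#' @export
readManifestJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.numeric(j$driver_coefficients)
  names(beta) <- as.character(j$driver_ids)
  new("GroundTruthManifest",
      driverIds = as.character(j$driver_ids), driverCoefficients = beta,
      subtypeOffsets = unlist(j$subtype_offsets),
      seed = as.integer(j$seed))
}
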