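# File-format boundaries: NIfTI volumes, CSV tables, JSON documents.

#' Read / write 3D or 4D volumes as NIfTI-1
#'
#' @param x numeric/integer array (3D or 4D).
#' @param path output `.nii.gz` path.
#' @param voxelSize isotropic voxel edge in mm.
#' @return `writeVolumeNIfTI` returns the path invisibly;
#'   `readVolumeNIfTI` returns a plain array.
#' @export
writeVolumeNIfTI <- function(x, path, voxelSize = 0.125) {
  img <- RNifti::asNifti(x, pixdim = rep(voxelSize, min(length(dim(x)), 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write every volume of a metric or count set as NIfTI
#'
#' @param set a [MetricVolumeSet-class] or [CellCountVolumeSet-class].
#' @param dir output directory (created if needed).
#' @param voxelSize voxel edge in mm.
#' @return Invisible named vector of paths.
#' @export
writeVolumeSetNIfTI <- function(set, dir, voxelSize = 0.125) {
  vols <- if (is(set, "MetricVolumeSet")) set@metrics else set@counts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(vols), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    writeVolumeNIfTI(vols[[nm]], p, voxelSize)
    p
  }, character(1))
  invisible(paths)
}

#' Serialize a correlation matrix as CSV and JSON
#'
#' The CSV is the long-format table (region, metric, cell_type, per-subject
#' r, t, p_raw, p_adj, significant); the JSON carries the same rows plus
#' the analysis parameters.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param csvPath,jsonPath output paths (`NULL` to skip either).
#' @return Invisible list of written paths.
#' @export
writeCorrelationMatrix <- function(cm, csvPath = NULL, jsonPath = NULL) {
  tab <- cbind(region = cm@region, cm@table)
  if (!is.null(csvPath))
    utils::write.csv(tab, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(region = cm@region, n_subjects = cm@nSubjects, alpha = cm@alpha,
           factor = cm@factor, pairs = tab),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(csv = csvPath, json = jsonPath))
}

#' Serialize a prediction result as JSON plus a per-block CSV
#'
#' @param pr a [PredictionResult-class].
#' @param jsonPath summary JSON path (`NULL` to skip).
#' @param csvPath per-block (block_id, reference, predicted) CSV path.
#' @param bootstrapCsvPath optional CSV of the bootstrap R/p distribution.
#' @return Invisible list of written paths.
#' @export
writePredictionResult <- function(pr, jsonPath = NULL, csvPath = NULL,
                                  bootstrapCsvPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(cell_type = pr@cellType, region = pr@region,
           n_blocks = length(pr@blockId), R = pr@R, p = pr@p,
           slope = pr@slope, intercept = pr@intercept,
           n_bootstrap = nrow(pr@bootstrap)),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csvPath))
    utils::write.csv(
      data.frame(block_id = pr@blockId, reference = pr@reference,
                 predicted = pr@predicted),
      csvPath, row.names = FALSE)
  if (!is.null(bootstrapCsvPath) && nrow(pr@bootstrap))
    utils::write.csv(pr@bootstrap, bootstrapCsvPath, row.names = FALSE)
  invisible(list(json = jsonPath, csv = csvPath,
                 bootstrap = bootstrapCsvPath))
}

# Provenance sidecar: config hash + seed, no timestamps so reruns are
# byte-identical.
writeProvenance <- function(path, config, seed, stage) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = contentHash(config),
         package_version = as.character(utils::packageVersion("dwicell"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
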