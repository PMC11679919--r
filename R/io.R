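# NIfTI / TSV / JSON export of generated data and results.

.asNiftiWithGeometry <- function(arr, voxelSizeMm, originMm) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (nd == 4L) c(voxelSizeMm, 1) else voxelSizeMm
  # world frame: scaled identity with translation at the stated origin
  aff <- diag(c(voxelSizeMm, 1))
  aff[1:3, 4] <- originMm
  RNifti::qform(img) <- structure(aff, code = 2L)
  img
}

#' Write a parcellation as 3D NIfTI
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param path output path (.nii or .nii.gz; plain .nii recommended for
#'   text-only artifact trees).
#' @return the path, invisibly.
#' @export
writeParcellation <- function(parcellation, path) {
  img <- .asNiftiWithGeometry(labelVolume(parcellation),
                              voxelSize(parcellation), originMm(parcellation))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parcellation from NIfTI
#'
#' @param path NIfTI path.
#' @return a \linkS4class{Parcellation}.
#' @export
readParcellation <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim(img))
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  originMm <- xf[1:3, 4]
  new("Parcellation", labelVolume = arr, voxelSizeMm = pd,
      originMm = as.numeric(originMm),
      regionIds = sort(unique(as.integer(arr[arr > 0]))))
}

#' Write one subject's series as 4D NIfTI
#'
#' @param record a \linkS4class{SubjectRecord}.
#' @param path output path.
#' @param voxelSizeMm,originMm voxel geometry (defaults 3 mm isotropic at 0).
#' @return the path, invisibly.
#' @export
writeSubjectSeries <- function(record, path, voxelSizeMm = c(3, 3, 3),
                               originMm = c(0, 0, 0)) {
  img <- .asNiftiWithGeometry(seriesData(record), voxelSizeMm, originMm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a subject series from NIfTI
#'
#' @param path NIfTI path.
#' @param subjectId,group,age,sex phenotype fields for the record.
#' @param trS repetition time in seconds.
#' @return a \linkS4class{SubjectRecord}.
#' @export
readSubjectSeries <- function(path, subjectId, group = "task", age = 30,
                              sex = "F", trS = 2) {
  img <- RNifti::readNifti(path)
  new("SubjectRecord", subjectId = subjectId, group = group, age = age,
      sex = sex, series = array(as.numeric(img), dim(img)), trS = trS)
}

#' Write a cohort: per-subject NIfTI plus a TSV manifest
#'
#' The manifest has columns subject_id, group, age, sex, path.
#'
#' @param cohort list of \linkS4class{SubjectRecord}.
#' @param dir output directory (created if needed).
#' @param voxelSizeMm,originMm voxel geometry.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, voxelSizeMm = c(3, 3, 3),
                        originMm = c(0, 0, 0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohortManifest(cohort)
  manifest$path <- file.path(dir, paste0(manifest$subject_id, ".nii"))
  for (s in seq_along(cohort))
    writeSubjectSeries(cohort[[s]], manifest$path[s], voxelSizeMm, originMm)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by \code{writeCohort}
#'
#' @param manifestPath path to the manifest TSV.
#' @param trS repetition time in seconds.
#' @return list of \linkS4class{SubjectRecord}.
#' @export
readCohort <- function(manifestPath, trS = 2) {
  manifest <- read.delim(manifestPath)
  lapply(seq_len(nrow(manifest)), function(s)
    readSubjectSeries(manifest$path[s], manifest$subject_id[s],
                      manifest$group[s], manifest$age[s], manifest$sex[s],
                      trS = trS))
}

#' Export an atlas: binary NIfTI mask, provenance TSV, summary JSON
#'
#' @param atlas an \linkS4class{EmotionAtlas}.
#' @param prefix output path prefix; writes \code{<prefix>_mask.nii},
#'   \code{<prefix>_provenance.tsv} and \code{<prefix>_summary.json}.
#' @return the mask path, invisibly.
#' @export
writeAtlasMask <- function(atlas, prefix) {
  p <- atlas@parcellation
  maskPath <- paste0(prefix, "_mask.nii")
  img <- .asNiftiWithGeometry(atlasMask(atlas), voxelSize(p), originMm(p))
  RNifti::writeNifti(img, maskPath)
  prov <- atlasProvenance(atlas)
  write.table(prov, paste0(prefix, "_provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    polarity = atlasPolarity(atlas),
    n_subroi_voxels = sum(prov$origin == "subroi"),
    n_external_voxels = sum(prov$origin == "external"),
    n_regions_touched = nRegionsTouched(atlas)
  ), paste0(prefix, "_summary.json"), auto_unbox = TRUE)
  invisible(maskPath)
}

#' Write ground truth as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    active_region_ids = truth@activeRegionIds,
    active_voxel_fraction = truth@activeVoxelFraction,
    effect_size = truth@effectSize,
    hemodynamic_delay_s = truth@hemodynamicDelayS,
    alff_clusters = lapply(truth@alffClusters, function(cl)
      list(group = cl$group, amplitude = cl$amplitude, freq_hz = cl$freqHz,
           voxels = unname(apply(cl$voxels, 1, as.integer, simplify = FALSE))))
  ), path, auto_unbox = TRUE)
  invisible(path)
}
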