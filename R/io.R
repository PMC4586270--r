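# NIfTI and table I/O.

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the affine and, for 4D data, the
#' repetition time. Voxel indices are 0-based in mm computations; peak
#' coordinates in reports are mm via the affine.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return `readVolume`: list with `data` (array), `affine` (4x4), `pixdim`,
#'   `tr` (seconds, 4D only).
#' @rdname volumeIO
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = as.array(img), affine = RNifti::xform(img), pixdim = pd,
       tr = if (length(dim(img)) >= 4) pd[4] else NA_real_)
}

#' @param data Numeric array (3D or 4D).
#' @param voxelSize Isotropic voxel size in mm.
#' @param tr Repetition time in seconds (4D data).
#' @param affine Optional 4x4 affine; default scales voxel indices by
#'   `voxelSize`.
#' @rdname volumeIO
#' @export
writeVolume <- function(data, path, voxelSize = 3, tr = 2, affine = NULL) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  pd <- c(rep(voxelSize, 3), if (nd >= 4) tr)
  RNifti::pixdim(img) <- pd[seq_len(nd)]
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelSize, 3), 1))
    affine[1, 1] <- -voxelSize   # RAS-ish default with left-right flip
  }
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel index to mm coordinates
#'
#' @param affine 4x4 affine matrix.
#' @param ijk Matrix (or vector) of 1-based voxel indices.
#' @return Matrix of mm coordinates.
#' @export
voxelToMm <- function(affine, ijk) {
  ijk <- rbind(t(matrix(ijk, ncol = 3)) - 1, 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

#' Write an atlas as label volume + region table
#'
#' @param atlas An `atlas`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>_regions.tsv`.
#' @export
writeAtlas <- function(atlas, prefix) {
  writeVolume(atlas$labels * 1, paste0(prefix, ".nii.gz"),
              voxelSize = atlas$voxelSize, tr = NA)
  utils::write.table(atlas$regions, paste0(prefix, "_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write / read a cohort score table
#'
#' @param cohort A `cohort` data frame.
#' @param path TSV path.
#' @rdname cohortIO
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohortIO
#' @export
readCohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("cohort", "data.frame")
  x
}
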