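#' Write a synthetic cohort to NIfTI files with a manifest
#'
#' One gzipped NIfTI volume per phase plus the lesion mask per subject,
#' with the physical voxel size in the header, and a manifest CSV
#' (`subject_id`, `label`, `group`, file paths) tying them together.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    paths <- file.path(dir, sprintf("%s_%s.nii.gz", s$id,
                                    c("ctu", "cta", "ctp", "mask")))
    vs <- s$volume$voxel_size
    write_nifti_volume(s$volume$ctu, paths[1], vs)
    write_nifti_volume(s$volume$cta, paths[2], vs)
    write_nifti_volume(s$volume$ctp, paths[3], vs)
    write_nifti_volume(s$mask$mask * 1, paths[4], vs)
    data.frame(subject_id = s$id, label = as.character(s$label),
               group = s$group, ctu = paths[1], cta = paths[2],
               ctp = paths[3], mask = paths[4])
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

write_nifti_volume <- function(x, path, voxel_size) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
}

#' Read a three-phase study from NIfTI files
#'
#' @param ctu,cta,ctp Paths to the unenhanced, arterial and portal phase
#'   volumes. Voxel size is taken from the unenhanced header.
#' @return A [multiphase_volume()].
#' @export
read_multiphase_nifti <- function(ctu, cta, ctp) {
  u <- RNifti::readNifti(ctu)
  vs <- RNifti::pixdim(u)[1:3]
  multiphase_volume(as.array(u),
                    as.array(RNifti::readNifti(cta)),
                    as.array(RNifti::readNifti(ctp)),
                    voxel_size = vs)
}

#' Read an ROI mask from a NIfTI file
#'
#' Nonzero voxels are marked.
#'
#' @param path Path to the mask volume.
#' @return An [roi_mask()].
#' @export
read_roi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(as.array(img) != 0, voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write an AEF map (values and validity mask) to NIfTI
#'
#' Invalid voxels are written as `NA` in the value volume; the companion
#' validity mask is written alongside with suffix `_valid`.
#'
#' @param aef An [compute_aef_map()] result.
#' @param path Output path for the value volume.
#' @return `path`, invisibly.
#' @export
write_aef_nifti <- function(aef, path) {
  stopifnot(inherits(aef, "aef_map"))
  write_nifti_volume(aef$values, path, aef$voxel_size)
  valid_path <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  if (valid_path == path) valid_path <- paste0(path, "_valid.nii.gz")
  write_nifti_volume(aef$valid * 1, valid_path, aef$voxel_size)
  invisible(path)
}
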