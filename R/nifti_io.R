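# NIfTI persistence of patient cases. Volumes are written with an affine
# built from the voxel spacing; masks round-trip bit-identically (stored as
# uint8), signal volumes within float tolerance.

case_volume_names <- function() {
  c("dwi_b0", "dwi_bhigh", "pwi", "brain_mask", "csf_mask",
    "ipsilateral_mask", "contralateral_mask", "contralateral_voi_mask",
    "core_truth", "penumbra_truth", "followup_lesion",
    "adc_truth", "atlas_tissue_prob", "atlas_region_id")
}

case_mask_names <- function() {
  c("brain_mask", "csf_mask", "ipsilateral_mask", "contralateral_mask",
    "contralateral_voi_mask", "core_truth", "penumbra_truth",
    "followup_lesion")
}

#' Write a patient case to a directory as NIfTI + CSV
#'
#' Each 3D/4D volume becomes `<name>.nii.gz` with the voxel spacing encoded
#' in the header; masks are stored as uint8. Covariates and the cohort label
#' go into a one-row `case.csv`, the simulated arterial input function into
#' `aif.csv`.
#'
#' @param case a `patient_case`.
#' @param directory existing, writable directory; the case is written into
#'   `directory/<id>/`.
#' @return invisibly, the vector of files written.
#' @export
write_case <- function(case, directory) {
  if (!dir.exists(directory))
    stop("directory does not exist: ", directory)
  dest <- file.path(directory, case$id)
  dir.create(dest, showWarnings = FALSE)
  files <- character(0)
  for (nm in case_volume_names()) {
    vol <- case[[nm]]
    if (is.null(vol)) next
    if (is.logical(vol)) storage.mode(vol) <- "integer"
    nd <- length(dim(vol))
    pd <- if (nd == 4) c(case$spacing_mm, case$TR_s) else case$spacing_mm
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- pd
    if (nm %in% case_mask_names())
      img <- RNifti::asNifti(img, datatype = "uint8")
    f <- file.path(dest, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  cov <- data.frame(id = case$id, cohort = case$cohort,
                    nihss = case$covariates$nihss, age = case$covariates$age,
                    sex = case$covariates$sex,
                    onset_to_imaging_min = case$covariates$onset_to_imaging,
                    seed = case$seed,
                    TR_s = case$TR_s, TE_s = case$TE_s,
                    b_high = max(case$b_values),
                    spacing_x = case$spacing_mm[1], spacing_y = case$spacing_mm[2],
                    spacing_z = case$spacing_mm[3])
  write.csv(cov, file.path(dest, "case.csv"), row.names = FALSE)
  aif <- data.frame(t = (seq_along(case$true_aif$values) - 1) * case$true_aif$dt,
                    value = case$true_aif$values)
  write.csv(aif, file.path(dest, "aif.csv"), row.names = FALSE)
  invisible(c(files, file.path(dest, c("case.csv", "aif.csv"))))
}

#' Read a patient case back from disk
#'
#' @param directory the per-case directory written by [write_case()].
#' @return a `patient_case`.
#' @export
read_case <- function(directory) {
  if (!dir.exists(directory)) stop("directory does not exist: ", directory)
  cov <- read.csv(file.path(directory, "case.csv"), stringsAsFactors = FALSE)
  case <- list(id = cov$id, cohort = cov$cohort, seed = cov$seed)
  for (nm in case_volume_names()) {
    f <- file.path(directory, paste0(nm, ".nii.gz"))
    if (!file.exists(f)) next
    vol <- as.array(RNifti::readNifti(f))
    if (nm %in% case_mask_names()) vol <- array(vol > 0.5, dim = dim(vol))
    if (nm == "atlas_region_id") storage.mode(vol) <- "integer"
    case[[nm]] <- vol
  }
  aif <- read.csv(file.path(directory, "aif.csv"))
  dt <- if (nrow(aif) > 1) aif$t[2] - aif$t[1] else 1
  case$true_aif <- list(values = aif$value, dt = dt, t0 = aif$t[1])
  case$covariates <- list(nihss = cov$nihss, age = cov$age, sex = cov$sex,
                          onset_to_imaging = cov$onset_to_imaging_min)
  case$spacing_mm <- c(cov$spacing_x, cov$spacing_y, cov$spacing_z)
  case$TR_s <- cov$TR_s
  case$TE_s <- cov$TE_s
  case$b_values <- c(0, cov$b_high)
  structure(case, class = "patient_case")
}
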