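# Per-voxel feature assembly: the 12-feature vectors (8 imaging/derived +
# 4 repeated clinical covariates), contralateral reference statistics, the
# two normalization variants, and stratified class balancing.

feature_columns <- function() {
  c("adc", "distance", "tissue_prob", "region_id", "cbv", "mtt", "tmax",
    "cbf", "nihss", "age", "sex", "onset_min")
}

ratio_normalized <- function() c("adc", "cbf", "cbv")
subtract_normalized <- function() c("mtt", "tmax")

#' Assemble the per-voxel feature table for one patient
#'
#' One row per voxel of the ipsilateral analysis mask (brain minus CSF):
#' ADC, distance to the ischemic core, white-matter probability, anatomical
#' region label, CBV, MTT, Tmax, CBF, and the four patient-level covariates
#' (NIHSS, age, sex, onset-to-imaging minutes) repeated per voxel. The label
#' is the CSF-excluded follow-up lesion. Voxels whose MTT is undefined
#' (CBF = 0) are dropped with a message.
#'
#' @param case a `patient_case`.
#' @param adc ADC map.
#' @param dist distance-to-core map.
#' @param atlas list from [sample_atlas()].
#' @param perf perfusion map list from [compute_perfusion_maps()].
#' @param csf_mask CSF mask used to restrict the analysis domain.
#' @param domain `"ipsilateral"` (study default) or `"brain"` (ablation).
#' @return data.frame with provenance (`patient_id`, `voxel_index`), the 12
#'   feature columns and `label`; attributes `normalization = "ABS"`,
#'   `balanced = "full"`.
#' @export
assemble_features <- function(case, adc, dist, atlas, perf,
                              csf_mask = case$csf_mask,
                              domain = c("ipsilateral", "brain")) {
  domain <- match.arg(domain)
  base <- if (domain == "ipsilateral") case$ipsilateral_mask else case$brain_mask
  mask <- base & !csf_mask
  if (!any(mask)) stop("empty analysis mask")
  idx <- which(mask)
  truth <- exclude_csf_from_truth(case$followup_lesion, csf_mask)
  tab <- data.frame(
    patient_id = case$id,
    voxel_index = idx,
    adc = adc[idx],
    distance = dist[idx],
    tissue_prob = atlas$tissue_prob[idx],
    region_id = factor(atlas$region_id[idx], levels = 1:9),
    cbv = perf$cbv[idx],
    mtt = perf$mtt[idx],
    tmax = perf$tmax[idx],
    cbf = perf$cbf[idx],
    nihss = case$covariates$nihss,
    age = case$covariates$age,
    sex = case$covariates$sex,
    onset_min = case$covariates$onset_to_imaging,
    label = as.integer(truth[idx]),
    stringsAsFactors = FALSE
  )
  drop <- !is.finite(tab$mtt)
  if (any(drop)) {
    message(sprintf("dropping %d voxel(s) with undefined MTT", sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }
  attr(tab, "normalization") <- "ABS"
  attr(tab, "balanced") <- "full"
  tab
}

#' Contralateral reference statistics for normalization
#'
#' Means of the five imaging parameters (ADC, CBF, CBV, MTT, Tmax) over the
#' CSF-excluded contralateral hemisphere (`"hemisphere"` mode) or over the
#' mirrored-lesion reference VOI (`"voi"` mode).
#'
#' @param case a `patient_case`.
#' @param adc ADC map.
#' @param perf perfusion maps.
#' @param mode `"hemisphere"` or `"voi"`.
#' @param csf_mask CSF mask to exclude.
#' @return list of class `reference_stats` with the five means and `mode`.
#' @export
compute_reference_stats <- function(case, adc, perf,
                                    mode = c("hemisphere", "voi"),
                                    csf_mask = case$csf_mask) {
  mode <- match.arg(mode)
  region <- if (mode == "hemisphere") case$contralateral_mask & !csf_mask
            else case$contralateral_voi_mask & !csf_mask
  if (!any(region)) stop("empty contralateral reference region (mode ", mode, ")")
  idx <- which(region)
  vals <- list(adc = adc[idx], cbf = perf$cbf[idx], cbv = perf$cbv[idx],
               mtt = perf$mtt[idx], tmax = perf$tmax[idx])
  means <- lapply(vals, function(v) mean(v[is.finite(v)]))
  for (p in ratio_normalized())
    if (!is.finite(means[[p]]) || means[[p]] == 0)
      stop("reference mean of ", p, " is zero or undefined; cannot form ratios")
  structure(c(setNames(means, paste0("mean_", names(means))),
              list(mode = mode)), class = "reference_stats")
}

#' Apply contralateral normalization to a feature table
#'
#' ADC, CBF and CBV become ratios to the contralateral mean; the temporal
#' parameters MTT and Tmax have the contralateral mean subtracted. All other
#' columns are untouched.
#'
#' @param table feature table from [assemble_features()].
#' @param refs [compute_reference_stats()] result for the same patient.
#' @return the normalized table, with attribute `normalization` set to
#'   `"RC"` (hemisphere) or `"RVO"` (VOI).
#' @export
normalize_features <- function(table, refs) {
  for (p in ratio_normalized()) table[[p]] <- table[[p]] / refs[[paste0("mean_", p)]]
  for (p in subtract_normalized()) table[[p]] <- table[[p]] - refs[[paste0("mean_", p)]]
  attr(table, "normalization") <- if (refs$mode == "hemisphere") "RC" else "RVO"
  table
}

#' Balance a training table by stratified undersampling
#'
#' `"full"` returns the table unchanged. `"stratified"` keeps, per patient,
#' all lesion (label 1) voxels and a seeded uniform random sample (without
#' replacement) of exactly as many non-lesion voxels. If a patient has fewer
#' non-lesion than lesion voxels, all non-lesion rows are kept with a
#' warning.
#'
#' @param table feature table (possibly several patients).
#' @param mode `"full"` or `"stratified"`.
#' @param seed RNG seed for the subsample.
#' @return the balanced table, attribute `balanced` set accordingly.
#' @export
balance_training_set <- function(table, mode = c("full", "stratified"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "full") {
    attr(table, "balanced") <- "full"
    return(table)
  }
  keep <- logical(nrow(table))
  with_seed(seed, {
    for (pid in unique(table$patient_id)) {
      rows <- which(table$patient_id == pid)
      lab <- table$label[rows]
      n1 <- sum(lab == 1)
      if (n1 == 0)
        stop("patient ", pid, " has no lesion voxels; violates study inclusion")
      zeros <- rows[lab == 0]
      keep[rows[lab == 1]] <- TRUE
      if (length(zeros) <= n1) {
        warning("patient ", pid, ": non-lesion pool smaller than lesion; keeping all")
        keep[zeros] <- TRUE
      } else {
        keep[sample(zeros, n1)] <- TRUE
      }
    }
  })
  out <- table[keep, , drop = FALSE]
  attr(out, "normalization") <- attr(table, "normalization")
  attr(out, "balanced") <- "stratified"
  out
}
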