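# Diffusion-side features: ADC map, brain/CSF segmentation, semi-automatic
# ischemic core segmentation by region growing, Euclidean distance-to-core
# map, and surrogate atlas lookup.

#' Compute the apparent diffusion coefficient map
#'
#' `ADC = ln(S_b0 / S_bhigh) / b` per voxel, in mm2/s. Voxels outside
#' `brain_mask` are set to `NA`.
#'
#' @param b0,bhigh 3D signal volumes without / with diffusion weighting.
#' @param b diffusion weighting difference in s/mm2 (> 0).
#' @param brain_mask logical 3D array; defaults to all voxels.
#' @return 3D array of ADC values (mm2/s), `NA` outside the mask.
#' @export
compute_adc <- function(b0, bhigh, b = 1000, brain_mask = NULL) {
  stopifnot_mask(b0); stopifnot_mask(bhigh)
  check_same_grid(b0, bhigh, "DWI volumes")
  if (b <= 0) stop("b-value difference must be positive")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(b0))
  check_same_grid(b0, brain_mask, "DWI and mask")
  bad <- sum(brain_mask & (b0 <= 0 | bhigh <= 0))
  if (bad > 0)
    stop(sprintf("nonpositive DWI signal inside the brain mask at %d voxel(s)", bad))
  adc <- array(NA_real_, dim(b0))
  adc[brain_mask] <- log(b0[brain_mask] / bhigh[brain_mask]) / b
  adc
}

#' Threshold-based brain/CSF segmentation on the ADC map
#'
#' CSF is segmented as brain voxels whose ADC exceeds a free-water cutoff;
#' the analysis mask is brain tissue minus CSF.
#'
#' @param adc ADC map (mm2/s), `NA` outside the brain.
#' @param brain_mask logical 3D array.
#' @param csf_threshold ADC cutoff in mm2/s (default 2000e-6, a typical
#'   free-water value).
#' @return list with `csf_mask` and `analysis_mask` (brain minus CSF).
#' @export
segment_brain_csf <- function(adc, brain_mask, csf_threshold = 2000e-6) {
  stopifnot_mask(adc)
  check_same_grid(adc, brain_mask)
  csf <- brain_mask & !is.na(adc) & (adc > csf_threshold)
  list(csf_mask = csf, analysis_mask = brain_mask & !csf)
}

#' Semi-automatic ischemic core segmentation by ADC region growing
#'
#' From each seed, grows the 6-connected component of voxels with
#' `ADC < upper_threshold` (within the analysis mask). Seeds at or above the
#' threshold contribute nothing (with a warning). An optional exclusion mask
#' stands in for manual correction of region-growing leakage.
#'
#' @param adc ADC map (mm2/s).
#' @param seeds matrix (n x 3) of 1-based voxel indices, or a list of index
#'   triples.
#' @param upper_threshold upper ADC bound, default 550e-6 mm2/s.
#' @param analysis_mask logical mask the core must lie in.
#' @param exclude optional logical mask of voxels to remove before growing.
#' @return logical 3D core mask.
#' @export
region_growing_core <- function(adc, seeds, upper_threshold = 550e-6,
                                analysis_mask = NULL, exclude = NULL) {
  stopifnot_mask(adc)
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  g <- dim(adc)
  if (is.null(analysis_mask)) analysis_mask <- !is.na(adc)
  accept <- analysis_mask & !is.na(adc) & (adc < upper_threshold)
  if (!is.null(exclude)) accept <- accept & !exclude
  inb <- seeds[, 1] >= 1 & seeds[, 1] <= g[1] &
         seeds[, 2] >= 1 & seeds[, 2] <= g[2] &
         seeds[, 3] >= 1 & seeds[, 3] <= g[3]
  lin <- (seeds[, 1] - 1L) + g[1] * (seeds[, 2] - 1L) + g[1] * g[2] * (seeds[, 3] - 1L)
  ok <- inb
  ok[inb] <- accept[lin[inb] + 1L]
  if (any(!ok))
    warning(sprintf("%d seed(s) at/above the ADC threshold or outside the mask ignored",
                    sum(!ok)))
  if (!any(ok)) {
    warning("no valid seeds: returning an empty core mask")
    return(array(FALSE, g))
  }
  out <- cpp_flood_fill6(as.logical(accept), g, as.integer(lin[ok]))
  array(out, g)
}

#' Exact Euclidean distance to the ischemic core
#'
#' Distance from every voxel center to the nearest core voxel center, either
#' in voxel units (spacing ignored) or in millimetres (anisotropic-aware).
#'
#' @param core logical 3D core mask (non-empty).
#' @param spacing_mm voxel spacing, used only in `"mm"` mode.
#' @param units `"voxel"` (default, matching the study's distance feature)
#'   or `"mm"`.
#' @return 3D array of distances, 0 on core voxels.
#' @export
distance_map <- function(core, spacing_mm = c(1, 1, 1),
                         units = c("voxel", "mm")) {
  units <- match.arg(units)
  stopifnot_mask(core)
  if (!any(core))
    stop("empty core mask: the distance feature requires an acute lesion")
  sp <- if (units == "mm") spacing_mm else c(1, 1, 1)
  d2 <- cpp_edt_squared(as.logical(core), dim(core), as.numeric(sp))
  array(sqrt(d2), dim(core))
}

#' Look up surrogate atlas features for a case
#'
#' Returns the per-voxel white-matter probability and the anatomical region
#' label (1..9) generated on the case's own grid, so no registration or
#' interpolation is involved.
#'
#' @param case a `patient_case`.
#' @return list with `tissue_prob` and `region_id` 3D arrays.
#' @export
sample_atlas <- function(case) {
  if (is.null(case$atlas_tissue_prob) || is.null(case$atlas_region_id))
    stop("case is missing surrogate atlas volumes")
  list(tissue_prob = case$atlas_tissue_prob, region_id = case$atlas_region_id)
}
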