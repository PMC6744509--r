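# Segmentation evaluation: Dice, confusion-matrix metrics, surface
# distances, volume difference; the LOO-calibrated evaluation driver; and
# the single-parameter thresholding baseline.

#' Remove acute CSF from the follow-up lesion ground truth
#'
#' Corrects for CSF redistribution due to swelling: voxels segmented as CSF
#' on the acute ADC are excluded from the follow-up lesion.
#'
#' @param lesion follow-up lesion mask.
#' @param csf acute CSF mask.
#' @return `lesion & !csf`; warns if the truth becomes empty.
#' @export
exclude_csf_from_truth <- function(lesion, csf) {
  check_same_grid(lesion, csf)
  out <- lesion & !csf
  if (any(lesion) && !any(out))
    warning("follow-up lesion lies entirely within CSF; empty ground truth")
  out
}

#' Dice similarity coefficient of two masks
#'
#' `D = 2|A n B| / (|A| + |B|)`. Both masks empty gives 1 (perfect
#' agreement on absence); one empty gives 0.
#'
#' @param A,B logical masks on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(A, B) {
  check_same_grid(A, B)
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Voxel confusion-matrix metrics inside an evaluation mask
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient, counting TP/FP/TN/FN only inside `eval_mask` (the
#' ipsilateral analysis mask in the study design). MCC is 0 when any
#' marginal factor is 0.
#'
#' @param pred,truth logical masks.
#' @param eval_mask logical evaluation domain.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `mcc`, and
#'   the raw counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred, truth, eval_mask) {
  check_same_grid(pred, truth)
  check_same_grid(pred, eval_mask)
  if (!any(eval_mask)) stop("empty evaluation mask")
  p <- pred[eval_mask]; t <- truth[eval_mask]
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + fp + tn + fn)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Mean surface distance and Hausdorff distance between two masks
#'
#' Surfaces are border voxels (mask voxels with a 6-neighbor outside).
#' Directed distances are exact Euclidean distances between surface voxel
#' centers; MSD averages the two directed mean distances, HD takes the
#' maximum of the two directed maxima. Either mask empty yields `NA`
#' sentinels (to be excluded from aggregation, never counted as zero).
#'
#' @param A,B logical masks.
#' @param spacing_mm voxel spacing.
#' @return list with `msd_mm` and `hd_mm`.
#' @export
surface_distances <- function(A, B, spacing_mm = c(1, 1, 1)) {
  check_same_grid(A, B)
  if (!any(A) || !any(B))
    return(list(msd_mm = NA_real_, hd_mm = NA_real_))
  g <- dim(A)
  sa <- cpp_surface_voxels(as.logical(A), g)
  sb <- cpp_surface_voxels(as.logical(B), g)
  da <- sqrt(cpp_edt_squared(sb, g, as.numeric(spacing_mm)))[as.logical(sa)]
  db <- sqrt(cpp_edt_squared(sa, g, as.numeric(spacing_mm)))[as.logical(sb)]
  list(msd_mm = mean(c(mean(da), mean(db))), hd_mm = max(max(da), max(db)))
}

#' Signed predicted-minus-true volume difference in mL
#'
#' @param pred,truth logical masks.
#' @param spacing_mm voxel spacing.
#' @return volume difference in mL (positive = over-prediction).
#' @export
volume_difference <- function(pred, truth, spacing_mm = c(1, 1, 1)) {
  check_same_grid(pred, truth)
  (sum(pred) - sum(truth)) * voxel_volume_ml(spacing_mm)
}

evaluate_one <- function(pred, truth, eval_mask, spacing_mm) {
  cm <- confusion_metrics(pred, truth, eval_mask)
  sdist <- surface_distances(pred, truth, spacing_mm)
  data.frame(dice = dice(pred, truth),
             sensitivity = cm$sensitivity, specificity = cm$specificity,
             accuracy = cm$accuracy, mcc = cm$mcc,
             msd_mm = sdist$msd_mm, hd_mm = sdist$hd_mm,
             volume_diff_ml = volume_difference(pred, truth, spacing_mm))
}

#' Evaluate a LOO prediction store with per-fold threshold calibration
#'
#' For every (patient, setting): the Dice-optimal threshold is selected on
#' the likelihood maps of all *other* patients of the same cohort and
#' setting (each binarized, post-processed and compared with its own
#' truth over the 101-point grid), then applied to the held-out patient's
#' map, post-processed and scored. Per-patient Dice-vs-threshold curves are
#' computed once per setting and reused across folds.
#'
#' @param store prediction store from [run_loo()].
#' @param pre matching list of preprocessed cases.
#' @param thresholds threshold grid (default 101 values, step 0.01).
#' @param min_component post-processing component filter.
#' @return data.frame: one row per (patient, setting) with the selected
#'   threshold and all metrics.
#' @export
evaluate_predictions <- function(store, pre, thresholds = seq(0, 1, by = 0.01),
                                 min_component = 10L) {
  pre_by_id <- setNames(pre, vapply(pre, function(p) p$case$id, character(1)))
  recs <- store
  keys <- vapply(recs, function(r) paste(r$setting_id, r$cohort), character(1))
  results <- list()
  for (grp in unique(keys)) {
    members <- recs[keys == grp]
    ids <- vapply(members, `[[`, character(1), "patient_id")
    curves <- lapply(members, function(r)
      dice_curve(r$map, pre_by_id[[r$patient_id]]$truth, thresholds,
                 min_component))
    cm <- do.call(cbind, curves)
    for (i in seq_along(members)) {
      r <- members[[i]]
      curve <- data.frame(threshold = thresholds,
                          mean_dice = rowMeans(cm[, -i, drop = FALSE]))
      class(curve) <- c("threshold_curve", class(curve))
      tau <- select_threshold(curve)
      p <- pre_by_id[[r$patient_id]]
      pred <- binarize_prediction(r$map, tau, min_component)
      row <- evaluate_one(pred, p$truth, p$eval_mask, p$case$spacing_mm)
      results[[length(results) + 1L]] <- cbind(
        data.frame(patient_id = r$patient_id, cohort = r$cohort,
                   classifier = r$classifier, normalization = r$normalization,
                   balancing = r$balancing, setting_id = r$setting_id,
                   threshold_used = tau),
        row)
    }
  }
  do.call(rbind, results)
}

# Direction in which a parameter marks infarction: low ADC/CBF/CBV,
# high MTT/Tmax.
param_direction <- function(param) {
  if (param %in% c("adc", "cbf", "cbv")) "le" else "ge"
}

single_param_map <- function(p, param, normalization) {
  m <- if (param == "adc") p$adc else p$perf[[param]]
  if (normalization != "ABS") {
    refs <- p$refs[[normalization]]
    mu <- refs[[paste0("mean_", param)]]
    if (param %in% ratio_normalized()) m <- m / mu else m <- m - mu
  }
  out <- array(NA_real_, dim(m))
  out[p$eval_mask] <- m[p$eval_mask]
  out
}

# Dice-vs-threshold curve of a physical parameter map for a given grid and
# direction ("le": predict infarct where value <= tau; "ge": >= tau).
param_dice_curve <- function(map, truth, grid, direction, min_component = 10L) {
  vapply(grid, function(tau) {
    pred <- if (direction == "le") !is.na(map) & map <= tau
            else !is.na(map) & map >= tau
    dice(postprocess_mask(pred, min_component), truth)
  }, numeric(1))
}

#' Single-parameter thresholding baseline
#'
#' Mirrors the classifier calibration for each imaging parameter (ADC, CBF,
#' CBV, MTT, Tmax) and normalization variant: per held-out patient, a
#' threshold grid of 101 evenly spaced quantiles of the pooled calibration
#' patients' map values is swept (direction fixed by physiology: infarct
#' where ADC/CBF/CBV are low, MTT/Tmax high), each binarization is
#' post-processed and Dice-scored against the calibration truths, and the
#' best threshold is applied to the held-out patient.
#'
#' @param pre list of preprocessed cases (one cohort or several; calibration
#'   is restricted to the same cohort).
#' @param params parameters to sweep, default all five.
#' @param normalizations subset of `c("ABS", "RC", "RVO")`.
#' @param min_component post-processing component filter.
#' @return data.frame: one row per (patient, parameter, normalization).
#' @export
single_param_baseline <- function(pre,
                                  params = c("adc", "cbf", "cbv", "mtt", "tmax"),
                                  normalizations = "ABS",
                                  min_component = 10L) {
  cohorts <- vapply(pre, function(p) p$case$cohort, character(1))
  results <- list()
  for (cohort in unique(cohorts)) {
    members <- pre[cohorts == cohort]
    for (param in params) {
      direction <- param_direction(param)
      for (norm in normalizations) {
        maps <- lapply(members, single_param_map, param = param,
                       normalization = norm)
        for (i in seq_along(members)) {
          calib <- members[-i]
          cmaps <- maps[-i]
          vals <- unlist(lapply(cmaps, function(m) m[!is.na(m) & is.finite(m)]))
          if (length(unique(vals)) < 2) {
            warning("degenerate (constant) ", param, " map; skipping fold")
            next
          }
          grid <- unique(quantile(vals, probs = seq(0, 1, length.out = 101),
                                  names = FALSE, type = 7))
          curves <- mapply(function(m, tr) param_dice_curve(m, tr, grid,
                                                            direction,
                                                            min_component),
                           cmaps, lapply(calib, `[[`, "truth"))
          mean_curve <- rowMeans(matrix(curves, nrow = length(grid)))
          tau <- grid[which.max(mean_curve)]
          p <- members[[i]]
          pred <- if (direction == "le") !is.na(maps[[i]]) & maps[[i]] <= tau
                  else !is.na(maps[[i]]) & maps[[i]] >= tau
          pred <- postprocess_mask(pred, min_component)
          row <- evaluate_one(pred, p$truth, p$eval_mask, p$case$spacing_mm)
          results[[length(results) + 1L]] <- cbind(
            data.frame(patient_id = p$case$id, cohort = cohort,
                       parameter = param, normalization = norm,
                       threshold_used = tau),
            row)
        }
      }
    }
  }
  do.call(rbind, results)
}

#' Summarize evaluation results into the cohort x setting Dice grid
#'
#' Pure aggregation of a results table: mean and SD of Dice per cohort x
#' classifier x normalization x balancing cell, with the best cell flagged
#' per cohort. Never recomputes predictions.
#'
#' @param results data.frame from [evaluate_predictions()].
#' @return data.frame with `mean_dice`, `sd_dice`, `n` and `best` flag.
#' @export
summarize_results <- function(results) {
  if (is.null(results) || nrow(results) == 0) stop("empty results table")
  agg <- aggregate(dice ~ cohort + classifier + normalization + balancing,
                   data = results,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(agg[, 1:4],
                    mean_dice = agg$dice[, "mean"],
                    sd_dice = agg$dice[, "sd"],
                    n = agg$dice[, "n"])
  out$best <- FALSE
  for (cohort in unique(out$cohort)) {
    rows <- which(out$cohort == cohort)
    out$best[rows[which.max(out$mean_dice[rows])]] <- TRUE
  }
  out[order(out$cohort, out$classifier, out$normalization, out$balancing), ]
}
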