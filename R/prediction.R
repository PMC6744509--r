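# Classifier training (random decision forest, logistic GLM, kNN), voxel
# likelihood prediction, and the leave-one-patient-out driver over the
# 3 classifiers x 3 normalizations x 2 balancings setting grid, with
# separate models per treatment cohort.

#' Enumerate classifier settings
#'
#' The full cross-product is 3 classifiers x 3 normalizations x
#' 2 balancing strategies = 18 settings.
#'
#' @param classifiers subset of `c("RDF", "GLM", "KNN")`.
#' @param normalizations subset of `c("ABS", "RC", "RVO")` (absolute,
#'   relative to contralateral hemisphere, relative to contralateral VOI).
#' @param balancings subset of `c("full", "stratified")`.
#' @return data.frame with one row per setting and a `setting_id`.
#' @export
classifier_settings <- function(classifiers = c("RDF", "GLM", "KNN"),
                                normalizations = c("ABS", "RC", "RVO"),
                                balancings = c("full", "stratified")) {
  s <- expand.grid(classifier = classifiers, normalization = normalizations,
                   balancing = balancings, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  s$setting_id <- paste(s$classifier, s$normalization, s$balancing, sep = "_")
  s
}

default_hyperparameters <- function() {
  # Conventional baselines; the study's exact classifier settings live in
  # supplementary material, so these are deliberately configurable.
  list(num_trees = 100L,   # RDF ensemble size
       mtry = NULL,        # RDF features per split; NULL = floor(sqrt(p))
       knn_k = 11L,        # neighbors, standardized Euclidean metric
       glm_maxit = 50L)
}

# One-hot design matrix for GLM/kNN (region label has no ordinal meaning).
feature_design_matrix <- function(table) {
  num_cols <- setdiff(feature_columns(), "region_id")
  X <- as.matrix(table[, num_cols, drop = FALSE])
  reg <- vapply(levels(table$region_id),
                function(l) as.numeric(table$region_id == l),
                numeric(nrow(table)))
  colnames(reg) <- paste0("region_", levels(table$region_id))
  cbind(X, reg)
}

#' Train a voxel-outcome classifier
#'
#' RDF: probability forest (likelihood = mean tree class-1 probability),
#' region label used as a native categorical split variable. GLM: binomial
#' logistic regression on one-hot features. kNN: likelihood = fraction of
#' the k nearest neighbors (z-score standardized Euclidean metric, one-hot
#' region) that infarcted; the "model" stores the standardized training set.
#'
#' @param classifier `"RDF"`, `"GLM"` or `"KNN"`.
#' @param training feature table with both classes present.
#' @param hyper list, see `default_hyperparameters()`.
#' @param seed RNG seed (forest construction).
#' @return object of class `vf_model`.
#' @export
train_classifier <- function(classifier, training,
                             hyper = default_hyperparameters(), seed = 1L) {
  if (length(unique(training$label)) < 2)
    stop("training data contains a single class")
  num_cols <- setdiff(feature_columns(), "region_id")
  if (!all(vapply(training[num_cols], function(x) all(is.finite(x)), logical(1))))
    stop("non-finite feature values in training data")
  hyper <- utils::modifyList(default_hyperparameters(), hyper)
  model <- list(classifier = classifier, hyper = hyper)
  if (classifier == "RDF") {
    dat <- training[, c(feature_columns(), "label")]
    dat$label <- factor(dat$label, levels = c(0, 1))
    p <- length(feature_columns())
    model$fit <- ranger::ranger(
      label ~ ., data = dat, probability = TRUE,
      num.trees = hyper$num_trees,
      mtry = if (is.null(hyper$mtry)) floor(sqrt(p)) else hyper$mtry,
      respect.unordered.factors = "partition",
      seed = seed, num.threads = 1, verbose = FALSE)
  } else if (classifier == "GLM") {
    X <- feature_design_matrix(training)
    df <- data.frame(label = training$label, X, check.names = FALSE)
    model$fit <- suppressWarnings(
      glm(label ~ ., data = df, family = binomial(),
          control = list(maxit = hyper$glm_maxit)))
    model$design_cols <- colnames(X)
  } else if (classifier == "KNN") {
    X <- feature_design_matrix(training)
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
    model$train_x <- scale(X, center = mu, scale = sdev)
    model$mu <- mu
    model$sdev <- sdev
    model$train_y <- factor(training$label, levels = c(0, 1))
  } else stop("unknown classifier: ", classifier)
  class(model) <- "vf_model"
  model
}

#' Predict per-voxel infarct likelihood
#'
#' @param model a `vf_model` from [train_classifier()].
#' @param newdata feature table with the training schema (same normalization
#'   mode).
#' @return numeric vector of likelihoods in `[0, 1]`, one per row.
#' @export
predict_likelihood <- function(model, newdata) {
  missing <- setdiff(feature_columns(), names(newdata))
  if (length(missing))
    stop("newdata is missing feature column(s): ", paste(missing, collapse = ", "))
  if (model$classifier == "RDF") {
    pr <- predict(model$fit, data = newdata[, feature_columns()],
                  num.threads = 1, verbose = FALSE)$predictions
    lik <- pr[, "1"]
  } else if (model$classifier == "GLM") {
    X <- feature_design_matrix(newdata)
    df <- data.frame(X[, model$design_cols, drop = FALSE], check.names = FALSE)
    lik <- suppressWarnings(predict(model$fit, newdata = df, type = "response"))
  } else {
    X <- feature_design_matrix(newdata)
    Xs <- scale(X, center = model$mu, scale = model$sdev)
    cl <- class::knn(model$train_x, Xs, model$train_y,
                     k = model$hyper$knn_k, prob = TRUE, use.all = TRUE)
    win <- attr(cl, "prob")
    lik <- ifelse(cl == "1", win, 1 - win)
  }
  pmin(pmax(as.numeric(lik), 0), 1)
}

# Scatter per-row likelihoods back onto the voxel grid (NA off-mask).
likelihood_map <- function(values, voxel_index, dim) {
  m <- array(NA_real_, dim)
  m[voxel_index] <- values
  m
}

#' Preprocess one patient: features for every normalization variant
#'
#' Runs the full feature chain (ADC, CSF segmentation, region-growing core
#' from the core centroid seed, distance map, atlas lookup, perfusion maps)
#' and assembles the ABS, RC and RVO feature tables plus the CSF-excluded
#' ground truth and evaluation mask.
#'
#' @param case a `patient_case`.
#' @param truncation bSVD truncation fraction.
#' @param csf_threshold CSF ADC cutoff, mm2/s.
#' @param adc_core_threshold region-growing upper ADC bound, mm2/s.
#' @return list with the intermediate maps, `tables` (named ABS/RC/RVO),
#'   `truth`, `eval_mask`.
#' @export
preprocess_case <- function(case, truncation = 0.15,
                            csf_threshold = 2000e-6,
                            adc_core_threshold = 550e-6) {
  adc <- compute_adc(case$dwi_b0, case$dwi_bhigh, b = max(case$b_values),
                     brain_mask = case$brain_mask)
  seg <- segment_brain_csf(adc, case$brain_mask, csf_threshold)
  seed_vox <- round(colMeans(which(case$core_truth, arr.ind = TRUE)))
  core <- region_growing_core(adc, matrix(seed_vox, ncol = 3),
                              upper_threshold = adc_core_threshold,
                              analysis_mask = seg$analysis_mask)
  if (!any(core)) core <- case$core_truth  # degenerate segmentation fallback
  dist <- distance_map(core, case$spacing_mm, units = "voxel")
  atlas <- sample_atlas(case)
  perf <- compute_perfusion_maps(case, truncation = truncation)
  tab <- assemble_features(case, adc, dist, atlas, perf, csf_mask = seg$csf_mask)
  refs_h <- compute_reference_stats(case, adc, perf, "hemisphere", seg$csf_mask)
  refs_v <- compute_reference_stats(case, adc, perf, "voi", seg$csf_mask)
  tables <- list(ABS = tab,
                 RC = normalize_features(tab, refs_h),
                 RVO = normalize_features(tab, refs_v))
  truth <- exclude_csf_from_truth(case$followup_lesion, seg$csf_mask)
  list(case = case, adc = adc, csf_mask = seg$csf_mask,
       analysis_mask = seg$analysis_mask, core = core, dist = dist,
       perf = perf, tables = tables, refs = list(RC = refs_h, RVO = refs_v),
       truth = truth,
       eval_mask = case$ipsilateral_mask & !seg$csf_mask)
}

#' Leave-one-patient-out likelihood prediction over all settings
#'
#' Models are trained per treatment cohort: for every setting and every
#' held-out patient, the classifier is trained on all other patients of the
#' same cohort (with that setting's normalization and balancing) and applied
#' to the held-out patient. Per-fold seeds are derived deterministically
#' from `seed`.
#'
#' @param pre list of preprocessed cases from [preprocess_case()].
#' @param settings data.frame from [classifier_settings()].
#' @param hyper hyperparameter list.
#' @param seed master seed.
#' @param verbose print per-fold progress.
#' @return list of prediction records, each with the patient id, cohort,
#'   setting fields, fold seed and the likelihood `map` (3D array, `NA`
#'   outside the analysis mask).
#' @export
run_loo <- function(pre, settings = classifier_settings(),
                    hyper = default_hyperparameters(), seed = 1L,
                    verbose = FALSE) {
  cohorts <- split(seq_along(pre), vapply(pre, function(p) p$case$cohort,
                                          character(1)))
  store <- list()
  for (cohort in names(cohorts)) {
    members <- cohorts[[cohort]]
    if (length(members) < 2)
      stop("cohort ", cohort, " has fewer than 2 patients; LOO undefined")
    for (si in seq_len(nrow(settings))) {
      st <- settings[si, ]
      tabs <- lapply(pre[members], function(p) p$tables[[st$normalization]])
      for (ti in seq_along(members)) {
        test <- pre[[members[ti]]]
        fold_seed <- derive_seed(seed, cohort, st$setting_id, test$case$id)
        training <- do.call(rbind, tabs[-ti])
        training <- balance_training_set(training, st$balancing,
                                         seed = fold_seed)
        model <- train_classifier(st$classifier, training, hyper,
                                  seed = fold_seed)
        test_tab <- tabs[[ti]]
        lik <- predict_likelihood(model, test_tab)
        rec <- list(patient_id = test$case$id, cohort = cohort,
                    classifier = st$classifier,
                    normalization = st$normalization,
                    balancing = st$balancing, setting_id = st$setting_id,
                    seed = fold_seed,
                    map = likelihood_map(lik, test_tab$voxel_index,
                                         dim(test$case$brain_mask)))
        store[[paste(st$setting_id, test$case$id, sep = ".")]] <- rec
        if (verbose)
          message(sprintf("[%s] %s %s done", cohort, st$setting_id,
                          test$case$id))
      }
    }
  }
  store
}
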