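# Experiment orchestration: a single YAML-serializable config drives
# simulation, the end-to-end study (preprocess -> perfusion -> features ->
# LOO -> calibration -> evaluation), and reporting. The resolved config is
# archived next to the outputs so any run can be reproduced.

#' Default run configuration
#'
#' @param ... named overrides merged recursively into the defaults (e.g.
#'   `synthetic = list(n_per_cohort = c(IAR = 2, IVR = 2, NR = 2))`).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    synthetic = list(),          # cohort_params() overrides
    perfusion = list(truncation = 0.15, baseline_window = 1:3,
                     mode = "linear", k_h = 0.73, rho = 1.04),
    features = list(csf_threshold = 2000e-6, adc_core_threshold = 550e-6),
    classifiers = list(num_trees = 100L, knn_k = 11L, mtry = NULL),
    settings = list(classifiers = c("RDF", "GLM", "KNN"),
                    normalizations = c("ABS", "RC", "RVO"),
                    balancings = c("full", "stratified"))
  )
  utils::modifyList(cfg, list(...))
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return full configuration (file values merged over the defaults).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(default_config()))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(default_config, user)
}

archive_config <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
}

config_params <- function(cfg) {
  do.call(cohort_params, c(cfg$synthetic, list(seed = cfg$seed)))
}

#' Simulate a cohort to disk
#'
#' Writes one NIfTI case directory per patient plus a cohort-level
#' `manifest.csv` (id, cohort, covariates, seed) and the resolved config.
#' Idempotent under an identical config and seed.
#'
#' @param config configuration list.
#' @param output_dir destination directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
simulate_study <- function(config = default_config(), output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  cases <- generate_cohort(params)
  rows <- lapply(cases, function(case) {
    write_case(case, output_dir)
    data.frame(id = case$id, cohort = case$cohort,
               nihss = case$covariates$nihss, age = case$covariates$age,
               sex = case$covariates$sex,
               onset_to_imaging_min = case$covariates$onset_to_imaging,
               seed = case$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  archive_config(config, output_dir)
  invisible(manifest)
}

#' Run the full tissue-outcome prediction study
#'
#' Generates (or loads) the cohort, preprocesses every patient, runs the
#' leave-one-patient-out prediction over all configured settings, calibrates
#' and evaluates, and (optionally) writes `results.csv`, a JSON summary
#' grid, per-prediction NIfTI likelihood maps and an `index.csv`.
#'
#' @param config configuration list.
#' @param output_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @param cohort_dir optional directory of a previously simulated cohort
#'   (read with [read_case()] instead of regenerating).
#' @param keep_store return the raw likelihood maps as well.
#' @param verbose print progress.
#' @return list with `results` (per patient x setting metrics), `summary`
#'   (cohort x setting Dice grid), and optionally `store`.
#' @export
run_study <- function(config = default_config(), output_dir = NULL,
                      cohort_dir = NULL, keep_store = FALSE,
                      verbose = FALSE) {
  cases <- if (is.null(cohort_dir)) {
    generate_cohort(config_params(config))
  } else {
    dirs <- list.dirs(cohort_dir, recursive = FALSE)
    lapply(dirs, read_case)
  }
  if (verbose) message("preprocessing ", length(cases), " cases")
  pre <- lapply(cases, preprocess_case,
                truncation = config$perfusion$truncation,
                csf_threshold = config$features$csf_threshold,
                adc_core_threshold = config$features$adc_core_threshold)
  settings <- do.call(classifier_settings, config$settings)
  hyper <- utils::modifyList(default_hyperparameters(), config$classifiers)
  store <- run_loo(pre, settings, hyper, seed = config$seed, verbose = verbose)
  results <- evaluate_predictions(store, pre)
  summary <- summarize_results(results)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(output_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(split(summary, summary$cohort),
                         file.path(output_dir, "summary.json"),
                         dataframe = "rows", pretty = TRUE)
    index <- do.call(rbind, lapply(names(store), function(k) {
      r <- store[[k]]
      data.frame(patient_id = r$patient_id, cohort = r$cohort,
                 classifier = r$classifier, normalization = r$normalization,
                 balancing = r$balancing, seed = r$seed,
                 path = file.path("likelihood", paste0(k, ".nii.gz")))
    }))
    likdir <- file.path(output_dir, "likelihood")
    dir.create(likdir, showWarnings = FALSE)
    for (k in names(store)) {
      img <- RNifti::asNifti(store[[k]]$map)
      RNifti::pixdim(img) <- pre[[1]]$case$spacing_mm
      RNifti::writeNifti(img, file.path(likdir, paste0(k, ".nii.gz")))
    }
    write.csv(index, file.path(output_dir, "index.csv"), row.names = FALSE)
    archive_config(config, output_dir)
  }
  out <- list(results = results, summary = summary)
  if (keep_store) {
    out$store <- store
    out$pre <- pre
  }
  out
}

#' Summarize a results directory
#'
#' @param results_dir directory containing `results.csv` from [run_study()].
#' @return the summary grid (see [summarize_results()]).
#' @export
report_study <- function(results_dir) {
  f <- file.path(results_dir, "results.csv")
  if (!file.exists(f)) stop("no results.csv in ", results_dir)
  summarize_results(read.csv(f, stringsAsFactors = FALSE))
}
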