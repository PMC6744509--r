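# Feature assembly, contralateral reference statistics, normalization
# variants and stratified balancing.

prep <- function() {
  if (is.null(.fixture_env$prep_nr))
    .fixture_env$prep_nr <- preprocess_case(fixture_case(noise = 0))
  .fixture_env$prep_nr
}

test_that("the feature table has exactly 12 feature columns", {
  tab <- prep()$tables$ABS
  expect_identical(voxelfate:::feature_columns(),
                   c("adc", "distance", "tissue_prob", "region_id", "cbv",
                     "mtt", "tmax", "cbf", "nihss", "age", "sex", "onset_min"))
  expect_length(voxelfate:::feature_columns(), 12)
  expect_true(all(voxelfate:::feature_columns() %in% names(tab)))
  expect_identical(setdiff(names(tab), voxelfate:::feature_columns()),
                   c("patient_id", "voxel_index", "label"))
})

test_that("labels and covariate repetition follow the voxel domain", {
  p <- prep()
  tab <- p$tables$ABS
  case <- p$case
  expect_true(all(tab$voxel_index %in% which(case$ipsilateral_mask & !p$csf_mask)))
  inside <- tab$voxel_index %in% which(p$truth)
  expect_identical(tab$label, as.integer(inside))
  expect_equal(length(unique(tab$nihss)), 1)   # repetition rule
  expect_equal(length(unique(tab$age)), 1)
  expect_equal(tab$nihss[1], case$covariates$nihss)
})

test_that("reference statistics average the contralateral region", {
  p <- prep()
  refs <- compute_reference_stats(p$case, p$adc, p$perf, "hemisphere",
                                  p$csf_mask)
  region <- p$case$contralateral_mask & !p$csf_mask
  expect_equal(refs$mean_adc, mean(p$adc[region]))       # CSF excluded
  expect_equal(refs$mean_cbf, mean(p$perf$cbf[region]))
  # CSF voxels must not shift the mean: including them would
  with_csf <- mean(p$adc[p$case$contralateral_mask], na.rm = TRUE)
  expect_gt(with_csf, refs$mean_adc)
  refs_v <- compute_reference_stats(p$case, p$adc, p$perf, "voi", p$csf_mask)
  voi <- p$case$contralateral_voi_mask & !p$csf_mask
  expect_equal(refs_v$mean_tmax, mean(p$perf$tmax[voi]))
  # single-voxel VOI returns that voxel's values
  case1 <- p$case
  case1$contralateral_voi_mask <- array(FALSE, dim(p$adc))
  vox <- which(p$case$contralateral_mask & !p$csf_mask)[1]
  case1$contralateral_voi_mask[vox] <- TRUE
  refs1 <- compute_reference_stats(case1, p$adc, p$perf, "voi", p$csf_mask)
  expect_equal(refs1$mean_adc, p$adc[vox])
  case1$contralateral_voi_mask[vox] <- FALSE
  expect_error(compute_reference_stats(case1, p$adc, p$perf, "voi",
                                       p$csf_mask), "empty")
})

test_that("normalization applies ratios and subtractions and is invertible", {
  p <- prep()
  tab <- p$tables$ABS
  refs <- compute_reference_stats(p$case, p$adc, p$perf, "hemisphere",
                                  p$csf_mask)
  norm <- normalize_features(tab, refs)
  expect_identical(attr(norm, "normalization"), "RC")
  expect_equal(norm$adc, tab$adc / refs$mean_adc)
  expect_equal(norm$mtt, tab$mtt - refs$mean_mtt)
  # identity values map to 1 (ratio) and 0 (subtraction)
  tab1 <- tab[1, ]
  tab1$adc <- refs$mean_adc
  tab1$mtt <- refs$mean_mtt
  n1 <- normalize_features(tab1, refs)
  expect_equal(n1$adc, 1)
  expect_equal(n1$mtt, 0)
  expect_equal(normalize_features(transform(tab1, adc = 330e-6),
                                  list(mean_adc = 660e-6, mean_cbf = 1,
                                       mean_cbv = 1, mean_mtt = 0,
                                       mean_tmax = 0, mode = "hemisphere"))$adc,
               0.5)
  # round trip
  back <- norm
  for (f in voxelfate:::ratio_normalized())
    back[[f]] <- back[[f]] * refs[[paste0("mean_", f)]]
  for (f in voxelfate:::subtract_normalized())
    back[[f]] <- back[[f]] + refs[[paste0("mean_", f)]]
  for (f in c("adc", "cbf", "cbv", "mtt", "tmax"))
    expect_equal(back[[f]], tab[[f]], tolerance = 1e-12)
  # only the five imaging columns differ between variants
  for (f in setdiff(names(tab), c("adc", "cbf", "cbv", "mtt", "tmax")))
    expect_identical(p$tables$RVO[[f]], tab[[f]])
})

test_that("stratified balancing equalizes per-patient class counts", {
  set.seed(42)
  n1 <- 500; n0 <- 10000
  tab <- toy_table(2 * (n1 + n0))[1:(n1 + n0), ]
  tab$patient_id <- "P1"
  tab$label <- c(rep(1L, n1), rep(0L, n0))
  bal <- balance_training_set(tab, "stratified", seed = 9)
  expect_equal(nrow(bal), 1000)
  expect_equal(sum(bal$label == 1), 500)
  expect_equal(sum(bal$label == 0), 500)
  expect_identical(attr(bal, "balanced"), "stratified")
  # determinism
  bal2 <- balance_training_set(tab, "stratified", seed = 9)
  expect_identical(bal$voxel_index, bal2$voxel_index)
  # full mode unchanged
  expect_equal(nrow(balance_training_set(tab, "full")), n1 + n0)
  # per-patient equality on a two-patient table
  tab2 <- rbind(tab, transform(tab, patient_id = "P2"))
  bal3 <- balance_training_set(tab2, "stratified", seed = 1)
  counts <- table(bal3$patient_id, bal3$label)
  expect_true(all(counts[, "0"] == counts[, "1"]))
  # degenerate: fewer non-lesion than lesion rows
  small <- tab[c(1:10, n1 + 1:3), ]
  expect_warning(bs <- balance_training_set(small, "stratified", seed = 2),
                 "smaller")
  expect_equal(nrow(bs), 13)
  # no lesion voxels at all -> error
  none <- tab[n1 + 1:5, ]
  expect_error(balance_training_set(none, "stratified"), "no lesion")
})
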