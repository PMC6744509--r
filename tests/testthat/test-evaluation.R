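# Evaluation metrics against independent brute-force oracles, CSF exclusion,
# and the single-parameter thresholding baseline.

test_that("Dice follows the overlap formula and empty-mask conventions", {
  g <- c(6, 6, 6)
  A <- array(FALSE, g); A[1:2, 1:5, 1] <- TRUE
  expect_equal(dice(A, A), 1)
  B <- array(FALSE, g); B[4:5, 1:5, 3] <- TRUE
  expect_equal(dice(A, B), 0)                       # disjoint, non-empty
  C <- array(FALSE, g); C[1:5, 1, 1] <- TRUE; C[1:5, 2, 1] <- TRUE
  D <- array(FALSE, g); D[1:5, 2, 1] <- TRUE; D[1:5, 3, 1] <- TRUE
  expect_equal(dice(C, D), 0.5)                     # |A|=|B|=10, overlap 5
  expect_equal(dice(array(FALSE, g), array(FALSE, g)), 1)
  expect_equal(dice(array(FALSE, g), A), 0)
})

test_that("CSF exclusion is plain set subtraction", {
  g <- c(6, 6, 4)
  lesion <- array(FALSE, g); lesion[1:5, 1:2, 1] <- TRUE   # 10 voxels
  csf <- array(FALSE, g); csf[1:3, 1, 1] <- TRUE           # 3 overlap
  expect_equal(sum(exclude_csf_from_truth(lesion, csf)), 7)
  none <- array(FALSE, g)
  expect_identical(exclude_csf_from_truth(lesion, none), lesion)
  expect_warning(out <- exclude_csf_from_truth(csf, csf), "empty")
  expect_false(any(out))
})

test_that("confusion metrics equal brute-force counts on random masks", {
  set.seed(31)
  g <- c(8, 8, 8)
  ev <- array(TRUE, g)
  for (rep in 1:30) {
    pred <- random_mask(g, 2, p_empty = 0.1)
    truth <- random_mask(g, 2, p_empty = 0.1)
    cm <- confusion_metrics(pred, truth, ev)
    bf <- brute_force_confusion(pred, truth, ev)
    expect_equal(c(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn), bf)
    sens <- if (bf["tp"] + bf["fn"] > 0) bf[["tp"]] / (bf[["tp"]] + bf[["fn"]]) else NA_real_
    expect_equal(cm$sensitivity, sens)
    den <- sqrt(bf[["tp"]] + bf[["fp"]]) * sqrt(bf[["tp"]] + bf[["fn"]]) *
      sqrt(bf[["tn"]] + bf[["fp"]]) * sqrt(bf[["tn"]] + bf[["fn"]])
    mcc <- if (den == 0) 0 else
      (bf[["tp"]] * bf[["tn"]] - bf[["fp"]] * bf[["fn"]]) / den
    expect_equal(cm$mcc, mcc, tolerance = 1e-12)
  }
  p <- array(FALSE, g); t <- random_mask(g, 1)
  expect_equal(confusion_metrics(p, t, ev)$sensitivity, 0)
  full <- random_mask(g, 1)
  cm1 <- confusion_metrics(full, full, ev)
  expect_equal(cm1$sensitivity, 1); expect_equal(cm1$mcc, 1)
  expect_error(confusion_metrics(p, t, array(FALSE, g)), "empty")
})

test_that("surface distances match the all-pairs oracle", {
  set.seed(57)
  g <- c(8, 8, 8)
  for (rep in 1:10) {
    A <- random_mask(g, 2); B <- random_mask(g, 2)
    if (!any(A)) A[2, 2, 2] <- TRUE
    if (!any(B)) B[5, 5, 5] <- TRUE
    sp <- sample(c(1, 1, 2), 3, replace = TRUE)
    got <- surface_distances(A, B, sp)
    want <- brute_force_surface(A, B, sp)
    expect_equal(got$msd_mm, want$msd, tolerance = 1e-9)
    expect_equal(got$hd_mm, want$hd, tolerance = 1e-9)
  }
  A <- random_mask(g, 2)
  expect_equal(surface_distances(A, A)$msd_mm, 0)
  expect_equal(surface_distances(A, A)$hd_mm, 0)
  # two single-voxel masks d apart
  P <- array(FALSE, g); P[2, 2, 2] <- TRUE
  Q <- array(FALSE, g); Q[2, 2, 6] <- TRUE
  sd1 <- surface_distances(P, Q, c(1, 1, 2.5))
  expect_equal(sd1$msd_mm, 10)
  expect_equal(sd1$hd_mm, 10)
  # empty mask: NA sentinels
  e <- surface_distances(array(FALSE, g), P)
  expect_true(is.na(e$msd_mm) && is.na(e$hd_mm))
})

test_that("volume difference is a signed unit conversion", {
  g <- c(12, 12, 12)
  pred <- array(FALSE, g); pred[1:10, 1:10, 1:10] <- TRUE   # 1000 voxels
  truth <- array(FALSE, g)
  expect_equal(volume_difference(pred, truth, c(1, 1, 1)), 1)   # 1 mL
  expect_equal(volume_difference(truth, pred, c(1, 1, 1)), -1)  # antisymmetry
  expect_equal(volume_difference(pred, pred, c(2, 2, 2)), 0)
  expect_equal(volume_difference(pred, truth, c(2, 2, 2)), 8)
})

test_that("a perfectly informative parameter reaches Dice 1 in the baseline", {
  pre <- fixture_pre()
  nr <- pre[vapply(pre, function(p) p$case$cohort, character(1)) == "NR"]
  # replace the ADC map by 1 - truth indicator: "<= tau" direction separates
  fake <- lapply(nr, function(p) {
    p$adc <- array(1, dim(p$adc))
    p$adc[p$truth] <- 0
    p
  })
  res <- single_param_baseline(fake, params = "adc", normalizations = "ABS")
  expect_true(all(res$dice > 0.95))   # post-processing may trim tiny bits
})

test_that("planted diffusion signal beats a pure-noise parameter map", {
  pre <- fixture_pre()
  nr <- pre[vapply(pre, function(p) p$case$cohort, character(1)) == "NR"]
  res_adc <- single_param_baseline(nr, params = "adc", normalizations = "ABS")
  noise <- lapply(nr, function(p) {
    set.seed(match(p$case$id, vapply(nr, function(q) q$case$id, character(1))))
    p$adc <- array(runif(length(p$adc)), dim(p$adc))
    p
  })
  res_noise <- single_param_baseline(noise, params = "adc",
                                     normalizations = "ABS")
  expect_gt(mean(res_adc$dice), mean(res_noise$dice))
})

test_that("aggregation summarizes without recomputation", {
  res <- data.frame(
    patient_id = rep(c("a", "b"), 4),
    cohort = "NR",
    classifier = rep(c("RDF", "GLM"), each = 4),
    normalization = "ABS",
    balancing = rep(c("full", "stratified"), each = 2),
    dice = c(0.5, 0.7, 0.4, 0.6, 0.3, 0.5, 0.2, 0.4))
  s <- summarize_results(res)
  expect_equal(nrow(s), 4)
  expect_equal(s$mean_dice[s$classifier == "RDF" & s$balancing == "full"], 0.6)
  expect_equal(s$sd_dice[s$classifier == "GLM" & s$balancing == "full"],
               sd(c(0.3, 0.5)))
  expect_equal(sum(s$best), 1)
  expect_error(summarize_results(res[0, ]), "empty")
})
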