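# Perfusion chain: concentration conversion, spline resampling, AIF
# selection, block-circulant SVD deconvolution, parameter maps.

test_that("signal-to-concentration inverts the exponential signal model", {
  S0 <- 100
  S <- rep(S0, 10)
  expect_equal(signal_to_concentration(S, 1:3, TE = 0.045), rep(0, 10))
  S[6] <- S0 * exp(-0.045 * 5)
  C <- signal_to_concentration(S, 1:3, TE = 0.045)
  expect_equal(C[6], 5)
  expect_error(signal_to_concentration(c(-1, S[-1]), 1:3, TE = 0.045),
               "nonpositive")
  expect_error(signal_to_concentration(S, 1:3, TE = 0.045, mode = "kjolby"),
               "coefficients")
  # quadratic correction applied on top of the linear conversion
  Ck <- signal_to_concentration(S, 1:3, TE = 0.045, mode = "kjolby",
                                coefficients = c(1, 0.1))
  expect_equal(Ck[6], 5 + 0.1 * 25)
})

test_that("noise-free generator signals round-trip to planted concentration", {
  case <- fixture_case(noise = 0)
  vox <- which(case$brain_mask & case$perf_truth$delay == 4)[1]
  S <- pwi_series(case$pwi, vox)
  C <- signal_to_concentration(S, 1:3, TE = case$TE_s)
  aif_m <- case$true_aif$values
  planted <- voxelfate:::forward_concentration(
    aif_m, 1, 25, 3, 4, 0.73, 1.04)
  t_frames <- (seq_along(S) - 1) * case$TR_s
  expected <- splinefun(seq_along(aif_m) - 1, planted, method = "fmm")(t_frames)
  expect_lt(max(abs(C - expected)), 1e-9)
})

test_that("temporal interpolation reproduces knots, lines and smooth curves", {
  y <- c(0, 3, 1, 4, 2, 5, 3)
  out <- interpolate_temporal(y, dt = 1)
  expect_equal(out$values, y)                      # already on the 1 s grid
  ramp <- 2 * (0:6) * 1.5 + 1                       # linear in time
  out2 <- interpolate_temporal(ramp, dt = 1.5)
  expect_equal(out2$values, 2 * seq(0, 9, by = 1) + 1)
  # smooth curve: spline error small against the closed form
  t0 <- seq(0, 30, by = 1.5)
  out3 <- interpolate_temporal(sin(2 * pi * t0 / 15), dt = 1.5)
  t1 <- seq(0, 30, by = 1)
  expect_lt(max(abs(out3$values - sin(2 * pi * t1 / 15))), 1e-2)
  expect_error(interpolate_temporal(c(1, 2, 3), dt = 1.5), "4 time points")
})

test_that("AIF selection returns the simulated or mask-averaged curve", {
  case <- fixture_case(noise = 0)
  expect_identical(select_aif(case, "known"), case$true_aif)
  conc <- rbind(c(0, 1, 2, 1), c(0, 3, 4, 3), c(0, 1, 2, 1))
  one <- select_aif(mode = "mask_mean", conc = conc, mask = c(F, T, F))
  expect_equal(one$values, c(0, 3, 4, 3))
  same <- select_aif(mode = "mask_mean", conc = conc[c(1, 3), ],
                     mask = c(TRUE, TRUE))
  expect_equal(same$values, c(0, 1, 2, 1))          # mean of identical curves
  expect_error(select_aif(mode = "mask_mean", conc = conc,
                          mask = c(F, F, F)), "empty arterial mask")
})

test_that("impulse AIF makes deconvolution the identity (up to dt)", {
  L <- 20
  aif <- c(1, numeric(L - 1))   # discrete delta of area dt, dt = 0.5
  C <- exp(-(0:(L - 1)) / 4)
  k <- bsvd_deconvolve(C, list(values = aif, dt = 0.5), dt = 0.5,
                       truncation = 0)
  expect_equal(k[seq_len(L)], C / 0.5, tolerance = 1e-8)
  expect_error(bsvd_deconvolve(C, list(values = numeric(L), dt = 0.5)),
               "all-zero")
  expect_error(bsvd_deconvolve(C[1:10], list(values = aif, dt = 0.5)),
               "different time grids")
})

test_that("noise-free deconvolution recovers planted flow, delay and kinetics", {
  # well-conditioned compact system: residue support + AIF support < L, so
  # the zero-padded circulant model is exact
  t <- 0:99
  aif <- voxelfate:::gamma_variate_aif(t, 8, 3, 1.5, 12)
  # spec-level kinetics: R(t) = exp(-t/6 s), CBF = 40
  f <- (1.04 / 0.73) * 40 / 6000
  ktrue <- ifelse(t <= 40, f * exp(-t / 6), 0)
  C <- convolve(aif, rev(ktrue), type = "open")[seq_along(t)] * 1
  k <- bsvd_deconvolve(C, list(values = aif, dt = 1), truncation = 0)
  cbf_rec <- (0.73 / 1.04) * max(k[seq_along(t)]) * 6000
  expect_lt(abs(cbf_rec - 40) / 40, 0.05)
  expect_lt(sqrt(sum((k[seq_along(t)] - ktrue)^2) / sum(ktrue^2)), 1e-6)
  # delayed tissue curve: argmax of k sits at the planted delay
  kdel <- ifelse(t >= 3 & t <= 43, f * exp(-(t - 3) / 6), 0)
  Cd <- convolve(aif, rev(kdel), type = "open")[seq_along(t)] * 1
  kd <- bsvd_deconvolve(Cd, list(values = aif, dt = 1), truncation = 0)
  expect_equal(which.max(kd[seq_along(t)]) - 1, 3)
})

test_that("raising the truncation never increases the residue energy", {
  t <- 0:40
  aif <- voxelfate:::gamma_variate_aif(t, 8, 3, 1.5, 12)
  f <- (1.04 / 0.73) * 30 / 6000
  C <- convolve(aif, rev(f * exp(-t / 5)), type = "open")[seq_along(t)]
  energies <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(tr)
    sum(bsvd_deconvolve(C, list(values = aif, dt = 1), truncation = tr)^2),
    numeric(1))
  expect_true(all(diff(energies) <= 1e-12))
})

test_that("perfusion parameters follow the central volume theorem", {
  # CBV 4 mL/100g at CBF 40 mL/100g/min -> MTT = 6 s
  t <- 0:58
  aif <- voxelfate:::gamma_variate_aif(t, 8, 3, 1.5, 12)
  C <- voxelfate:::forward_concentration(aif, 1, 40, 4, 0, 0.73, 1.04)
  k <- bsvd_deconvolve(C, list(values = aif, dt = 1), truncation = 0)
  pp <- perfusion_parameters(k, C, aif, dt = 1)
  expect_equal(pp$cbf, 40, tolerance = 1e-6)
  expect_equal(pp$cbv, 4, tolerance = 1e-3)
  expect_equal(pp$mtt, 6, tolerance = 1e-3)
  expect_equal(pp$tmax, 0)
  # tissue curve identical to the AIF: unit volume ratio
  ka <- bsvd_deconvolve(aif, list(values = aif, dt = 1), truncation = 0)
  pa <- perfusion_parameters(ka, aif, aif, dt = 1)
  expect_equal(pa$cbv, 0.73 / 1.04 * 100, tolerance = 1e-9)
})

test_that("volume driver matches the curve-level path and planted truth", {
  case <- fixture_case(noise = 0)
  perf <- compute_perfusion_maps(case, truncation = 0)
  # one voxel recomputed through the curve-level operations
  vox <- which(case$brain_mask & case$perf_truth$delay == 0)[1]
  S <- pwi_series(case$pwi, vox)
  C <- signal_to_concentration(S, 1:3, TE = case$TE_s)
  Ci <- interpolate_temporal(C, dt = case$TR_s)
  aif <- select_aif(case, "known")
  L <- min(length(Ci$values), length(aif$values))
  k <- bsvd_deconvolve(Ci$values[1:L], list(values = aif$values[1:L], dt = 1),
                       truncation = 0)
  pp <- perfusion_parameters(k, Ci$values[1:L], aif$values[1:L], dt = 1)
  expect_equal(perf$cbf[vox], pp$cbf, tolerance = 1e-9)
  expect_equal(perf$tmax[vox], pp$tmax)
  # planted values per region after the TR-grid round trip: CBF/MTT within
  # 10% (spline resampling error), CBV within 5%, Tmax within one time step
  for (rg in list(c(60, 4, 0), c(25, 3, 4), c(10, 1.5, 8))) {
    sel <- case$brain_mask & !case$csf_mask & case$perf_truth$cbf == rg[1]
    expect_lt(abs(mean(perf$cbf[sel]) - rg[1]) / rg[1], 0.10)
    expect_lt(abs(mean(perf$cbv[sel]) - rg[2]) / rg[2], 0.05)
    mtt_true <- rg[2] / rg[1] * 60
    expect_lt(abs(mean(perf$mtt[sel]) - mtt_true) / mtt_true, 0.1)
    expect_lte(abs(mean(perf$tmax[sel]) - rg[3]), 1)
  }
})
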