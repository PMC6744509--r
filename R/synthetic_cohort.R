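# Synthetic stroke cohort generator.
#
# Emulates the study population: three treatment cohorts (IAR = intraarterial
# recanalizers, IVR = intravenous recanalizers, NR = non-recanalizers), each
# patient carrying co-registered DWI (b=0 and high-b), a 4D dynamic
# susceptibility contrast PWI series, hemisphere/CSF masks, an ischemic core
# (low ADC), a hypoperfused penumbra (reduced CBF, elevated MTT and Tmax) and
# a follow-up lesion equal to the core plus the non-salvaged, core-adjacent
# part of the penumbra. Cohort-specific penumbral salvage gives each cohort a
# learnable treatment effect.

#' Parameters for the synthetic stroke cohort
#'
#' Returns the default study conditions; any field may be overridden via
#' `...`. Covariate distributions are per-cohort means with standard errors
#' (converted internally to SDs using the cohort size they were estimated
#' from) for NIHSS, age and onset-to-imaging time, plus the percentage of
#' female patients.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `cohort_params`.
#' @details Key defaults: cohort sizes IAR 33 / IVR 23 / NR 34; DWI b-values
#'   0 and 1000 s/mm2; PWI TR 1.5 s, TE 0.045 s, 40 frames; mean ADC
#'   (mm2/s): tissue 800e-6, core 400e-6, CSF 3000e-6; perfusion triples
#'   (CBF mL/100g/min, CBV mL/100g, bolus delay s): normal (60, 4, 0),
#'   penumbra (25, 3, 4), core (10, 1.5, 8); penumbral salvage fraction
#'   IAR 0.6, IVR 0.5, NR 0.1.
#' @export
cohort_params <- function(...) {
  p <- list(
    n_per_cohort = c(IAR = 33L, IVR = 23L, NR = 34L),
    grid_shape   = c(24L, 24L, 24L),
    spacing_mm   = c(2, 2, 2),
    b_values     = c(0, 1000),
    TR_s         = 1.5,
    TE_s         = 0.045,
    n_timepoints = 40L,
    adc_tissue   = c(mean = 800e-6, sd = 40e-6),
    adc_core     = c(mean = 400e-6, sd = 30e-6),
    adc_csf      = c(mean = 3000e-6, sd = 100e-6),
    perf_normal   = c(cbf = 60, cbv = 4,   delay = 0),
    perf_core     = c(cbf = 10, cbv = 1.5, delay = 8),
    perf_penumbra = c(cbf = 25, cbv = 3,   delay = 4),
    salvage_fraction = c(IAR = 0.6, IVR = 0.5, NR = 0.1),
    covariate_distributions = list(
      IAR = list(nihss = c(15.85, 0.91), age = c(70, 1.76),
                 pct_female = 52, onset = c(162.61, 17.71), n_ref = 33),
      IVR = list(nihss = c(14.30, 1.31), age = c(74, 2.74),
                 pct_female = 78, onset = c(97.83, 12.28), n_ref = 23),
      NR  = list(nihss = c(15.85, 0.89), age = c(75, 2.19),
                 pct_female = 96, onset = c(171.76, 22.08), n_ref = 34)
    ),
    noise_sd = 0.02,      # fractional Gaussian signal noise; 0 = clean
    dwi_s0   = 1000,      # DWI b=0 signal level (a.u.)
    pwi_s0   = 100,       # PWI pre-bolus signal level (a.u.)
    aif      = c(t0 = 8, alpha = 3, beta = 1.5, amplitude = 12),
    k_h      = 0.73,      # hematocrit correction used in the forward model
    rho      = 1.04,      # brain tissue density g/mL
    seed     = 42L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown cohort parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  # YAML-sourced configs deliver named lists where vectors are expected
  for (f in c("n_per_cohort", "grid_shape", "spacing_mm", "b_values",
              "salvage_fraction", "adc_tissue", "adc_core", "adc_csf",
              "perf_normal", "perf_core", "perf_penumbra", "aif"))
    if (is.list(p[[f]])) p[[f]] <- unlist(p[[f]])
  p$n_per_cohort <- vapply(p$n_per_cohort, as.integer, integer(1))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (any(p$n_per_cohort <= 0)) stop("n_per_cohort must be positive")
  if (any(p$salvage_fraction < 0 | p$salvage_fraction > 1))
    stop("salvage_fraction must lie in [0, 1]")
  if (!(p$adc_core[["mean"]] < p$adc_tissue[["mean"]] &&
        p$adc_tissue[["mean"]] < p$adc_csf[["mean"]]))
    stop("ADC ordering violated: need core < tissue < CSF mean")
  for (f in c("perf_normal", "perf_core", "perf_penumbra"))
    if (any(p[[f]][c("cbf", "cbv")] <= 0))
      stop(f, ": CBF and CBV must be strictly positive")
  if (p$dwi_s0 <= 0 || p$pwi_s0 <= 0) stop("signal levels must be positive")
  if (any(p$grid_shape < c(16L, 16L, 8L)))
    stop("grid_shape too small: need at least 16 x 16 x 8 voxels")
  invisible(p)
}

# Ellipsoid mask helper on a voxel grid (1-based centers/radii in voxels).
ellipsoid_mask <- function(dim, center, radii) {
  cx <- seq_len(dim[1]); cy <- seq_len(dim[2]); cz <- seq_len(dim[3])
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Normalized ellipsoidal squared radius of every voxel w.r.t. the brain.
ellipsoid_rho2 <- function(dim, center, radii) {
  cx <- seq_len(dim[1]); cy <- seq_len(dim[2]); cz <- seq_len(dim[3])
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# Gamma-variate arterial input function on time grid t (seconds).
gamma_variate_aif <- function(t, t0, alpha, beta, amplitude) {
  tt <- pmax(t - t0, 0)
  tp <- alpha * beta
  a <- ifelse(tt > 0, (tt / tp)^alpha * exp(alpha * (1 - tt / tp)), 0)
  amplitude * a
}

# Tissue concentration on the 1 s model grid by discrete convolution of the
# AIF with the delayed scaled residue function k(t) = f * R(t - delay),
# R(t) = exp(-t / tau). `f` folds in the density/hematocrit constants so the
# analysis chain recovers CBF in mL/100g/min. The time constant tau is set
# so that the residue's *numerical* area on the analysis grid (rectangle
# sum, the same quadrature the deconvolution chain uses) equals the planted
# MTT = CBV/CBF: tau = -dt / log(1 - dt/MTT). This makes the forward model
# the exact inverse of the analysis chain, so noise-free recovery of CBF,
# CBV, MTT and Tmax is exact rather than biased by dt/2.
forward_concentration <- function(aif, dt, cbf, cbv, delay, k_h, rho) {
  mtt_s <- cbv / cbf * 60
  if (mtt_s <= dt)
    stop("planted MTT must exceed the model grid interval (", dt, " s)")
  tau <- -dt / log(1 - dt / mtt_s)
  f <- (rho / k_h) * cbf / 6000          # mL/g/s
  t <- (seq_along(aif) - 1) * dt
  k <- ifelse(t >= delay, f * exp(-(t - delay) / tau), 0)
  full <- convolve(aif, rev(k), type = "open") * dt
  full[seq_along(aif)]
}

#' Generate one synthetic stroke patient
#'
#' Builds a parametric head: an ellipsoidal brain split by a midline plane
#' into ipsi- and contralateral hemispheres, ventricular CSF blobs, and a
#' nested core/penumbra lesion system in the ipsilateral hemisphere. The
#' follow-up lesion is the core plus the fraction of the penumbra closest to
#' the core that the cohort's salvage fraction leaves uninfarcted. DWI obeys
#' the mono-exponential diffusion signal model and PWI is forward-simulated
#' from per-region perfusion triples through the indicator-dilution model.
#'
#' @param params a [cohort_params()] object.
#' @param cohort one of `"IAR"`, `"IVR"`, `"NR"`.
#' @param seed RNG seed for this patient.
#' @param id patient identifier string.
#' @return a list of class `patient_case`; see package vignette for fields.
#' @export
generate_patient <- function(params, cohort = c("IAR", "IVR", "NR"),
                             seed = params$seed, id = paste0(cohort, "_1")) {
  cohort <- match.arg(cohort)
  validate_cohort_params(params)
  g <- as.integer(params$grid_shape)
  ctr <- (g + 1) / 2
  brain_r <- 0.45 * g

  brain <- ellipsoid_mask(g, ctr, brain_r)
  xidx <- slice.index(brain, 1)
  ipsi <- brain & (xidx > ctr[1])
  contra <- brain & (xidx <= ctr[1])

  csf <- (ellipsoid_mask(g, ctr + c(0, 0.15, 0) * g, 0.10 * g * c(1, 1, 1.6)) |
          ellipsoid_mask(g, ctr - c(0, 0.15, 0) * g, 0.10 * g * c(1, 1, 1.6))) & brain

  core_ctr <- ctr + c(0.22 * g[1], 0, 0)
  core_ell <- ellipsoid_mask(g, core_ctr, 0.10 * g)
  pen_ell  <- ellipsoid_mask(g, core_ctr, 0.18 * g)
  if (any(core_ell & !(ipsi & !csf)))
    stop("lesion core does not fit inside the ipsilateral hemisphere; ",
         "enlarge grid_shape or adjust geometry")
  core <- core_ell & ipsi & !csf
  pen <- pen_ell & !core_ell & ipsi & !csf
  if (!any(core) || !any(pen))
    stop("degenerate lesion geometry: empty core or penumbra")

  # Follow-up lesion: core plus the (1 - salvage) fraction of the penumbra
  # nearest the core (ties broken by voxel index for determinism).
  salvage <- params$salvage_fraction[[cohort]]
  d2 <- cpp_edt_squared(as.logical(core), g, c(1, 1, 1))
  pen_idx <- which(pen)
  keep_n <- round((1 - salvage) * length(pen_idx))
  ord <- pen_idx[order(d2[pen_idx], pen_idx)]
  followup <- core
  if (keep_n > 0) followup[ord[seq_len(keep_n)]] <- TRUE

  voi <- array(FALSE, g)  # mirror of the core across the midline plane
  ci <- which(core, arr.ind = TRUE)
  mi <- cbind(g[1] + 1L - ci[, 1], ci[, 2], ci[, 3])
  voi[mi] <- TRUE
  voi <- voi & contra & !csf

  set.seed(seed)
  nb <- sum(brain)
  adc <- array(0, g)
  tiss_idx <- which(brain & !csf & !core)
  adc[tiss_idx] <- pmin(pmax(rnorm(length(tiss_idx), params$adc_tissue[["mean"]],
                                   params$adc_tissue[["sd"]]), 600e-6), 1500e-6)
  core_idx <- which(core)
  adc[core_idx] <- pmin(pmax(rnorm(length(core_idx), params$adc_core[["mean"]],
                                   params$adc_core[["sd"]]), 250e-6), 540e-6)
  csf_idx <- which(csf)
  adc[csf_idx] <- pmax(rnorm(length(csf_idx), params$adc_csf[["mean"]],
                             params$adc_csf[["sd"]]), 2200e-6)

  bhigh_val <- max(params$b_values)
  noise <- function(n) if (params$noise_sd > 0) 1 + rnorm(n, 0, params$noise_sd) else rep(1, n)
  dwi_b0 <- array(10, g)
  dwi_b0[brain] <- params$dwi_s0 * noise(nb)
  dwi_bhigh <- array(10, g)
  dwi_bhigh[brain] <- pmax(params$dwi_s0 * exp(-bhigh_val * adc[brain]) * noise(nb), 1e-3)
  dwi_b0[brain] <- pmax(dwi_b0[brain], 1e-3)

  # Perfusion forward model on the internal 1 s grid.
  nt <- params$n_timepoints
  t_end <- (nt - 1) * params$TR_s
  t_model <- seq(0, floor(t_end), by = 1)
  aif <- gamma_variate_aif(t_model, params$aif[["t0"]], params$aif[["alpha"]],
                           params$aif[["beta"]], params$aif[["amplitude"]])
  regions <- list(normal = params$perf_normal, penumbra = params$perf_penumbra,
                  core = params$perf_core)
  t_frames <- (seq_len(nt) - 1) * params$TR_s
  conc_frames <- lapply(regions, function(r) {
    cm <- forward_concentration(aif, 1, r[["cbf"]], r[["cbv"]], r[["delay"]],
                                params$k_h, params$rho)
    splinefun(t_model, cm, method = "fmm")(t_frames)
  })

  region_lab <- array("normal", g)
  region_lab[pen] <- "penumbra"
  region_lab[core] <- "core"
  pwi <- array(params$pwi_s0, c(g, nt))
  b_lin <- which(brain)
  nvox_t <- length(b_lin)
  sig <- vapply(seq_len(nt), function(ti) {
    cvals <- numeric(nvox_t)
    for (rn in names(regions)) {
      sel <- region_lab[b_lin] == rn
      cvals[sel] <- conc_frames[[rn]][ti]
    }
    pmax(params$pwi_s0 * exp(-params$TE_s * cvals) * noise(nvox_t), 1e-3)
  }, numeric(nvox_t))
  for (ti in seq_len(nt)) {
    slab <- pwi[, , , ti]
    slab[b_lin] <- sig[, ti]
    pwi[, , , ti] <- slab
  }

  # Ground-truth perfusion maps (for recovery tests and reporting).
  truth_maps <- list(cbf = array(NA_real_, g), cbv = array(NA_real_, g),
                     delay = array(NA_real_, g))
  for (rn in names(regions)) {
    sel <- brain & (region_lab == rn)
    truth_maps$cbf[sel] <- regions[[rn]][["cbf"]]
    truth_maps$cbv[sel] <- regions[[rn]][["cbv"]]
    truth_maps$delay[sel] <- regions[[rn]][["delay"]]
  }

  atlas <- make_surrogate_atlas(brain, g, ctr, brain_r)

  cd <- params$covariate_distributions[[cohort]]
  sdmul <- sqrt(cd$n_ref)  # reported dispersions are standard errors
  covariates <- list(
    nihss = min(max(round(rnorm(1, cd$nihss[1], cd$nihss[2] * sdmul)), 0L), 42L),
    age = min(max(round(rnorm(1, cd$age[1], cd$age[2] * sdmul)), 18L), 100L),
    sex = rbinom(1, 1, cd$pct_female / 100),
    onset_to_imaging = max(rnorm(1, cd$onset[1], cd$onset[2] * sdmul), 30)
  )

  structure(list(
    id = id, cohort = cohort, seed = seed,
    dwi_b0 = dwi_b0, dwi_bhigh = dwi_bhigh, pwi = pwi,
    brain_mask = brain, csf_mask = csf,
    ipsilateral_mask = ipsi, contralateral_mask = contra,
    contralateral_voi_mask = voi,
    core_truth = core, penumbra_truth = pen, followup_lesion = followup,
    adc_truth = adc, perf_truth = truth_maps,
    atlas_tissue_prob = atlas$tissue_prob, atlas_region_id = atlas$region_id,
    true_aif = list(values = aif, dt = 1, t0 = 0),
    covariates = covariates,
    spacing_mm = params$spacing_mm,
    b_values = params$b_values, TR_s = params$TR_s, TE_s = params$TE_s
  ), class = "patient_case")
}

# Surrogate atlas: nine anatomical region labels by nearest-anchor
# assignment on a 3x3 in-plane anchor grid, plus a smooth white-matter
# probability field (1 at the brain center, 0 at the surface). Stands in for
# MNI atlas registration, which needs real anatomy.
make_surrogate_atlas <- function(brain, g, ctr, brain_r) {
  anchors <- as.matrix(expand.grid(fx = c(0.3, 0.5, 0.7), fy = c(0.3, 0.5, 0.7)))
  anchors <- cbind(anchors[, 1] * g[1], anchors[, 2] * g[2], ctr[3])
  idx <- which(brain, arr.ind = TRUE)
  d2 <- sapply(seq_len(nrow(anchors)), function(a)
    (idx[, 1] - anchors[a, 1])^2 + (idx[, 2] - anchors[a, 2])^2 +
      (idx[, 3] - anchors[a, 3])^2)
  region <- array(NA_integer_, g)
  region[brain] <- max.col(-d2, ties.method = "first")
  tp <- array(NA_real_, g)
  rho2 <- ellipsoid_rho2(g, ctr, brain_r)
  tp[brain] <- pmin(pmax(1 - rho2[brain], 0), 1)
  list(region_id = region, tissue_prob = tp)
}

#' Generate a full synthetic cohort
#'
#' @param params a [cohort_params()] object.
#' @return list of `patient_case` objects (IAR, then IVR, then NR), with
#'   per-patient seeds derived deterministically from `params$seed`.
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  cases <- list()
  for (cohort in names(params$n_per_cohort)) {
    n <- params$n_per_cohort[[cohort]]
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", cohort, i)
      seed_i <- derive_seed(params$seed, cohort, i)
      cases[[id]] <- generate_patient(params, cohort, seed = seed_i, id = id)
    }
  }
  cases
}
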