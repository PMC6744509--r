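# Dynamic susceptibility contrast perfusion analysis: signal-to-concentration
# conversion, temporal resampling to a 1 s grid, arterial input function
# selection, block-circulant SVD deconvolution with singular-value
# truncation, and the CBF / CBV / MTT / Tmax parameter maps.

#' Convert a PWI signal curve to contrast concentration
#'
#' Linear mode uses the log conversion `C(t) = -ln(S(t)/S0) / TE` with `S0`
#' the mean over the baseline window. The optional quadratic mode applies a
#' user-supplied tissue relaxivity correction `C' = a1*C + a2*C^2` on top of
#' the linear result (coefficients are deliberately not defaulted, as they
#' are scanner- and tissue-specific).
#'
#' @param S positive signal vector (or matrix: voxels x time).
#' @param baseline_window integer indices of pre-bolus frames (default 1:3).
#' @param TE echo time in seconds.
#' @param mode `"linear"` or `"kjolby"` (quadratic correction).
#' @param coefficients numeric `c(a1, a2)` for the quadratic mode.
#' @return concentration curve(s), same shape as `S`.
#' @export
signal_to_concentration <- function(S, baseline_window = 1:3, TE,
                                    mode = c("linear", "kjolby"),
                                    coefficients = NULL) {
  mode <- match.arg(mode)
  if (length(baseline_window) < 1) stop("baseline window must be non-empty")
  if (any(S <= 0)) stop("nonpositive PWI signal")
  vec <- is.null(dim(S))
  Sm <- if (vec) matrix(S, nrow = 1) else S
  s0 <- rowMeans(Sm[, baseline_window, drop = FALSE])
  if (any(s0 <= 0)) stop("nonpositive baseline signal S0")
  C <- -log(Sm / s0) / TE
  if (mode == "kjolby") {
    if (is.null(coefficients) || length(coefficients) != 2)
      stop("kjolby mode requires `coefficients = c(a1, a2)`")
    C <- coefficients[1] * C + coefficients[2] * C^2
  }
  if (vec) C[1, ] else C
}

#' Resample a concentration curve onto a uniform 1 s grid
#'
#' Cubic spline resampling spanning the original time range. The spline
#' reproduces the samples at the original knots and is exact for
#' polynomials up to degree 3.
#'
#' @param values concentration samples (vector, or matrix voxels x time).
#' @param dt original sampling interval in seconds.
#' @param target_dt target interval, default 1 s.
#' @param t0 time of the first sample, default 0.
#' @return list with `values` (same shape class as input), `dt`, `t0`.
#' @export
interpolate_temporal <- function(values, dt, target_dt = 1, t0 = 0) {
  vec <- is.null(dim(values))
  Vm <- if (vec) matrix(values, nrow = 1) else values
  L <- ncol(Vm)
  if (L < 4) stop("need at least 4 time points for cubic spline resampling")
  t_orig <- t0 + (seq_len(L) - 1) * dt
  t_new <- seq(t_orig[1], t_orig[L], by = target_dt)
  # Spline interpolation is linear in the data: build the weight matrix once
  # by interpolating the unit vectors, then map all voxels in one product.
  W <- vapply(seq_len(L), function(j) {
    e <- numeric(L); e[j] <- 1
    splinefun(t_orig, e, method = "fmm")(t_new)
  }, numeric(length(t_new)))
  out <- Vm %*% t(W)
  list(values = if (vec) out[1, ] else out, dt = target_dt, t0 = t_orig[1])
}

#' Select the arterial input function for a case
#'
#' `"known"` mode returns the simulated ground-truth AIF carried by a
#' synthetic case (already on the 1 s model grid); `"mask_mean"` averages
#' the concentration curves of the voxels in an arterial mask.
#'
#' @param case a `patient_case` (for `"known"` mode).
#' @param mode `"known"` or `"mask_mean"`.
#' @param conc voxels x time concentration matrix (for `"mask_mean"`).
#' @param mask logical vector/array selecting arterial rows of `conc`.
#' @param dt sampling interval of `conc`, seconds.
#' @return list with `values`, `dt`, `t0`.
#' @export
select_aif <- function(case = NULL, mode = c("known", "mask_mean"),
                       conc = NULL, mask = NULL, dt = 1) {
  mode <- match.arg(mode)
  if (mode == "known") {
    if (is.null(case$true_aif)) stop("case carries no simulated AIF")
    return(case$true_aif)
  }
  if (is.null(conc) || is.null(mask)) stop("mask_mean mode needs `conc` and `mask`")
  sel <- which(as.logical(mask))
  if (length(sel) == 0) stop("empty arterial mask")
  list(values = colMeans(conc[sel, , drop = FALSE]), dt = dt, t0 = 0)
}

# Truncated pseudo-inverse of the 2L block-circulant AIF convolution matrix.
# Shared by all voxels of a patient, so it is computed once.
bsvd_operator <- function(aif_values, dt, truncation = 0.15) {
  if (all(aif_values == 0)) stop("all-zero AIF cannot be deconvolved")
  L <- length(aif_values)
  L2 <- 2L * L
  apad <- c(aif_values, numeric(L))
  first_col <- apad
  D <- matrix(0, L2, L2)
  for (j in seq_len(L2))
    D[, j] <- dt * first_col[((seq_len(L2) - j) %% L2) + 1L]
  sv <- svd(D)
  keep <- sv$d >= truncation * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Block-circulant SVD deconvolution of a tissue concentration curve
#'
#' Builds the `2L x 2L` zero-padded block-circulant convolution matrix of
#' the AIF, zeroes singular values below `truncation` times the largest, and
#' applies the pseudo-inverse to the zero-padded tissue curve. The circulant
#' formulation makes the recovered residue signal `k(t) = CBF * R(t)`
#' insensitive to bolus delay.
#'
#' @param C_tissue tissue concentration curve (vector length L, or matrix
#'   voxels x L).
#' @param aif AIF as returned by [select_aif()] (same grid as `C_tissue`).
#' @param dt sampling interval, seconds.
#' @param truncation singular-value cutoff as a fraction of the maximum
#'   (default 0.15).
#' @return residue signal(s) of length `2L` (vector or voxels x 2L matrix).
#' @export
bsvd_deconvolve <- function(C_tissue, aif, dt = aif$dt, truncation = 0.15) {
  av <- if (is.list(aif)) aif$values else aif
  vec <- is.null(dim(C_tissue))
  Cm <- if (vec) matrix(C_tissue, nrow = 1) else C_tissue
  if (ncol(Cm) != length(av))
    stop("tissue curve and AIF are on different time grids")
  Dinv <- bsvd_operator(av, dt, truncation)
  L <- length(av)
  cpad <- cbind(Cm, matrix(0, nrow(Cm), L))
  k <- cpad %*% t(Dinv)
  if (vec) k[1, ] else k
}

#' Perfusion parameters from a deconvolved residue signal
#'
#' CBF is the peak of `k(t)` (central volume scaling via the
#' hematocrit-density constant), CBV the area ratio of tissue curve to AIF,
#' MTT their ratio via the central volume theorem, and Tmax the time of the
#' residue peak on the deconvolution grid.
#'
#' @param k residue signal (vector of length 2L from [bsvd_deconvolve()]).
#' @param C_tissue tissue concentration curve (length L).
#' @param aif AIF list or vector (length L).
#' @param dt grid interval, seconds.
#' @param k_h hematocrit correction constant, default 0.73.
#' @param rho brain tissue density in g/mL, default 1.04.
#' @return list with `cbf` (mL/100g/min), `cbv` (mL/100g), `mtt` (s, `NA`
#'   where CBF is 0), `tmax` (s).
#' @export
perfusion_parameters <- function(k, C_tissue, aif, dt = 1,
                                 k_h = 0.73, rho = 1.04) {
  av <- if (is.list(aif)) aif$values else aif
  L <- length(av)
  kk <- k[seq_len(L)]
  pk <- max(kk)
  cbf <- (k_h / rho) * pk * 6000          # mL/g/s -> mL/100g/min
  tmax <- (which.max(kk) - 1) * dt
  num <- sum(C_tissue) * dt
  den <- sum(av) * dt
  if (num < 0) { warning("negative tissue integral clipped to 0"); num <- 0 }
  cbv <- (k_h / rho) * 100 * num / den    # mL/100g
  mtt <- if (cbf > 0) cbv / cbf * 60 else NA_real_
  list(cbf = max(cbf, 0), cbv = cbv, mtt = mtt, tmax = tmax)
}

#' Full perfusion analysis of one patient
#'
#' Runs the volume-wise chain: signal to concentration inside the brain
#' mask, cubic-spline resampling to the 1 s grid, AIF selection,
#' block-circulant SVD deconvolution (one operator per patient), and the
#' four parameter maps. A motion/slice-time correction hook
#' (`precorrect`) is applied to the 4D series first if supplied; synthetic
#' data is motion-free so the default is the identity.
#'
#' @param case a `patient_case`.
#' @param truncation singular-value truncation fraction, default 0.15.
#' @param baseline_window pre-bolus frame indices, default 1:3.
#' @param mode concentration conversion mode, see
#'   [signal_to_concentration()].
#' @param coefficients quadratic-mode coefficients.
#' @param aif_mode `"known"` (simulated AIF) or `"mask_mean"`.
#' @param arterial_mask logical mask for `"mask_mean"` AIF selection.
#' @param k_h,rho proportionality constants, see [perfusion_parameters()].
#' @param precorrect optional function applied to the 4D PWI array first.
#' @return list of 3D maps `cbf`, `cbv`, `mtt`, `tmax` (`NA` outside the
#'   brain mask) plus `n_undefined_mtt`, the count of voxels whose MTT is
#'   undefined because CBF was 0.
#' @export
compute_perfusion_maps <- function(case, truncation = 0.15,
                                   baseline_window = 1:3,
                                   mode = "linear", coefficients = NULL,
                                   aif_mode = c("known", "mask_mean"),
                                   arterial_mask = NULL,
                                   k_h = 0.73, rho = 1.04,
                                   precorrect = NULL) {
  aif_mode <- match.arg(aif_mode)
  pwi <- case$pwi
  if (!is.null(precorrect)) pwi <- precorrect(pwi)
  g <- dim(pwi)[1:3]
  nt <- dim(pwi)[4]
  b_lin <- which(case$brain_mask)
  S <- matrix(pwi, nrow = prod(g), ncol = nt)[b_lin, , drop = FALSE]
  C <- signal_to_concentration(S, baseline_window, TE = case$TE_s,
                               mode = mode, coefficients = coefficients)
  Ci <- interpolate_temporal(C, dt = case$TR_s, target_dt = 1)
  aif <- if (aif_mode == "known") select_aif(case, "known")
         else select_aif(case, "mask_mean", conc = Ci$values,
                         mask = arterial_mask[b_lin], dt = 1)
  L <- min(ncol(Ci$values), length(aif$values))
  Cv <- Ci$values[, seq_len(L), drop = FALSE]
  av <- aif$values[seq_len(L)]
  K <- bsvd_deconvolve(Cv, list(values = av, dt = 1), dt = 1, truncation)
  kk <- K[, seq_len(L), drop = FALSE]
  pk <- apply(kk, 1, max)
  tmax_v <- (max.col(kk, ties.method = "first") - 1) * 1
  cbf_v <- pmax((k_h / rho) * pk * 6000, 0)
  num <- pmax(rowSums(Cv) * 1, 0)
  cbv_v <- (k_h / rho) * 100 * num / (sum(av) * 1)
  mtt_v <- ifelse(cbf_v > 0, cbv_v / cbf_v * 60, NA_real_)
  maps <- list()
  for (nm in c("cbf", "cbv", "mtt", "tmax")) maps[[nm]] <- array(NA_real_, g)
  maps$cbf[b_lin] <- cbf_v
  maps$cbv[b_lin] <- cbv_v
  maps$mtt[b_lin] <- mtt_v
  maps$tmax[b_lin] <- tmax_v
  maps$n_undefined_mtt <- sum(is.na(mtt_v))
  maps
}
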