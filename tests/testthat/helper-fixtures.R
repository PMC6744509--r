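# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small, noise-free single patient on the default 24^3 grid.
fixture_case <- function(noise = 0, cohort = "NR", seed = 101) {
  key <- paste("case", noise, cohort, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    p <- cohort_params(n_per_cohort = c(IAR = 1L, IVR = 1L, NR = 1L),
                       noise_sd = noise)
    .fixture_env[[key]] <- generate_patient(p, cohort, seed = seed,
                                            id = paste0(cohort, "_01"))
  }
  .fixture_env[[key]]
}

# Tiny multi-patient preprocessed cohort for LOO-level tests.
fixture_pre <- function() {
  if (is.null(.fixture_env$pre)) {
    p <- cohort_params(n_per_cohort = c(IAR = 2L, IVR = 2L, NR = 3L),
                       grid_shape = c(20L, 20L, 10L), seed = 7L)
    cases <- generate_cohort(p)
    .fixture_env$pre <- lapply(cases, preprocess_case)
  }
  .fixture_env$pre
}

# Random blobby 3D mask: union of a few random boxes, for metric oracles.
random_mask <- function(dim, n_boxes = 3, p_empty = 0) {
  m <- array(FALSE, dim)
  if (runif(1) < p_empty) return(m)
  for (b in seq_len(n_boxes)) {
    lo <- sapply(dim, function(d) sample.int(d, 1))
    hi <- pmin(lo + sapply(dim, function(d) sample.int(max(d %/% 2, 1), 1)), dim)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}

# Feature table with the full schema but synthetic content (for classifier
# unit tests). `signal` shifts the feature means of label-1 rows.
toy_table <- function(n, seed = 1, signal = 0) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  mk <- function(mu = 0) rnorm(n) + signal * label * mu
  data.frame(
    patient_id = rep(c("A", "B"), each = ceiling(n / 2))[seq_len(n)],
    voxel_index = seq_len(n),
    adc = mk(-1), distance = mk(-1), tissue_prob = runif(n),
    region_id = factor(sample(1:9, n, replace = TRUE), levels = 1:9),
    cbv = mk(-1), mtt = mk(1), tmax = mk(1), cbf = mk(-1),
    nihss = rep(12, n), age = rep(70, n), sex = rep(1, n),
    onset_min = rep(120, n),
    label = label)
}

# Independent brute-force oracles (deliberately naive implementations).

brute_force_edt <- function(mask, spacing = c(1, 1, 1)) {
  g <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(Inf, g)
  for (x in seq_len(g[1])) for (y in seq_len(g[2])) for (z in seq_len(g[3])) {
    d2 <- (src[, 1] - x)^2 * spacing[1]^2 + (src[, 2] - y)^2 * spacing[2]^2 +
      (src[, 3] - z)^2 * spacing[3]^2
    out[x, y, z] <- sqrt(min(d2))
  }
  out
}

brute_force_confusion <- function(pred, truth, mask) {
  p <- pred[mask]; t <- truth[mask]
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(p)) {
    if (p[i] && t[i]) tp <- tp + 1
    else if (p[i] && !t[i]) fp <- fp + 1
    else if (!p[i] && t[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# All-pairs surface distances between border voxel centers.
brute_force_surface <- function(A, B, spacing = c(1, 1, 1)) {
  border <- function(m) {
    g <- dim(m)
    out <- array(FALSE, g)
    for (x in seq_len(g[1])) for (y in seq_len(g[2])) for (z in seq_len(g[3])) {
      if (!m[x, y, z]) next
      nb <- c(
        if (x > 1) m[x - 1, y, z] else FALSE, if (x < g[1]) m[x + 1, y, z] else FALSE,
        if (y > 1) m[x, y - 1, z] else FALSE, if (y < g[2]) m[x, y + 1, z] else FALSE,
        if (z > 1) m[x, y, z - 1] else FALSE, if (z < g[3]) m[x, y, z + 1] else FALSE)
      if (any(!nb) || x == 1 || x == g[1] || y == 1 || y == g[2] ||
          z == 1 || z == g[3]) out[x, y, z] <- TRUE
    }
    out
  }
  sa <- which(border(A), arr.ind = TRUE)
  sb <- which(border(B), arr.ind = TRUE)
  dmat <- matrix(0, nrow(sa), nrow(sb))
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb)))
    dmat[i, j] <- sqrt(sum(((sa[i, ] - sb[j, ]) * spacing)^2))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(msd = mean(c(mean(dab), mean(dba))), hd = max(max(dab), max(dba)))
}

# Time series of one voxel (linear index) from a 4D volume.
pwi_series <- function(pwi, vox) {
  g <- dim(pwi)
  pwi[vox + prod(g[1:3]) * (seq_len(g[4]) - 1)]
}
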