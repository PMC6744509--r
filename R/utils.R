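# Internal helpers: deterministic seed derivation, array utilities,
# input validation.

#' Derive a reproducible child seed from a master seed
#'
#' Stable arithmetic hash chaining the master seed with any number of
#' integer/character tags (patient index, fold, setting id, ...). Keeps the
#' result in 1..2^31-2 so it is always a valid `set.seed()` input. The
#' multiplier is small enough that all intermediate products stay below
#' 2^53, i.e. exact in double arithmetic.
#'
#' @param seed master seed (integer).
#' @param ... integer or character tags identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (t in as.numeric(tag)) {
      h <- (h * 69069 + t + 1) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr with a local RNG state seeded from `seed`; restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Logical 3D array from a vector + dim.
as_mask <- function(v, dim) {
  array(as.logical(v), dim = dim)
}

stopifnot_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  invisible(TRUE)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share the same voxel grid (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# Voxel volume in mL for a spacing in mm.
voxel_volume_ml <- function(spacing_mm) prod(spacing_mm) / 1000
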