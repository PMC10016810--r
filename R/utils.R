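#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state
# afterwards, so generators are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based voxel coordinates (n x 3 integer matrix) -> 1-based linear index
# into an array of dimension `dim`.
voxel_linear_index <- function(vox, dim) {
  stopifnot(ncol(vox) == 3L)
  1L + vox[, 1L] + dim[1L] * (vox[, 2L] + dim[2L] * vox[, 3L])
}

linear_index_voxel <- function(idx, dim) {
  idx0 <- idx - 1L
  x <- idx0 %% dim[1L]
  y <- (idx0 %/% dim[1L]) %% dim[2L]
  z <- idx0 %/% (dim[1L] * dim[2L])
  cbind(x, y, z)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}
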