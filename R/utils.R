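## Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gyromagnetic ratio of the proton in MHz/T
#' @keywords internal
GAMMA_MHZ_PER_T <- 42.577

stopIfNotFinite <- function(x, name) {
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a stage-specific seed from a base seed
#'
#' All randomness in a multi-stage run is funneled through one base seed and
#' fanned out per stage by hashing the stage name, so stages stay independent
#' and reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param seed base integer seed
#' @param stage stage name (character)
#' @return an integer seed in `[0, 2^31 - 1]`
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483647)
}

#' Voxel-count reduction factor between two grid resolutions
#'
#' The multiresolution pipeline gains speed proportionally to the number of
#' original voxels pooled into one coarse voxel. For a typical clinical
#' acquisition at ~0.6 x 0.6 x 1 mm^3 pooled to 6 x 6 x 6 mm^3 this factor is
#' 600.
#'
#' @param fine voxel dimensions of the acquired grid (mm, any length)
#' @param coarse voxel dimensions of the coarse grid (same length)
#' @return ratio of coarse voxel volume to fine voxel volume
#' @examples
#' voxelReductionFactor(c(0.6, 0.6, 1), c(6, 6, 6))
#' @export
voxelReductionFactor <- function(fine, coarse) {
  stopifnot(length(fine) == length(coarse), all(fine > 0), all(coarse > 0))
  prod(coarse) / prod(fine)
}

## Evaluate all monomials x^i * y^j with i + j <= order on a grid in [-1, 1]^2
## and combine them with the given coefficients.
polyField <- function(shape, coef, order) {
  y <- seq(-1, 1, length.out = shape[1])
  x <- seq(-1, 1, length.out = shape[2])
  out <- matrix(0, shape[1], shape[2])
  k <- 0L
  for (i in 0:order) {
    for (j in 0:(order - i)) {
      k <- k + 1L
      out <- out + coef[k] * outer(y^i, x^j)
    }
  }
  out
}

nPolyTerms <- function(order) (order + 1L) * (order + 2L) / 2L

## Run `expr` with a deterministic RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
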