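## Multicoil simulation and SVD coil compression. Sensitivities are smooth
## random complex fields; compression projects both echoes with the SAME
## leading-singular-vector matrix (computed from the joint coil-by-pixel
## matrix of both echoes) so the inter-echo phase is preserved.

#' Simulate a multicoil dual-echo acquisition
#'
#' Each coil sees the single-coil forward simulation multiplied by its own
#' smooth complex sensitivity, plus independent complex Gaussian noise.
#'
#' @param truth a [PhantomTruth-class]
#' @param params an [AcquisitionParams-class]
#' @param nCoils number of receive coils (>= 1)
#' @param noiseSigma per-component noise standard deviation (per coil)
#' @param seed integer seed (sensitivities and noise)
#' @param unitSensitivities force all sensitivities to 1 (testing hook)
#' @return list with `coils` (list of [DualEchoImage-class], one per coil)
#'   and `sensitivities` (list of complex matrices)
#' @export
simulateMulticoil <- function(truth, params = acquisitionParams(),
                              nCoils = 6L, noiseSigma = 0, seed = 1L,
                              unitSensitivities = FALSE) {
  if (nCoils < 1L) stop("'nCoils' must be >= 1", call. = FALSE)
  shape <- dim(truth@water)
  base <- forwardSimulate(
    truth@water, truth@fat, truth@b0Hz, truth@phi0, params,
    noiseSigma = 0
  )
  withSeed(stageSeed(seed, "coils"), {
    sens <- lapply(seq_len(nCoils), function(k) {
      if (unitSensitivities) {
        return(matrix(1 + 0i, shape[1], shape[2]))
      }
      re <- polyField(shape, rnorm(nPolyTerms(2)), 2)
      im <- polyField(shape, rnorm(nPolyTerms(2)), 2)
      s <- complex(real = 1 + 0.5 * re / max(abs(re)),
                   imaginary = 0.5 * im / max(abs(im)))
      matrix(s, shape[1], shape[2])
    })
    coils <- lapply(seq_len(nCoils), function(k) {
      s1 <- sens[[k]] * base@s1
      s2 <- sens[[k]] * base@s2
      if (noiseSigma > 0) {
        n <- length(s1)
        s1 <- s1 + complex(
          real = rnorm(n, sd = noiseSigma),
          imaginary = rnorm(n, sd = noiseSigma)
        )
        s2 <- s2 + complex(
          real = rnorm(n, sd = noiseSigma),
          imaginary = rnorm(n, sd = noiseSigma)
        )
      }
      dualEchoImage(matrix(s1, shape[1], shape[2]),
        matrix(s2, shape[1], shape[2]), params)
    })
    list(coils = coils, sensitivities = sens)
  })
}

#' SVD coil compression to virtual channels
#'
#' Stacks both echoes of all coils into one coil-by-pixel matrix, takes its
#' singular value decomposition, and projects BOTH echoes with the same
#' leading left-singular-vector matrix. The retained signal energy fraction
#' (sum of kept squared singular values over the total) is reported.
#'
#' @param stack list of [DualEchoImage-class] objects, one per coil
#' @param nVirtual number of virtual channels (1 <= nVirtual <= nCoils)
#' @return list with `coils` (list of `nVirtual` [DualEchoImage-class]),
#'   `energyFraction`, and `projection` (the nVirtual x nCoils matrix)
#' @export
compressCoils <- function(stack, nVirtual) {
  nCoils <- length(stack)
  if (nVirtual < 1L) stop("'nVirtual' must be >= 1", call. = FALSE)
  if (nVirtual > nCoils) {
    stop("'nVirtual' cannot exceed the number of coils", call. = FALSE)
  }
  shape <- dim(stack[[1L]]@s1)
  m <- do.call(rbind, lapply(stack, function(im) {
    c(as.vector(im@s1), as.vector(im@s2))
  }))
  sv <- svd(m, nu = nVirtual, nv = 0)
  proj <- Conj(t(sv$u[, seq_len(nVirtual), drop = FALSE]))
  comp <- proj %*% m
  npix <- prod(shape)
  coils <- lapply(seq_len(nVirtual), function(k) {
    dualEchoImage(
      matrix(comp[k, seq_len(npix)], shape[1], shape[2]),
      matrix(comp[k, npix + seq_len(npix)], shape[1], shape[2]),
      stack[[1L]]@params
    )
  })
  list(
    coils = coils,
    energyFraction = sum(sv$d[seq_len(nVirtual)]^2) / sum(sv$d^2),
    projection = proj
  )
}
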