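## Multiresolution helpers: block-mean downsampling of complex images and
## bilinear upsampling of unit phasor maps. Both are deliberately explicit
## (rather than delegating to a generic image-resize routine) so the
## coordinate conventions are pinned: downsampling averages non-overlapping
## factor x factor blocks (trailing partial blocks averaged over their actual
## size), and upsampling aligns pixel centers, interpolating real and
## imaginary parts before renormalizing to unit modulus.

#' Block-mean downsampling of a complex image
#'
#' @param img complex (or numeric) matrix
#' @param factor integer block size (>= 1)
#' @return the downsampled matrix, `ceiling(dim / factor)` in shape
#' @export
downsampleComplex <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1", call. = FALSE)
  if (factor == 1L) return(img)
  d <- dim(img)
  if (factor > max(d)) {
    stop("'factor' larger than the image", call. = FALSE)
  }
  gr <- ((seq_len(d[1]) - 1L) %/% factor) + 1L
  gc <- ((seq_len(d[2]) - 1L) %/% factor) + 1L
  ## block sums via aggregation matrices (complex-safe), then divide by the
  ## actual block sizes so trailing partial blocks average correctly
  aggMat <- function(groups) {
    ng <- max(groups)
    m <- matrix(0, ng, length(groups))
    m[cbind(groups, seq_along(groups))] <- 1
    m
  }
  br <- aggMat(gr)
  bc <- aggMat(gc)
  sums <- br %*% img %*% t(bc)
  counts <- tabulate(gr) %o% tabulate(gc)
  sums / counts
}

#' Bilinear upsampling of a unit phasor map
#'
#' Interpolates real and imaginary parts with pixel-center alignment, then
#' renormalizes to unit modulus; interpolants of vanishing magnitude are
#' replaced by the nearest source pixel's value.
#'
#' @param phasor complex matrix of unit-modulus values
#' @param targetShape integer vector `c(nrow, ncol)`, at least the source
#'   shape
#' @return complex matrix of shape `targetShape` with unit modulus everywhere
#' @export
upsamplePhasor <- function(phasor, targetShape) {
  d <- dim(phasor)
  targetShape <- as.integer(targetShape)
  if (any(targetShape < d)) {
    stop("'targetShape' must be at least the source shape", call. = FALSE)
  }
  if (identical(targetShape, d)) return(phasor)
  ## 1-based source coordinate of each target pixel center
  fy <- d[1] / targetShape[1]
  fx <- d[2] / targetShape[2]
  sy <- (seq_len(targetShape[1]) - 0.5) * fy + 0.5
  sx <- (seq_len(targetShape[2]) - 0.5) * fx + 0.5
  interp1 <- function(coord, n) {
    c0 <- pmin(pmax(floor(coord), 1), n)
    c1 <- pmin(c0 + 1, n)
    t <- pmin(pmax(coord - c0, 0), 1)
    list(lo = as.integer(c0), hi = as.integer(c1), t = t)
  }
  iy <- interp1(sy, d[1])
  ix <- interp1(sx, d[2])
  re <- Re(phasor)
  im <- Im(phasor)
  bil <- function(m) {
    a <- m[iy$lo, ix$lo, drop = FALSE] * ((1 - iy$t) %o% (1 - ix$t)) +
      m[iy$hi, ix$lo, drop = FALSE] * (iy$t %o% (1 - ix$t)) +
      m[iy$lo, ix$hi, drop = FALSE] * ((1 - iy$t) %o% ix$t) +
      m[iy$hi, ix$hi, drop = FALSE] * (iy$t %o% ix$t)
    a
  }
  out <- complex(real = bil(re), imaginary = bil(im))
  out <- matrix(out, targetShape[1], targetShape[2])
  m <- Mod(out)
  tiny <- m < 1e-12
  if (any(tiny)) {
    ## fall back to nearest-neighbor where opposed phasors cancelled
    ny <- as.integer(pmin(pmax(round(sy), 1), d[1]))
    nx <- as.integer(pmin(pmax(round(sx), 1), d[2]))
    nn <- phasor[ny, nx, drop = FALSE]
    out[tiny] <- nn[tiny]
    m[tiny] <- Mod(out[tiny])
  }
  out / m
}
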