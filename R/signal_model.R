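## Dual-echo chemical-shift signal model.
##
## Per pixel the two echoes are
##   S1 = (W + C1 F) exp(i phi1),  S2 = (W + C2 F) exp(i phi2),
## with W, F >= 0 the water/fat amplitudes, Ck = exp(i 2 pi df TEk) the fat
## dephasing factor at echo time TEk (df the fat frequency offset in Hz), and
## phik = phi0 + 2 pi b0 TEk the receive plus B0-induced phase. Magnitudes
## alone determine (W, F) up to a swap; each of the two amplitude orderings
## implies its own inter-echo phasor candidate, and choosing between them is
## the field-map estimation problem handled by the selector module.

#' Construct acquisition parameters
#'
#' @param te1,te2 echo times in ms (in-phase, out-of-phase)
#' @param fieldStrength main field in Tesla
#' @param fatShiftPpm signed fat-water chemical shift in ppm (default -3.5,
#'   single-resonance fat model)
#' @param pixelSpacing pixel spacing `c(dy, dx)` in mm
#' @return an [AcquisitionParams-class] object
#' @examples
#' acquisitionParams(te1 = 2.23, te2 = 1.31, fieldStrength = 3)
#' @export
acquisitionParams <- function(te1 = 2.23, te2 = 1.31, fieldStrength = 3.0,
                              fatShiftPpm = -3.5, pixelSpacing = c(1, 1)) {
  new("AcquisitionParams",
    te1 = te1, te2 = te2, fieldStrength = fieldStrength,
    fatShiftPpm = fatShiftPpm, pixelSpacing = as.numeric(pixelSpacing)
  )
}

#' Fat frequency offset in Hz implied by acquisition parameters
#'
#' @param params an [AcquisitionParams-class] object
#' @return signed offset in Hz (`fatShiftPpm * 42.577 MHz/T * fieldStrength`)
#' @export
fatFrequencyOffset <- function(params) {
  params@fatShiftPpm * GAMMA_MHZ_PER_T * params@fieldStrength
}

#' Fat dephasing factor at a given echo time
#'
#' @param teMs echo time in ms (>= 0)
#' @param deltaFHz fat frequency offset in Hz
#' @return the unit complex number `exp(i 2 pi deltaFHz teMs 1e-3)`
#' @examples
#' dephasingFactor(0, -447)        # 1
#' dephasingFactor(2, -250)        # -1 (half a cycle)
#' @export
dephasingFactor <- function(teMs, deltaFHz) {
  if (length(teMs) != 1L || !is.finite(teMs) || teMs < 0) {
    stop("'teMs' must be a single finite non-negative number", call. = FALSE)
  }
  if (length(deltaFHz) != 1L || !is.finite(deltaFHz)) {
    stop("'deltaFHz' must be a single finite number", call. = FALSE)
  }
  exp(1i * 2 * pi * deltaFHz * teMs * 1e-3)
}

#' Both dephasing factors for an acquisition
#'
#' @param params an [AcquisitionParams-class] object
#' @return complex vector `c(C1, C2)`
#' @export
dephasingFactors <- function(params) {
  df <- fatFrequencyOffset(params)
  c(dephasingFactor(params@te1, df), dephasingFactor(params@te2, df))
}

#' Construct a dual-echo image
#'
#' @param s1,s2 complex matrices of identical shape
#' @param params an [AcquisitionParams-class] object
#' @return a [DualEchoImage-class]
#' @export
dualEchoImage <- function(s1, s2, params = acquisitionParams()) {
  storage.mode(s1) <- "complex"
  storage.mode(s2) <- "complex"
  new("DualEchoImage", s1 = s1, s2 = s2, params = params)
}

#' Simulate a dual-echo acquisition from ground-truth maps
#'
#' Evaluates the signal model per pixel and optionally adds i.i.d. complex
#' Gaussian noise (standard deviation `noiseSigma` per real/imaginary
#' component), seeded for reproducibility.
#'
#' @param water,fat non-negative amplitude maps (same shape)
#' @param b0Hz B0 field map in Hz
#' @param phi0 receive phase map in radians
#' @param params an [AcquisitionParams-class]
#' @param noiseSigma noise standard deviation per component (>= 0)
#' @param seed integer seed used when `noiseSigma > 0`
#' @return a [DualEchoImage-class]
#' @export
forwardSimulate <- function(water, fat, b0Hz = 0 * water, phi0 = 0 * water,
                            params = acquisitionParams(), noiseSigma = 0,
                            seed = 1L) {
  d <- dim(water)
  for (nm in c("fat", "b0Hz", "phi0")) {
    if (!identical(dim(get(nm)), d)) {
      stop(sprintf("'%s' shape differs from 'water'", nm), call. = FALSE)
    }
  }
  if (any(water < 0) || any(fat < 0)) {
    stop("'water' and 'fat' must be non-negative", call. = FALSE)
  }
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0", call. = FALSE)
  cc <- dephasingFactors(params)
  tes <- c(params@te1, params@te2)
  sig <- vector("list", 2L)
  for (k in 1:2) {
    phase <- phi0 + 2 * pi * b0Hz * tes[k] * 1e-3
    sig[[k]] <- (water + cc[k] * fat) * exp(1i * phase)
  }
  if (noiseSigma > 0) {
    withSeed(seed, {
      for (k in 1:2) {
        n <- matrix(
          complex(
            real = rnorm(length(water), sd = noiseSigma),
            imaginary = rnorm(length(water), sd = noiseSigma)
          ),
          d[1], d[2]
        )
        sig[[k]] <- sig[[k]] + n
      }
    })
  }
  dualEchoImage(sig[[1]], sig[[2]], params)
}

#' Per-pixel candidate water/fat amplitudes from echo magnitudes
#'
#' Solves `|W + C1 F|^2 = |S1|^2`, `|W + C2 F|^2 = |S2|^2` for non-negative
#' (W, F): with p = W F = (|S1|^2 - |S2|^2) / (2 (Re C1 - Re C2)) and
#' q = W^2 + F^2 = |S1|^2 - 2 p Re C1, the amplitudes are the roots of
#' t^2 - s t + p with s = sqrt(max(q + 2 p, 0)). Negative products or
#' discriminants (noise floor) are clamped to zero and flagged in the
#' degenerate mask. Candidate 1 assigns the larger root to water; candidate 2
#' is the swap. Phasor slots are filled by [phasorCandidates()].
#'
#' @param s1Mag,s2Mag non-negative magnitude maps
#' @param c1,c2 unit complex dephasing factors with `Re(c1) != Re(c2)`
#' @return a [PhasorCandidates-class] with amplitudes and trivial (unit)
#'   phasors
#' @export
amplitudeCandidates <- function(s1Mag, s2Mag, c1, c2) {
  if (!identical(dim(s1Mag), dim(s2Mag))) {
    stop("'s1Mag' and 's2Mag' must have identical shape", call. = FALSE)
  }
  if (any(s1Mag < 0) || any(s2Mag < 0)) {
    stop("magnitudes must be non-negative", call. = FALSE)
  }
  if (abs(Re(c1) - Re(c2)) < 1e-12) {
    stop(
      "Re(c1) == Re(c2): echo times do not separate water and fat ",
      "(ill-posed acquisition)",
      call. = FALSE
    )
  }
  a1 <- s1Mag^2
  a2 <- s2Mag^2
  p <- (a1 - a2) / (2 * (Re(c1) - Re(c2)))
  q <- a1 - 2 * p * Re(c1)
  sum2 <- q + 2 * p # (W + F)^2
  disc <- q - 2 * p # (W - F)^2
  degenerate <- (p < 0) | (sum2 < 0) | (disc < 0) | (a1 == 0 & a2 == 0)
  s <- sqrt(pmax(sum2, 0))
  dif <- sqrt(pmax(disc, 0))
  w1 <- (s + dif) / 2
  f1 <- pmax((s - dif) / 2, 0)
  dm <- dim(s1Mag)
  one <- matrix(1 + 0i, dm[1], dm[2])
  new("PhasorCandidates",
    w1 = w1, f1 = f1, w2 = f1, f2 = w1, p1 = one, p2 = one,
    degenerate = matrix(degenerate, dm[1], dm[2])
  )
}

#' Candidate inter-echo phasors for both amplitude candidates
#'
#' For candidate k the field-map phasor is
#' `Pk = conj(S1) S2 / ((Wk + conj(C1) Fk) (Wk + C2 Fk))`, normalized to unit
#' modulus. On degenerate pixels (and wherever the denominator vanishes) the
#' phasor is set to 1 and the pixel flagged.
#'
#' @param img a [DualEchoImage-class]
#' @param cands a [PhasorCandidates-class] from [amplitudeCandidates()]
#' @param c1,c2 dephasing factors used to build `cands`
#' @return `cands` with `p1`, `p2` and an updated degenerate mask
#' @export
phasorCandidates <- function(img, cands, c1, c2) {
  num <- Conj(img@s1) * img@s2
  degenerate <- cands@degenerate
  ps <- vector("list", 2L)
  for (k in 1:2) {
    w <- if (k == 1L) cands@w1 else cands@w2
    f <- if (k == 1L) cands@f1 else cands@f2
    den <- (w + Conj(c1) * f) * (w + c2 * f)
    p <- num / den
    m <- Mod(p)
    bad <- !is.finite(m) | m == 0 | Mod(den) < 1e-300
    p[bad] <- 1 + 0i
    m[bad] <- 1
    degenerate <- degenerate | bad
    ps[[k]] <- p / m
  }
  ps[[1]][cands@degenerate] <- 1 + 0i
  ps[[2]][cands@degenerate] <- 1 + 0i
  new("PhasorCandidates",
    w1 = cands@w1, f1 = cands@f1, w2 = cands@w2, f2 = cands@f2,
    p1 = ps[[1]], p2 = ps[[2]], degenerate = degenerate
  )
}

#' Water/fat amplitudes given a resolved field-map phasor
#'
#' Demodulates the second echo by the conjugate phasor and solves the 2x2
#' linear system `[1 C1; 1 C2] [u; v] = [S1; S2 conj(P)]` per pixel. Water
#' and fat are returned as magnitudes `|u|`, `|v|` (clinical display
#' convention); the residual measures how far (u, v) deviate from sharing a
#' common phase, and is zero for noiseless data with the exact phasor.
#'
#' @param img a [DualEchoImage-class]
#' @param phasor unit-modulus complex matrix (the selected field phasor)
#' @param c1,c2 dephasing factors; must differ
#' @return list with matrices `water`, `fat`, `residual`
#' @export
amplitudesFromPhasor <- function(img, phasor, c1, c2) {
  if (abs(c1 - c2) < 1e-12) {
    stop("c1 == c2: singular amplitude system", call. = FALSE)
  }
  if (!identical(dim(phasor), dim(img@s1))) {
    stop("'phasor' shape differs from the image", call. = FALSE)
  }
  s1 <- img@s1
  s2d <- img@s2 * Conj(phasor)
  u <- (c2 * s1 - c1 * s2d) / (c2 - c1)
  v <- (s2d - s1) / (c2 - c1)
  theta <- Arg(u + v)
  common <- exp(1i * theta)
  residual <- Mod(u - Mod(u) * common) + Mod(v - Mod(v) * common)
  list(water = Mod(u), fat = Mod(v), residual = residual)
}
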