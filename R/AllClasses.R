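## Central S4 containers. All images are 2D slices stored as base matrices
## (complex for signals/phasors, double for amplitude and field maps); volumes
## are handled as loops over slices by callers.

#' Acquisition parameters for a dual-echo scan
#'
#' Echo times are in milliseconds throughout the user-facing interface and are
#' converted to seconds only inside formulas. The fat chemical shift is a
#' single-resonance model, signed in ppm (fat resonates below water, so the
#' default is negative); the fat frequency offset in Hz is always derived as
#' `fatShiftPpm * 42.577 * fieldStrength` rather than stored.
#'
#' @slot te1 echo time of the in-phase echo (ms)
#' @slot te2 echo time of the out-of-phase echo (ms)
#' @slot fieldStrength main field strength (Tesla)
#' @slot fatShiftPpm signed fat-water chemical shift (ppm)
#' @slot pixelSpacing pixel spacing `c(dy, dx)` in mm
#' @export
setClass("AcquisitionParams",
  representation(
    te1 = "numeric", te2 = "numeric", fieldStrength = "numeric",
    fatShiftPpm = "numeric", pixelSpacing = "numeric"
  ),
  prototype(
    te1 = 2.23, te2 = 1.31, fieldStrength = 3.0,
    fatShiftPpm = -3.5, pixelSpacing = c(1, 1)
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  for (f in c("te1", "te2", "fieldStrength", "fatShiftPpm")) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", f))
    }
  }
  if (length(msg) == 0L) {
    if (object@te1 <= 0) msg <- c(msg, "'te1' must be > 0")
    if (object@te2 <= 0) msg <- c(msg, "'te2' must be > 0")
    if (object@te1 == object@te2) msg <- c(msg, "'te1' and 'te2' must differ")
    if (object@fieldStrength <= 0) {
      msg <- c(msg, "'fieldStrength' must be > 0")
    }
  }
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0)) {
    msg <- c(msg, "'pixelSpacing' must be two positive numbers")
  }
  if (length(msg)) msg else TRUE
})

#' Paired complex dual-echo images
#'
#' @slot s1 complex matrix, in-phase signal
#' @slot s2 complex matrix, out-of-phase signal (same shape as `s1`)
#' @slot params an [AcquisitionParams-class] object
#' @export
setClass("DualEchoImage",
  representation(s1 = "matrix", s2 = "matrix", params = "AcquisitionParams")
)

setValidity("DualEchoImage", function(object) {
  msg <- character()
  if (!is.complex(object@s1) || !is.complex(object@s2)) {
    msg <- c(msg, "'s1' and 's2' must be complex matrices")
  }
  if (!identical(dim(object@s1), dim(object@s2))) {
    msg <- c(msg, "'s1' and 's2' must have identical shape")
  }
  if (length(msg) == 0L &&
      (any(!is.finite(object@s1)) || any(!is.finite(object@s2)))) {
    msg <- c(msg, "signal values must all be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Per-pixel candidate amplitude pairs and phasors
#'
#' Candidate 2 is the amplitude swap of candidate 1 (`w2 == f1`, `f2 == w1`);
#' candidate 1 assigns the larger amplitude to water. The ordering is
#' arbitrary bookkeeping: the selection stage decides the output.
#'
#' @slot w1,f1 candidate-1 water/fat amplitudes (non-negative matrices)
#' @slot w2,f2 candidate-2 amplitudes
#' @slot p1,p2 candidate unit phasors (complex matrices; 1 on degenerate pixels)
#' @slot degenerate logical matrix marking pixels where candidates coincide,
#'   amplitudes were clamped, or the phasor denominator vanished
#' @export
setClass("PhasorCandidates",
  representation(
    w1 = "matrix", f1 = "matrix", w2 = "matrix", f2 = "matrix",
    p1 = "matrix", p2 = "matrix", degenerate = "matrix"
  )
)

setValidity("PhasorCandidates", function(object) {
  msg <- character()
  d <- dim(object@w1)
  for (f in c("f1", "w2", "f2", "p1", "p2", "degenerate")) {
    if (!identical(dim(slot(object, f)), d)) {
      msg <- c(msg, sprintf("'%s' shape differs from 'w1'", f))
    }
  }
  for (f in c("w1", "f1", "w2", "f2")) {
    if (any(slot(object, f) < 0)) {
      msg <- c(msg, sprintf("'%s' must be non-negative", f))
    }
  }
  if (length(msg) == 0L) {
    if (max(abs(Mod(object@p1) - 1)) > 1e-9 ||
        max(abs(Mod(object@p2) - 1)) > 1e-9) {
      msg <- c(msg, "candidate phasors must have unit modulus")
    }
    if (!isTRUE(all.equal(object@w2, object@f1, tolerance = 1e-12)) ||
        !isTRUE(all.equal(object@f2, object@w1, tolerance = 1e-12))) {
      msg <- c(msg, "candidate 2 must be the amplitude swap of candidate 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Neighborhood specification for the smoothness penalty graph
#'
#' @slot offsets integer matrix with columns `dr`, `dc`; `(0, 0)` excluded
#' @slot metric distance function identifier (only `"euclidean"`)
#' @export
setClass("NeighborSpec",
  representation(offsets = "matrix", metric = "character"),
  prototype(metric = "euclidean")
)

setValidity("NeighborSpec", function(object) {
  msg <- character()
  o <- object@offsets
  if (ncol(o) != 2L || nrow(o) < 1L) {
    msg <- c(msg, "'offsets' must be a non-empty two-column matrix")
  } else {
    if (any(o[, 1] == 0 & o[, 2] == 0)) {
      msg <- c(msg, "offset (0,0) is not allowed")
    }
    if (anyDuplicated(paste(o[, 1], o[, 2]))) {
      msg <- c(msg, "duplicate offsets")
    }
  }
  if (!identical(object@metric, "euclidean")) {
    msg <- c(msg, "only the \"euclidean\" metric is supported")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse pairwise penalty graph for phasor selection
#'
#' Stores, for every ordered pixel pair (r, s) with s in the neighbor set of
#' r, the 2x2 block of penalties between candidate i at r and candidate j at
#' s. Entries are kept as four parallel columns of a matrix (`v11`, `v12`,
#' `v21`, `v22`) alongside integer pixel indices `r` and `s` (column-major
#' linear indices into the image).
#'
#' @slot shape image dimensions `c(nrow, ncol)`
#' @slot r,s integer vectors of ordered pair endpoints
#' @slot blocks numeric matrix with columns v11, v12, v21, v22 (non-negative)
#' @slot weights per-pair magnitude/distance weights `min(|S1|)/d` (may be
#'   empty for hand-built graphs; the solver then falls back to a scale
#'   derived from the blocks)
#' @slot offsets the neighbor offsets the graph was built with
#' @export
setClass("PenaltyGraph",
  representation(
    shape = "integer", r = "integer", s = "integer",
    blocks = "matrix", weights = "numeric", offsets = "matrix"
  ),
  prototype(weights = numeric())
)

setValidity("PenaltyGraph", function(object) {
  msg <- character()
  n <- length(object@r)
  if (length(object@s) != n || nrow(object@blocks) != n) {
    msg <- c(msg, "'r', 's' and 'blocks' must have matching lengths")
  }
  if (ncol(object@blocks) != 4L) {
    msg <- c(msg, "'blocks' must have four columns")
  }
  if (length(object@weights) && length(object@weights) != n) {
    msg <- c(msg, "'weights' must be empty or one value per pair")
  }
  if (n > 0 && any(object@blocks < 0)) {
    msg <- c(msg, "penalty entries must be non-negative")
  }
  if (n > 0) {
    np <- prod(object@shape)
    if (min(object@r, object@s) < 1L || max(object@r, object@s) > np) {
      msg <- c(msg, "pixel indices out of range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of solving the phasor-selection problem
#'
#' @slot labels integer matrix of per-pixel labels in `{1, 2}`
#' @slot energy the selection energy `f(x)` of `labels` on the graph
#' @slot converged logical
#' @slot iterations total iteration count (relaxed + discrete sweeps)
#' @slot history energies of accepted (monotone) iterates
#' @export
setClass("SelectionMap",
  representation(
    labels = "matrix", energy = "numeric", converged = "logical",
    iterations = "integer", history = "numeric"
  )
)

setValidity("SelectionMap", function(object) {
  msg <- character()
  if (!all(object@labels %in% c(1L, 2L))) {
    msg <- c(msg, "labels must be 1 or 2")
  }
  if (length(object@energy) != 1L || object@energy < -1e-9) {
    msg <- c(msg, "'energy' must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' Separated water/fat maps with provenance
#'
#' @slot water,fat non-negative amplitude maps
#' @slot phasor selected unit phasor map (complex; `NA` for network output)
#' @slot selection integer label map in `{1, 2}` (0 where not applicable)
#' @slot meta list of options and provenance
#' @export
setClass("WaterFatResult",
  representation(
    water = "matrix", fat = "matrix", phasor = "matrix",
    selection = "matrix", meta = "list"
  )
)

setValidity("WaterFatResult", function(object) {
  msg <- character()
  if (any(object@water < 0) || any(object@fat < 0)) {
    msg <- c(msg, "'water' and 'fat' must be non-negative")
  }
  if (!identical(dim(object@water), dim(object@fat))) {
    msg <- c(msg, "'water' and 'fat' must have identical shape")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth synthetic phantom
#'
#' @slot water,fat true amplitude maps (arbitrary units, >= 0)
#' @slot b0Hz B0 field map in Hz
#' @slot phi0 receive phase map in radians
#' @slot tissueMask integer labels: 0 background, 1 water-dominant tissue,
#'   2 fat rim, 3 mixed marrow
#' @slot spec the generating parameters, including the seed
#' @export
setClass("PhantomTruth",
  representation(
    water = "matrix", fat = "matrix", b0Hz = "matrix",
    phi0 = "matrix", tissueMask = "matrix", spec = "list"
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  d <- dim(object@water)
  for (f in c("fat", "b0Hz", "phi0", "tissueMask")) {
    if (!identical(dim(slot(object, f)), d)) {
      msg <- c(msg, sprintf("'%s' shape differs from 'water'", f))
    }
  }
  if (any(object@water < 0) || any(object@fat < 0)) {
    msg <- c(msg, "'water' and 'fat' must be non-negative")
  }
  if (length(msg) == 0L) {
    bg <- object@tissueMask == 0L
    if (any(object@water[bg] != 0) || any(object@fat[bg] != 0)) {
      msg <- c(msg, "background pixels must have zero water and fat")
    }
    if (any(!is.finite(object@b0Hz))) msg <- c(msg, "'b0Hz' must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Image fidelity metrics for a predicted/reference pair
#'
#' @slot corr Pearson correlation over all evaluated pixels
#' @slot l1 mean absolute error after normalization
#' @slot ssim mean local structural similarity
#' @slot psnr peak signal-to-noise ratio in dB (capped at 99)
#' @slot nPixels number of pixels evaluated
#' @slot normalization record of the scaling applied to both images
#' @export
setClass("MetricsRecord",
  representation(
    corr = "numeric", l1 = "numeric", ssim = "numeric", psnr = "numeric",
    nPixels = "integer", normalization = "list"
  )
)

setValidity("MetricsRecord", function(object) {
  msg <- character()
  if (is.finite(object@corr) && abs(object@corr) > 1 + 1e-12) {
    msg <- c(msg, "'corr' must lie in [-1, 1]")
  }
  if (object@l1 < 0) msg <- c(msg, "'l1' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A trained (or freshly initialized) separation network
#'
#' @slot config network architecture configuration (see [networkConfig()])
#' @slot params named list of layer parameter arrays
#' @slot norm input/output normalization record fitted on training data
#' @slot history training history (per-epoch train/val loss), may be empty
#' @export
setClass("DixonNet",
  representation(
    config = "list", params = "list", norm = "list", history = "list"
  )
)
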