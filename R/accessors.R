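#' @describeIn DualEchoImage-class in-phase complex image
#' @param x object
#' @export
setMethod("s1", "DualEchoImage", function(x) x@s1)

#' @describeIn DualEchoImage-class out-of-phase complex image
#' @export
setMethod("s2", "DualEchoImage", function(x) x@s2)

#' @describeIn DualEchoImage-class acquisition parameters
#' @export
setMethod("acqParams", "DualEchoImage", function(x) x@params)

#' @describeIn WaterFatResult-class water amplitude map
#' @param x object
#' @export
setMethod("water", "WaterFatResult", function(x) x@water)

#' @describeIn WaterFatResult-class fat amplitude map
#' @export
setMethod("fat", "WaterFatResult", function(x) x@fat)

#' @describeIn WaterFatResult-class selected unit phasor map
#' @export
setMethod("phasor", "WaterFatResult", function(x) x@phasor)

#' @describeIn WaterFatResult-class per-pixel candidate label map
#' @export
setMethod("selection", "WaterFatResult", function(x) x@selection)

#' @describeIn PhantomTruth-class true water map
#' @param x object
#' @export
setMethod("water", "PhantomTruth", function(x) x@water)

#' @describeIn PhantomTruth-class true fat map
#' @export
setMethod("fat", "PhantomTruth", function(x) x@fat)

#' @describeIn PhantomTruth-class B0 field map (Hz)
#' @export
setMethod("b0Hz", "PhantomTruth", function(x) x@b0Hz)

#' @describeIn PhantomTruth-class tissue label map
#' @export
setMethod("tissueMask", "PhantomTruth", function(x) x@tissueMask)

#' @describeIn PhasorCandidates-class degenerate-pixel mask
#' @param x object
#' @export
setMethod("degenerateMask", "PhasorCandidates", function(x) x@degenerate)

#' @export
setMethod("dim", "DualEchoImage", function(x) dim(x@s1))

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: TE1=%.3g ms, TE2=%.3g ms, B0=%.3g T, fat shift=%.3g ppm\n",
    object@te1, object@te2, object@fieldStrength, object@fatShiftPpm
  ))
  cat(sprintf(
    "  fat frequency offset: %.1f Hz; pixel spacing %.3g x %.3g mm\n",
    fatFrequencyOffset(object), object@pixelSpacing[1], object@pixelSpacing[2]
  ))
})

setMethod("show", "DualEchoImage", function(object) {
  d <- dim(object@s1)
  cat(sprintf("DualEchoImage: %d x %d complex dual-echo slice\n", d[1], d[2]))
  show(object@params)
})

setMethod("show", "PhasorCandidates", function(object) {
  d <- dim(object@w1)
  cat(sprintf(
    "PhasorCandidates: %d x %d, %d degenerate pixel(s)\n",
    d[1], d[2], sum(object@degenerate)
  ))
})

setMethod("show", "PenaltyGraph", function(object) {
  cat(sprintf(
    "PenaltyGraph: %d x %d image, %d ordered pairs, %d neighbor offsets\n",
    object@shape[1], object@shape[2], length(object@r), nrow(object@offsets)
  ))
})

setMethod("show", "SelectionMap", function(object) {
  cat(sprintf(
    "SelectionMap: %d x %d, energy %.6g, %s after %d iteration(s)\n",
    nrow(object@labels), ncol(object@labels), object@energy,
    if (object@converged) "converged" else "not converged", object@iterations
  ))
})

setMethod("show", "WaterFatResult", function(object) {
  d <- dim(object@water)
  cat(sprintf("WaterFatResult: %d x %d water/fat maps\n", d[1], d[2]))
  if (!is.null(object@meta$method)) {
    cat(sprintf("  method: %s\n", object@meta$method))
  }
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@water)
  cat(sprintf(
    "PhantomTruth: %d x %d, B0 range [%.1f, %.1f] Hz, %.0f%% tissue\n",
    d[1], d[2], min(object@b0Hz), max(object@b0Hz),
    100 * mean(object@tissueMask > 0)
  ))
})

setMethod("show", "MetricsRecord", function(object) {
  cat(sprintf(
    "MetricsRecord: corr=%.4f, l1=%.4f, ssim=%.4f, psnr=%.2f dB (n=%d)\n",
    object@corr, object@l1, object@ssim, object@psnr, object@nPixels
  ))
})

setMethod("show", "DixonNet", function(object) {
  cat(sprintf(
    "DixonNet: %d levels, channels (%s), %d parameters%s\n",
    object@config$nLevels,
    paste(object@config$channels, collapse = ", "),
    parameterCount(object),
    if (length(object@history)) ", trained" else ", untrained"
  ))
})
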