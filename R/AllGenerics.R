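#' @export
setGeneric("s1", function(x) standardGeneric("s1"))

#' @export
setGeneric("s2", function(x) standardGeneric("s2"))

#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))

#' @export
setGeneric("water", function(x) standardGeneric("water"))

#' @export
setGeneric("fat", function(x) standardGeneric("fat"))

#' @export
setGeneric("phasor", function(x) standardGeneric("phasor"))

#' @export
setGeneric("selection", function(x) standardGeneric("selection"))

#' @export
setGeneric("b0Hz", function(x) standardGeneric("b0Hz"))

#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @export
setGeneric("degenerateMask", function(x) standardGeneric("degenerateMask"))

#' @export
setGeneric("selectionEnergy", function(graph, labels) {
  standardGeneric("selectionEnergy")
})
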