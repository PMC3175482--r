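# Generics for the package's S4 classes. Accessor names are chosen to avoid
# masking common generics from stats/Bioconductor.

#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @export
setGeneric("discardedGenes", function(x) standardGeneric("discardedGenes"))

#' @export
setGeneric("distanceCap", function(x) standardGeneric("distanceCap"))

#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @export
setGeneric("shrinkage", function(x) standardGeneric("shrinkage"))

#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @export
setGeneric("plsWeights", function(x) standardGeneric("plsWeights"))

#' @export
setGeneric("plsLoadings", function(x) standardGeneric("plsLoadings"))

#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))

#' @export
setGeneric("yLoadings", function(x) standardGeneric("yLoadings"))

#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))

#' @export
setGeneric("chosenModel", function(x) standardGeneric("chosenModel"))
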