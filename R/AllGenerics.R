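#' @export
setGeneric("widthClass", function(x) standardGeneric("widthClass"))

#' @export
setGeneric("estimateLambda", function(x, ...) standardGeneric("estimateLambda"))

#' @export
setGeneric("callHotspots", function(x, ...) standardGeneric("callHotspots"))

#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))

#' @export
setGeneric("lambdaTable", function(x) standardGeneric("lambdaTable"))

#' @export
setGeneric("annotateGenes", function(x, genes, ...) standardGeneric("annotateGenes"))
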