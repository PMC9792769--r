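#' @rdname GeneSignature-class
#' @param x,object a package object.
#' @export
setGeneric("upSet", function(x) standardGeneric("upSet"))

#' @rdname GeneSignature-class
#' @export
setGeneric("downSet", function(x) standardGeneric("downSet"))

#' @rdname GeneSignature-class
#' @export
setGeneric("geneDirections", function(x) standardGeneric("geneDirections"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureStats", function(x) standardGeneric("signatureStats"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureThresholds",
           function(x) standardGeneric("signatureThresholds"))

#' @rdname DrugRankSet-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname DrugRankSet-class
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname DrugRankSet-class
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("cdtIds", function(x) standardGeneric("cdtIds"))
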