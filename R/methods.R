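## Accessors and show methods for the core classes.

#' @describeIn GeneSignature-class genes called up in disease (s(g) = +1).
#' @export
setMethod("upSet", "GeneSignature", function(x) {
  as.character(x@stats$gene[x@stats$direction == 1L])
})

#' @describeIn GeneSignature-class genes called down in disease (s(g) = -1).
#' @export
setMethod("downSet", "GeneSignature", function(x) {
  as.character(x@stats$gene[x@stats$direction == -1L])
})

#' @describeIn GeneSignature-class named integer vector of s(g) over all
#'   tested genes (-1, 0, +1).
#' @export
setMethod("geneDirections", "GeneSignature", function(x) {
  structure(as.integer(x@stats$direction), names = as.character(x@stats$gene))
})

#' @describeIn GeneSignature-class the per-gene statistics table.
#' @export
setMethod("signatureStats", "GeneSignature", function(x) x@stats)

#' @describeIn GeneSignature-class list with alphaQ, minAbsLfc and cohort.
#' @export
setMethod("signatureThresholds", "GeneSignature", function(x) {
  list(alphaQ = x@alphaQ, minAbsLfc = x@minAbsLfc, cohort = x@cohort)
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf(
    "GeneSignature [cohort: %s] %d genes tested; %d up / %d down (q < %g, |log2FC| >= %g)\n",
    object@cohort, nrow(object@stats), sum(object@stats$direction == 1L),
    sum(object@stats$direction == -1L), object@alphaQ, object@minAbsLfc))
  invisible(NULL)
})

#' @describeIn DrugRankSet-class gene identifiers of the shared universe.
#' @export
setMethod("geneUniverse", "DrugRankSet", function(x) rownames(x@ranks))

#' @describeIn DrugRankSet-class drug identifiers.
#' @export
setMethod("drugIds", "DrugRankSet", function(x) colnames(x@ranks))

#' @describeIn DrugRankSet-class the genes x drugs integer rank matrix.
#' @export
setMethod("rankMatrix", "DrugRankSet", function(x) x@ranks)

setMethod("show", "DrugRankSet", function(object) {
  cat(sprintf("DrugRankSet: %d drugs over a universe of %d genes\n",
              ncol(object@ranks), nrow(object@ranks)))
  invisible(NULL)
})

#' @describeIn SignedNetwork-class the edge table.
#' @export
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)

#' @describeIn SignedNetwork-class unique source (CDT) identifiers.
#' @export
setMethod("cdtIds", "SignedNetwork", function(x) {
  sort(unique(as.character(x@edges$source)))
})

setMethod("show", "SignedNetwork", function(object) {
  e <- object@edges
  cat(sprintf(
    "SignedNetwork: %d edges, %d CDTs, %d target genes (%d activating / %d inhibiting)\n",
    nrow(e), length(unique(e$source)), length(unique(e$target)),
    sum(e$sign == 1L), sum(e$sign == -1L)))
  invisible(NULL)
})
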