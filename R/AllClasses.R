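#' GeneSignature: a cohort's signed differential-expression signature
#'
#' Holds the per-gene moderated-t differential expression result for one
#' cohort together with the thresholds used to call direction. The direction
#' sign s(g) is +1 for genes significantly up in tumors (q < alphaQ and
#' log2FC >= +minAbsLfc), -1 for genes significantly down (q < alphaQ and
#' log2FC <= -minAbsLfc), and 0 otherwise.
#'
#' @slot stats a \link[S4Vectors]{DataFrame} with columns \code{gene},
#'   \code{log2fc}, \code{t}, \code{p}, \code{q}, \code{direction}.
#' @slot alphaQ FDR threshold used for direction calls.
#' @slot minAbsLfc minimum absolute log2 fold-change used for direction calls.
#' @slot cohort label of the cohort the signature was derived from.
#'
#' @seealso [buildSignature()], [moderatedTTest()]
#' @export
setClass("GeneSignature",
  slots = c(
    stats = "DFrame",
    alphaQ = "numeric",
    minAbsLfc = "numeric",
    cohort = "character"
  )
)

setValidity("GeneSignature", function(object) {
  st <- object@stats
  need <- c("gene", "log2fc", "t", "p", "q", "direction")
  if (!all(need %in% colnames(st))) {
    return(paste0("stats must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(st$gene)) {
    return("duplicate gene identifiers in signature stats")
  }
  if (length(object@alphaQ) != 1L || is.na(object@alphaQ) ||
      object@alphaQ <= 0 || object@alphaQ > 1) {
    return("alphaQ must be a single value in (0, 1]")
  }
  if (length(object@minAbsLfc) != 1L || is.na(object@minAbsLfc) ||
      object@minAbsLfc < 0) {
    return("minAbsLfc must be a single non-negative value")
  }
  if (!all(st$direction %in% c(-1L, 0L, 1L))) {
    return("direction must be -1, 0 or 1")
  }
  expected <- callDirections(st$log2fc, st$q, object@alphaQ, object@minAbsLfc)
  if (!identical(as.integer(st$direction), expected)) {
    return("direction column is inconsistent with q/log2fc and thresholds")
  }
  TRUE
})

#' Construct a GeneSignature from a per-gene statistics table
#'
#' @param stats DataFrame or data.frame with columns gene, log2fc, t, p, q,
#'   direction.
#' @param alphaQ,minAbsLfc thresholds that produced the direction column.
#' @param cohort cohort label.
#' @return a [GeneSignature-class] object.
#' @export
GeneSignature <- function(stats, alphaQ = 0.05, minAbsLfc = 0,
                          cohort = NA_character_) {
  new("GeneSignature", stats = as(stats, "DFrame"),
      alphaQ = alphaQ, minAbsLfc = minAbsLfc, cohort = as.character(cohort))
}

# shared direction rule: exact zero fold-changes are never called
callDirections <- function(log2fc, q, alphaQ, minAbsLfc) {
  sig <- !is.na(q) & !is.na(log2fc) & q < alphaQ
  up <- sig & log2fc >= minAbsLfc & log2fc > 0
  dn <- sig & log2fc <= -minAbsLfc & log2fc < 0
  as.integer(ifelse(up, 1L, ifelse(dn, -1L, 0L)))
}

#' DrugRankSet: drug-exposure rank profiles over a shared gene universe
#'
#' A genes x drugs integer matrix in which each column is a permutation of
#' 1..n_genes: rank 1 is the gene most up-regulated under exposure to that
#' drug, rank n the most down-regulated.
#'
#' @slot ranks integer matrix with gene rownames and drug colnames; every
#'   column is a permutation of \code{seq_len(nrow)}.
#'
#' @seealso [readDrugProfiles()], [generateDrugProfiles()]
#' @export
setClass("DrugRankSet", slots = c(ranks = "matrix"))

setValidity("DrugRankSet", function(object) {
  m <- object@ranks
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("ranks matrix must have gene rownames and drug colnames")
  }
  if (anyDuplicated(rownames(m))) return("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) return("duplicate drug identifiers")
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (!identical(sort(as.integer(m[, j])), seq_len(n))) {
      return(sprintf("ranks for drug '%s' are not a permutation of 1..%d",
                     colnames(m)[j], n))
    }
  }
  TRUE
})

#' Construct a DrugRankSet
#'
#' @param ranks integer matrix (genes x drugs) of exposure ranks; each column
#'   must be a permutation of 1..nrow(ranks).
#' @return a [DrugRankSet-class] object.
#' @export
DrugRankSet <- function(ranks) {
  storage.mode(ranks) <- "integer"
  new("DrugRankSet", ranks = ranks)
}

#' SignedNetwork: CDT-to-gene signed interaction edges
#'
#' Edge list of a directed network whose source nodes are chemicals, drugs or
#' toxicants (CDTs) and whose targets are genes. Each edge carries a sign
#' (+1 activation, -1 inhibition) and a confidence weight in (0, 1].
#'
#' @slot edges a \link[S4Vectors]{DataFrame} with columns \code{source},
#'   \code{target}, \code{sign}, \code{weight}.
#'
#' @seealso [readNetwork()], [scoreAllRegulators()]
#' @export
setClass("SignedNetwork", slots = c(edges = "DFrame"))

setValidity("SignedNetwork", function(object) {
  e <- object@edges
  need <- c("source", "target", "sign", "weight")
  if (!all(need %in% colnames(e))) {
    return(paste0("edges must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (!all(e$sign %in% c(-1L, 1L))) return("edge sign must be +1 or -1")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0) || any(e$weight > 1)) {
      return("edge weights must lie in (0, 1]")
    }
    if (anyDuplicated(paste(e$source, e$target, sep = "\r"))) {
      return("duplicated (source, target) edge")
    }
    if (any(!nzchar(e$source)) || any(!nzchar(e$target))) {
      return("empty source or target identifier")
    }
  }
  TRUE
})

#' Construct a SignedNetwork from an edge table
#'
#' @param edges DataFrame or data.frame with columns source, target, sign
#'   (+1/-1) and weight in (0, 1].
#' @return a [SignedNetwork-class] object.
#' @export
SignedNetwork <- function(edges) {
  e <- as(edges, "DFrame")
  e$sign <- as.integer(e$sign)
  e$weight <- as.numeric(e$weight)
  new("SignedNetwork", edges = e)
}
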