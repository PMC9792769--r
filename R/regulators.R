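## Upstream-regulator analysis on a signed CDT-to-gene network: classify DE
## target genes as consistent with an activated (HA) or inhibited (HI)
## regulator, combine the evidence in a confidence-weighted z-score, and map
## it to a normal p-value. A therapeutic (reverting) drug looks *inhibited*
## in disease tissue, because disease is modeled as the state associated
## with the drug's absence.

# edges of one CDT joined to the signature's DE directions
.cdtDeEdges <- function(cdt, network, signature) {
  e <- networkEdges(network)
  e <- e[e$source == cdt, , drop = FALSE]
  dirs <- geneDirections(signature)
  sg <- dirs[match(e$target, names(dirs))]
  sg[is.na(sg)] <- 0L
  e$sg <- as.integer(sg)
  e
}

#' Per-gene consistency counts for one CDT
#'
#' A DE target gene (s(g) != 0, at least one incoming edge from the CDT)
#' counts toward HA (regulator activated) if any of its incoming edges has
#' sign(e) = sign(g), and toward HI (regulator inhibited) if any edge has
#' sign(e) != sign(g). Non-DE genes contribute nothing.
#'
#' @param cdt CDT identifier.
#' @param network a [SignedNetwork-class] object.
#' @param signature a [GeneSignature-class] object.
#' @return named integer vector: nConsistentHA, nConsistentHI, nDeTargets.
#' @export
consistencyCounts <- function(cdt, network, signature) {
  e <- .cdtDeEdges(cdt, network, signature)
  de <- e[e$sg != 0L, , drop = FALSE]
  if (!nrow(de)) {
    return(c(nConsistentHA = 0L, nConsistentHI = 0L, nDeTargets = 0L))
  }
  byGene <- split(seq_len(nrow(de)), de$target)
  ha <- sum(vapply(byGene, function(i) any(de$sign[i] == de$sg[i]), logical(1)))
  hi <- sum(vapply(byGene, function(i) any(de$sign[i] != de$sg[i]), logical(1)))
  c(nConsistentHA = as.integer(ha), nConsistentHI = as.integer(hi),
    nDeTargets = length(byGene))
}

#' Confidence-weighted regulator z-score for one CDT
#'
#' z = sum over edges e to DE genes g of w(e) * s(e) * s(g), divided by
#' sqrt(sum of w(e)^2) over the same edges. With unit weights and k edges
#' this is (HA-consistent - HI-consistent edges) / sqrt(k). Negative z
#' supports the inhibited hypothesis, i.e. a drug whose presence would
#' revert the observed changes.
#'
#' @inheritParams consistencyCounts
#' @return the z-score, or NA if the CDT has no edge to a DE gene.
#' @export
regulatorZscore <- function(cdt, network, signature) {
  e <- .cdtDeEdges(cdt, network, signature)
  de <- e[e$sg != 0L, , drop = FALSE]
  if (!nrow(de)) return(NA_real_)
  sum(de$weight * de$sign * de$sg) / sqrt(sum(de$weight^2))
}

#' Map a regulator z-score to a normal-distribution p-value
#'
#' \code{inhibited}: left tail Phi(z) (therapeutic reversal);
#' \code{activated}: right tail 1 - Phi(z); \code{two_sided}: 2*Phi(-|z|).
#'
#' @param z finite z-score.
#' @param hypothesis one of "inhibited", "activated", "two_sided".
#' @return p-value in [0, 1].
#' @export
zscorePvalue <- function(z, hypothesis = c("inhibited", "activated",
                                           "two_sided")) {
  hypothesis <- match.arg(hypothesis)
  if (any(!is.finite(z))) stop("z must be finite")
  switch(hypothesis,
         inhibited = pnorm(z),
         activated = 1 - pnorm(z),
         two_sided = 2 * pnorm(-abs(z)))
}

#' Score every CDT of a network against one signature
#'
#' One result row per CDT with at least one edge to a DE gene, filtered to
#' p < alpha under the chosen tail and sorted ascending by p. The
#' \code{consistent_over_targets} column formats the inhibited-consistent
#' count over the DE target count in the "15/19" convention. CDTs with no
#' DE-gene edge are omitted with a note.
#'
#' @inheritParams consistencyCounts
#' @param alpha significance threshold for retaining CDTs (use 1 to keep
#'   all).
#' @param tail hypothesis tail for the p-value; the default "inhibited"
#'   selects drugs that would revert the disease changes.
#' @return \link[S4Vectors]{DataFrame} with columns cdt_id, n_de_targets,
#'   n_consistent_HI, n_consistent_HA, consistent_over_targets, z, p, call.
#' @export
scoreAllRegulators <- function(network, signature, alpha = 0.05,
                               tail = c("inhibited", "activated",
                                        "two_sided")) {
  tail <- match.arg(tail)
  stopIfNotScalarProb(alpha, "alpha", openUpper = FALSE)
  cdts <- cdtIds(network)
  rows <- lapply(cdts, function(cdt) {
    cc <- consistencyCounts(cdt, network, signature)
    if (cc[["nDeTargets"]] == 0L) return(NULL)
    z <- regulatorZscore(cdt, network, signature)
    p <- zscorePvalue(z, tail)
    S4Vectors::DataFrame(
      cdt_id = cdt,
      n_de_targets = cc[["nDeTargets"]],
      n_consistent_HI = cc[["nConsistentHI"]],
      n_consistent_HA = cc[["nConsistentHA"]],
      consistent_over_targets = sprintf("%d/%d", cc[["nConsistentHI"]],
                                        cc[["nDeTargets"]]),
      z = z, p = p,
      call = if (p < alpha && z != 0) (if (z < 0) "inhibited" else
        "activated") else "none")
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) {
    message(sprintf("%d CDT(s) without DE-gene edges omitted from regulator scoring",
                    skipped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(S4Vectors::DataFrame(cdt_id = character(0),
                                n_de_targets = integer(0),
                                n_consistent_HI = integer(0),
                                n_consistent_HA = integer(0),
                                consistent_over_targets = character(0),
                                z = numeric(0), p = numeric(0),
                                call = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(out$p, out$cdt_id), , drop = FALSE]
}

#' Intersect regulator calls across cohorts
#'
#' Keeps only CDTs significant in every supplied result table (the
#' multi-cohort pattern: drugs with a significant therapeutic effect on all
#' cancers analyzed), ordered by the first table's p-value.
#'
#' @param results named list of tables from [scoreAllRegulators()], one per
#'   signature/cohort, already filtered at the desired alpha.
#' @return the first table restricted to the common CDTs, with per-table
#'   p-values appended as \code{p.<name>} columns.
#' @export
intersectRegulators <- function(results) {
  if (!length(results)) stop("no regulator tables supplied")
  common <- Reduce(intersect, lapply(results, function(r) r$cdt_id))
  out <- results[[1L]][results[[1L]]$cdt_id %in% common, , drop = FALSE]
  if (length(results) > 1L && !is.null(names(results))) {
    for (nm in names(results)[-1L]) {
      r <- results[[nm]]
      out[[paste0("p.", nm)]] <- r$p[match(out$cdt_id, r$cdt_id)]
    }
  }
  out[order(out$p, out$cdt_id), , drop = FALSE]
}
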