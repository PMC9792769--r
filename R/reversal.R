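## Connectivity-map style signature-reversal scoring: a two-sided KS
## composite on a drug's exposure rank profile, normalized per collection to
## [-1, +1], with a gene-set permutation null. The largest negative score
## marks the strongest reverter.

#' Two-sided KS enrichment statistic of a gene set in a rank profile
#'
#' With pos(1) < ... < pos(t) the sorted profile ranks of the set genes and
#' n the universe size: a = max_j(j/t - pos(j)/n),
#' b = max_j(pos(j)/n - (j-1)/t); returns a if a > b else -b. Positive
#' values mean the set concentrates at the top (most up-regulated) end of
#' the profile, negative at the bottom.
#'
#' @param geneSet non-empty character vector, a subset of the profile
#'   universe.
#' @param ranks named integer vector gene -> rank (a permutation of 1..n),
#'   e.g. one column of [rankMatrix()].
#' @return a value in [-1, 1].
#' @export
ksStatistic <- function(geneSet, ranks) {
  if (!length(geneSet)) stop("gene set is empty")
  missing <- setdiff(geneSet, names(ranks))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from profile universe: %s",
                 paste(missing, collapse = ", ")))
  }
  n <- length(ranks)
  pos <- sort(unname(ranks[geneSet]))
  t <- length(pos)
  j <- seq_len(t)
  a <- max(j / t - pos / n)
  b <- max(pos / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Raw connectivity scores of every drug against a signature
#'
#' ks_up and ks_down are the KS statistics of the signature's up- and
#' down-sets in each drug profile; raw_score = 0 when the two components
#' share a sign, else ks_up - ks_down. A reverting drug (disease-up genes at
#' the bottom of the drug profile, disease-down genes at the top) scores
#' negative.
#'
#' @param signature a [GeneSignature-class] object.
#' @param drugs a [DrugRankSet-class] object.
#' @return \link[S4Vectors]{DataFrame} with columns drug_id, ks_up, ks_down,
#'   raw_score; metadata records the up/down set sizes after intersection
#'   with the universe.
#' @export
connectivityScores <- function(signature, drugs) {
  universe <- geneUniverse(drugs)
  up <- intersect(upSet(signature), universe)
  down <- intersect(downSet(signature), universe)
  if (!length(up) || !length(down)) {
    warning("signature up- or down-set has empty intersection with the drug universe; no drug scored")
    out <- S4Vectors::DataFrame(drug_id = character(0), ks_up = numeric(0),
                                ks_down = numeric(0), raw_score = numeric(0))
    S4Vectors::metadata(out) <- list(nUp = length(up), nDown = length(down),
                                     nUniverse = length(universe))
    return(out)
  }
  m <- rankMatrix(drugs)
  ids <- drugIds(drugs)
  ku <- vapply(ids, function(d) {
    ksStatistic(up, structure(m[, d], names = universe))
  }, numeric(1))
  kd <- vapply(ids, function(d) {
    ksStatistic(down, structure(m[, d], names = universe))
  }, numeric(1))
  raw <- ifelse(sign(ku) == sign(kd), 0, ku - kd)
  out <- S4Vectors::DataFrame(drug_id = ids, ks_up = unname(ku),
                              ks_down = unname(kd), raw_score = unname(raw))
  S4Vectors::metadata(out) <- list(nUp = length(up), nDown = length(down),
                                   nUniverse = length(universe))
  out
}

#' Scale raw connectivity scores to the [-1, +1] collection scale
#'
#' norm_score = raw_score / max(|raw_score|) over the collection (all zero
#' when that maximum is 0), so the strongest-magnitude reverter attains
#' exactly -1.
#'
#' @param scores DataFrame from [connectivityScores()].
#' @return the same table with a \code{norm_score} column added.
#' @export
normalizeScores <- function(scores) {
  if (!nrow(scores)) {
    scores$norm_score <- numeric(0)
    return(scores)
  }
  mx <- max(abs(scores$raw_score))
  scores$norm_score <- if (mx > 0) scores$raw_score / mx else
    rep(0, nrow(scores))
  scores
}

#' Permutation p- and q-values for connectivity scores
#'
#' For each drug, the null redraws disjoint random up/down gene sets of the
#' observed sizes from the profile universe and recomputes the raw score;
#' p = (1 + #\{|raw*| >= |raw|\}) / (1 + nPerm) (two-sided by magnitude,
#' add-one smoothed), and q is the BH adjustment across drugs. Deterministic
#' given \code{seed}.
#'
#' @param scores DataFrame from [connectivityScores()] (its metadata carries
#'   the set sizes).
#' @param drugs the [DrugRankSet-class] the scores were computed on.
#' @param nPerm number of permutations per drug (>= 1; >= 100 recommended).
#' @param seed integer seed.
#' @return the table with \code{p} and \code{q} columns added.
#' @export
permutationPvalues <- function(scores, drugs, nPerm = 1000, seed = 1) {
  if (!is.numeric(nPerm) || length(nPerm) != 1L || nPerm < 1) {
    stop("nPerm must be a positive integer")
  }
  nPerm <- as.integer(nPerm)
  meta <- S4Vectors::metadata(scores)
  n <- length(geneUniverse(drugs))
  if (!nrow(scores)) {
    scores$p <- numeric(0)
    scores$q <- numeric(0)
    return(scores)
  }
  p <- withSeed(seed, {
    vapply(seq_len(nrow(scores)), function(i) {
      nullRaw <- .ksNullRaw(meta$nUp, meta$nDown, n, nPerm)
      (1 + sum(abs(nullRaw) >= abs(scores$raw_score[i]))) / (1 + nPerm)
    }, numeric(1))
  })
  scores$p <- p
  scores$q <- bhAdjust(p)
  scores
}

#' Filter and order drugs by reversal strength
#'
#' Keeps drugs with q < alphaQ, sorts ascending by norm_score (largest
#' negative, i.e. strongest reverter, first; ties broken by drug_id) and
#' assigns ranks 1..k.
#'
#' @param scores DataFrame with norm_score and q columns.
#' @param alphaQ FDR threshold for retaining drugs.
#' @return the filtered, ordered table with a \code{rank} column first.
#' @export
rankDrugs <- function(scores, alphaQ = 0.05) {
  stopIfNotScalarProb(alphaQ, "alphaQ", openUpper = FALSE)
  keep <- scores[!is.na(scores$q) & scores$q < alphaQ, , drop = FALSE]
  if (!nrow(keep)) {
    warning("no drug passes the FDR threshold; returning an empty ranking")
  }
  ord <- order(keep$norm_score, keep$drug_id)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  keep[, c("rank", setdiff(colnames(keep), "rank"))]
}

#' Score, test and rank a drug collection against a signature
#'
#' Convenience composition of [connectivityScores()], [normalizeScores()]
#' and [permutationPvalues()]; use [rankDrugs()] on the result for the
#' final filtered ordering.
#'
#' @inheritParams permutationPvalues
#' @inheritParams connectivityScores
#' @return annotated score table (one row per drug).
#' @export
scoreDrugs <- function(signature, drugs, nPerm = 1000, seed = 1) {
  scores <- normalizeScores(connectivityScores(signature, drugs))
  permutationPvalues(scores, drugs, nPerm = nPerm, seed = seed)
}
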