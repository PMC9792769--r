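## Ranking evaluation: NDCG and sensitivity-at-cutoff curves against random
## controls. Relevance is binary; approved and investigational drugs are
## both labeled relevant.

#' Binary relevance labels for an ordered drug list
#'
#' @param drugs ordered character vector of ranked drug ids (no duplicates).
#' @param gold character vector of relevant drug ids; drugs absent from it
#'   get relevance 0.
#' @return integer vector of 0/1 relevances in list order.
#' @export
relevanceLabels <- function(drugs, gold) {
  if (anyDuplicated(drugs)) stop("ranked drug list contains duplicates")
  as.integer(drugs %in% gold)
}

#' Discounted cumulative gain at a cutoff
#'
#' DCG(p) = sum over i = 1..p of (2^rel_i - 1) / log2(i + 1).
#'
#' @param relevances binary 0/1 vector in rank order.
#' @param p cutoff rank (1 <= p <= length(relevances)).
#' @return the DCG value.
#' @export
dcg <- function(relevances, p = length(relevances)) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    stop("cutoff p must be a positive integer")
  }
  if (p > length(relevances)) stop("cutoff p exceeds list length")
  i <- seq_len(p)
  sum((2^relevances[i] - 1) / log2(i + 1))
}

#' Normalized discounted cumulative gain at a cutoff
#'
#' NDCG = DCG / IDCG, where IDCG is the DCG of the relevance multiset
#' sorted descending and truncated at p. Defined as 0 when no drug in the
#' list is relevant (IDCG = 0).
#'
#' @inheritParams dcg
#' @return a value in [0, 1].
#' @export
ndcg <- function(relevances, p = length(relevances)) {
  ideal <- sort(relevances, decreasing = TRUE)
  idcg <- dcg(ideal, p)
  if (idcg == 0) return(0)
  dcg(relevances, p) / idcg
}

#' Sensitivity (recall of gold drugs) at rank cutoffs
#'
#' sensitivity(k) = |top-k of the list intersected with gold| / |gold|.
#'
#' @param drugs ordered character vector of ranked drug ids.
#' @param gold non-empty character vector of relevant drug ids.
#' @param cutoffs increasing integer rank cutoffs, each <= length(drugs).
#' @return data.frame with columns cutoff, sensitivity.
#' @export
sensitivityAtCutoffs <- function(drugs, gold, cutoffs) {
  if (!length(gold)) {
    stop("gold-standard set is empty; use NDCG-only evaluation")
  }
  if (any(cutoffs < 1) || any(cutoffs > length(drugs))) {
    stop("cutoffs must lie in 1..length(drugs)")
  }
  hits <- cumsum(drugs %in% gold)
  data.frame(cutoff = as.integer(cutoffs),
             sensitivity = hits[cutoffs] / length(unique(gold)))
}

#' Random-control curves for a ranked drug list
#'
#' Uniformly permutes the same candidate drug list \code{nControls} times
#' and reports, per cutoff, the mean sensitivity with an empirical 5-95%
#' band and the mean NDCG. Deterministic given \code{seed}. The expected
#' mean sensitivity at cutoff k is approximately k / length(drugs).
#'
#' @inheritParams sensitivityAtCutoffs
#' @param nControls number of random orderings (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns cutoff, mean_sensitivity, lo_sensitivity,
#'   hi_sensitivity, mean_ndcg.
#' @export
randomControlCurve <- function(drugs, gold, cutoffs, nControls = 1000,
                               seed = 1) {
  if (!is.numeric(nControls) || length(nControls) != 1L || nControls < 1) {
    stop("nControls must be a positive integer")
  }
  if (!length(gold)) {
    stop("gold-standard set is empty; use NDCG-only evaluation")
  }
  if (any(cutoffs < 1) || any(cutoffs > length(drugs))) {
    stop("cutoffs must lie in 1..length(drugs)")
  }
  nControls <- as.integer(nControls)
  sens <- matrix(NA_real_, nrow = nControls, ncol = length(cutoffs))
  nd <- matrix(NA_real_, nrow = nControls, ncol = length(cutoffs))
  withSeed(seed, {
    for (b in seq_len(nControls)) {
      perm <- sample(drugs)
      rel <- relevanceLabels(perm, gold)
      hits <- cumsum(rel)
      sens[b, ] <- hits[cutoffs] / length(unique(gold))
      nd[b, ] <- vapply(cutoffs, function(p) ndcg(rel, p), numeric(1))
    }
  })
  data.frame(
    cutoff = as.integer(cutoffs),
    mean_sensitivity = colMeans(sens),
    lo_sensitivity = apply(sens, 2L, quantile, probs = 0.05, names = FALSE),
    hi_sensitivity = apply(sens, 2L, quantile, probs = 0.95, names = FALSE),
    mean_ndcg = colMeans(nd))
}
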